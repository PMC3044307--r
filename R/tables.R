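#' Directional and pairwise information tables
#'
#' The trained model: per-state information differences in natural-log
#' units (nats).  `dir[s, m, r]` is the directional information carried
#' by residue `r` at window offset `m` about state `s` at the center;
#' `pair[s, p, r1, r2]` is the pairwise information carried by the
#' residue pair (`r1`, `r2`) at position-pair index `p`.  Each entry is
#' the log-likelihood ratio of observing the evidence under state `s`
#' versus not-`s`, plus the log prior-odds correction, so downstream
#' normalization is a pure function of the three per-state sums.
#'
#' Tables may be held at double precision or quantized to 32-bit
#' integers at a fixed scale (see [quantizeTables()]).
#'
#' @slot dir `3 x 17 x 21` numeric (or integer, when quantized) array.
#' @slot pair `3 x 136 x 21 x 21` numeric (or integer) array.
#' @slot quantized Logical flag.
#' @slot scale Quantization scale; `NA` for double-precision tables.
#' @seealso [countsToInformation()], [quantizeTables()],
#'   [segmentPairTable()], [saveModel()]
#' @export
setClass("InformationTables",
         representation(dir = "array", pair = "array",
                        quantized = "logical", scale = "numeric"),
         validity = function(object) {
           if (!identical(dim(object@dir), c(3L, .WINDOW, .NRES)))
             return("'dir' must be a 3 x 17 x 21 array")
           if (!identical(dim(object@pair), c(3L, .NPAIRS, .NRES, .NRES)))
             return("'pair' must be a 3 x 136 x 21 x 21 array")
           if (length(object@quantized) != 1L || is.na(object@quantized))
             return("'quantized' must be TRUE or FALSE")
           if (object@quantized) {
             if (!is.integer(object@dir) || !is.integer(object@pair))
               return("quantized tables must hold integer values")
             if (length(object@scale) != 1L || is.na(object@scale) ||
                 object@scale <= 0)
               return("quantized tables need a positive 'scale'")
           } else {
             if (!all(is.finite(object@dir)) || !all(is.finite(object@pair)))
               return("table entries must all be finite")
           }
           TRUE
         })

setMethod("show", "InformationTables", function(object) {
  cat("InformationTables (3 states, 17-residue window, 21-symbol alphabet)\n")
  cat(sprintf("  dir : 3 x 17 x 21; pair: 3 x 136 x 21 x 21 (%d KB/state at double precision)\n",
              pairTableBytes(object) %/% 1024L))
  if (object@quantized)
    cat(sprintf("  quantized to int32 at scale %g\n", object@scale))
  else
    cat("  double precision\n")
})

#' @rdname InformationTables-class
#' @param x An `InformationTables` object.
#' @return `dirInformation` and `pairInformation` return the stored
#'   arrays; `isQuantized` the flag; `quantScale` the scale (`NA` when
#'   not quantized).
#' @export
dirInformation <- function(x) {
  stopifnot(is(x, "InformationTables"))
  x@dir
}

#' @rdname InformationTables-class
#' @export
pairInformation <- function(x) {
  stopifnot(is(x, "InformationTables"))
  x@pair
}

#' @rdname InformationTables-class
#' @export
isQuantized <- function(x) {
  stopifnot(is(x, "InformationTables"))
  x@quantized
}

#' @rdname InformationTables-class
#' @export
quantScale <- function(x) {
  stopifnot(is(x, "InformationTables"))
  x@scale
}

# Tables as double-precision arrays regardless of storage (quantized
# entries are divided by the scale).
.tableValues <- function(tables) {
  if (tables@quantized)
    list(dir = tables@dir / tables@scale, pair = tables@pair / tables@scale)
  else
    list(dir = tables@dir, pair = tables@pair)
}

#' Turn raw counts into information tables
#'
#' For each state `s` the evidence from the other two states is pooled
#' ("not-s") and each entry becomes the smoothed information difference
#' `ln((count_s + d) / (count_notS + d))`.  Because the counts scale
#' with the per-state totals, this is the log-likelihood ratio of the
#' observation under `s` versus not-`s` *with the log prior odds folded
#' in* (it equals `ln(P(obs|s)/P(obs|notS)) + ln(n_s/n_notS)`), i.e. the
#' per-observation posterior log odds.  Under the `2/17` / `15/17`
#' combination of [informationSum()] the constant prior part survives
#' exactly once (136 pair terms at weight 2/17 contribute 16 copies, 17
#' directional terms at weight 15/17 remove 15), so the window sum is
#' the posterior log odds of the window and a model trained on
#' signal-free data degenerates to predicting the most common state.
#' The pseudocount `d > 0` guarantees finite entries even for counts
#' that are zero on small training sets.
#'
#' @param counts A [TrainingCounts-class] object.
#' @param pseudocount Smoothing constant; defaults to the one stored in
#'   `counts`.
#' @return An [InformationTables-class] object at double precision.
#' @export
countsToInformation <- function(counts, pseudocount = counts@pseudocount) {
  stopifnot(is(counts, "TrainingCounts"))
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  d <- pseudocount
  dirTot <- counts@singlet[1L, , ] + counts@singlet[2L, , ] + counts@singlet[3L, , ]
  pairTot <- counts@pair[1L, , , ] + counts@pair[2L, , , ] + counts@pair[3L, , , ]
  dir <- array(0, dim = dim(counts@singlet))
  pair <- array(0, dim = dim(counts@pair))
  for (s in 1:3) {
    dir[s, , ] <- log((counts@singlet[s, , ] + d) /
                      (dirTot - counts@singlet[s, , ] + d))
    pair[s, , , ] <- log((counts@pair[s, , , ] + d) /
                         (pairTot - counts@pair[s, , , ] + d))
  }
  new("InformationTables", dir = dir, pair = pair,
      quantized = FALSE, scale = NA_real_)
}

#' Quantize tables to 32-bit integers
#'
#' Stores every entry `v` as `round(v * scale)` (round half away from
#' zero) in 32-bit integers, halving the storage of the double-precision
#' tables.  The dequantization error is at most `0.5 / scale` per entry;
#' at the default scale `2^16` that is below `2^-16` nats, far inside
#' the margin that separates the three per-residue information sums in
#' practice, so the predicted states are unchanged.
#'
#' @param tables A double-precision [InformationTables-class].
#' @param scale Positive scale; `scale * max(|v|)` must fit in int32.
#' @return A quantized [InformationTables-class].
#' @seealso [dequantizeTables()]
#' @export
quantizeTables <- function(tables, scale = 2^16) {
  stopifnot(is(tables, "InformationTables"))
  if (tables@quantized)
    stop("tables are already quantized", call. = FALSE)
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive number", call. = FALSE)
  maxAbs <- max(abs(tables@dir), abs(tables@pair))
  if (maxAbs * scale > .Machine$integer.max)
    stop(sprintf("quantization overflow: |v| = %g at scale %g exceeds the 32-bit range",
                 maxAbs, scale), call. = FALSE)
  q <- function(a) {
    out <- as.integer(sign(a) * floor(abs(a) * scale + 0.5))
    array(out, dim = dim(a))
  }
  new("InformationTables", dir = q(tables@dir), pair = q(tables@pair),
      quantized = TRUE, scale = scale)
}

#' @rdname quantizeTables
#' @return `dequantizeTables` maps a quantized model back to double
#'   precision (entries divided by the scale).
#' @export
dequantizeTables <- function(tables) {
  stopifnot(is(tables, "InformationTables"))
  if (!tables@quantized)
    return(tables)
  v <- .tableValues(tables)
  new("InformationTables", dir = v$dir, pair = v$pair,
      quantized = FALSE, scale = NA_real_)
}

#' Pairwise table segmented by position pair
#'
#' The pairwise table split into 136 independent segments, one per
#' window-position pair, each holding the packed 3-state `21 x 21` block
#' for that pair index.  Segments partition the table exactly (disjoint
#' and exhaustive), so any entry can be served from a single segment —
#' the software analogue of distributing the table across independent
#' memory banks for conflict-free parallel lookup.
#'
#' @slot segments List of 136 `3 x 21 x 21` arrays.
#' @slot dir The directional table, carried unchanged.
#' @slot quantized,scale Storage metadata, as in
#'   [InformationTables-class].
#' @export
setClass("SegmentedTables",
         representation(segments = "list", dir = "array",
                        quantized = "logical", scale = "numeric"),
         validity = function(object) {
           if (length(object@segments) != .NPAIRS)
             return("exactly 136 segments required")
           ok <- vapply(object@segments, function(seg)
             identical(dim(seg), c(3L, .NRES, .NRES)), logical(1L))
           if (!all(ok))
             return("each segment must be a 3 x 21 x 21 array")
           TRUE
         })

setMethod("show", "SegmentedTables", function(object) {
  cat(sprintf("SegmentedTables: %d pair-table segments of 3 x 21 x 21%s\n",
              length(object@segments),
              if (object@quantized) " (quantized)" else ""))
})

#' Split the pairwise table into 136 segments
#'
#' @param tables An [InformationTables-class] object.
#' @return A [SegmentedTables-class] object.
#' @export
segmentPairTable <- function(tables) {
  stopifnot(is(tables, "InformationTables"))
  segments <- lapply(seq_len(.NPAIRS), function(p) tables@pair[, p, , ])
  new("SegmentedTables", segments = segments, dir = tables@dir,
      quantized = tables@quantized, scale = tables@scale)
}

#' @rdname segmentPairTable
#' @param seg A [SegmentedTables-class] object.
#' @param p Pair index, 0-based (0..135).
#' @param r1,r2 Residue codes, 0-based (0..20), `r1` at the earlier
#'   window position.
#' @return `fetchSegment` returns the packed 3-state value vector
#'   (named `H`, `E`, `C`) read from segment `p` alone.
#' @export
fetchSegment <- function(seg, p, r1, r2) {
  stopifnot(is(seg, "SegmentedTables"))
  p <- as.integer(p)
  if (p < 0L || p >= .NPAIRS)
    stop("pair index must lie in 0..135", call. = FALSE)
  if (r1 < 0L || r1 >= .NRES || r2 < 0L || r2 >= .NRES)
    stop("residue codes must lie in 0..20", call. = FALSE)
  setNames(seg@segments[[p + 1L]][, r1 + 1L, r2 + 1L], .STATES)
}

#' @rdname segmentPairTable
#' @return `reassembleTables` rebuilds the full
#'   [InformationTables-class]; reassembly is bit-exact.
#' @export
reassembleTables <- function(seg) {
  stopifnot(is(seg, "SegmentedTables"))
  pair <- array(if (seg@quantized) 0L else 0,
                dim = c(3L, .NPAIRS, .NRES, .NRES))
  for (p in seq_len(.NPAIRS))
    pair[, p, , ] <- seg@segments[[p]]
  new("InformationTables", dir = seg@dir, pair = pair,
      quantized = seg@quantized, scale = seg@scale)
}

#' Byte footprint of the pairwise table
#'
#' At double precision one state's pairwise table occupies
#' `21 * 21 * 136 * 8` bytes — the address stride between two successive
#' per-state lookups when states are stored block-contiguously.
#'
#' @param tables An [InformationTables-class] object (geometry only; the
#'   count assumes 8-byte entries).
#' @param perState If `TRUE` (default), one state's block; otherwise all
#'   three states.
#' @return Integer byte count.
#' @examples
#' tbl <- countsToInformation(
#'   accumulateCounts(list(list(sequence = encodeSequence("ACD", "x"),
#'                              structure = c("H", "H", "C")))))
#' pairTableBytes(tbl)            # 479808
#' pairTableBytes(tbl) %/% 1024   # 468 KB
#' @export
pairTableBytes <- function(tables, perState = TRUE) {
  stopifnot(is(tables, "InformationTables"))
  per <- .NRES * .NRES * .NPAIRS * 8L
  if (perState) per else 3L * per
}
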