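# Window geometry: 17 residues, 8 on each side of the center, and the
# C(17,2) = 136 unordered position pairs enumerated lexicographically.
.WINDOW <- 17L
.HALF <- 8L
.NPAIRS <- 136L

# 136 x 2 matrix of 0-based (j1, j2) with j1 < j2, row p+1 = pair index p.
.PAIRS <- local({
  idx <- which(upper.tri(matrix(0L, .WINDOW, .WINDOW)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  cbind(j1 = idx[, 1L] - 1L, j2 = idx[, 2L] - 1L)
})

#' Index of an unordered window-position pair
#'
#' Maps an ordered pair of window positions `j1 < j2` (0-based, both in
#' 0..16) to its index in the lexicographic enumeration of the 136
#' unordered pairs: `j1*17 - j1*(j1+1)/2 + (j2 - j1 - 1)`.
#' [pairPositions()] is the inverse.
#'
#' @param j1,j2 Window positions, 0-based, `j1 < j2`.
#' @return Integer pair index in 0..135 (vectorized).
#' @examples
#' pairIndex(0, 1)    # 0
#' pairIndex(15, 16)  # 135
#' @export
pairIndex <- function(j1, j2) {
  j1 <- as.integer(j1); j2 <- as.integer(j2)
  if (any(j1 < 0L | j2 >= .WINDOW | j1 >= j2))
    stop("pair positions must satisfy 0 <= j1 < j2 <= 16", call. = FALSE)
  j1 * .WINDOW - (j1 * (j1 + 1L)) %/% 2L + (j2 - j1 - 1L)
}

#' @rdname pairIndex
#' @param p Pair index in 0..135.
#' @return `pairPositions(p)` returns a two-column matrix of 0-based
#'   `(j1, j2)`.
#' @export
pairPositions <- function(p) {
  p <- as.integer(p)
  if (any(p < 0L | p >= .NPAIRS))
    stop("pair index must lie in 0..135", call. = FALSE)
  .PAIRS[p + 1L, , drop = FALSE]
}

#' Raw training counts
#'
#' Occurrence counts accumulated over a training database: for every
#' residue position with known state `s`, the 17-residue window around it
#' contributes one count per window offset (singlet) and one per
#' unordered position pair (pair).  Positions beyond the sequence ends
#' count as the boundary symbol `X`.
#'
#' @slot singlet `3 x 17 x 21` array: `[s, m, r]` counts residue code `r`
#'   at window offset `m` around a position in state `s`.
#' @slot pair `3 x 136 x 21 x 21` array: `[s, p, r1, r2]` counts the
#'   ordered residue pair (`r1` at the earlier window position) at pair
#'   index `p`.
#' @slot nState Named numeric vector of total positions per state.
#' @slot pseudocount Positive smoothing constant carried to
#'   [countsToInformation()].
#' @export
setClass("TrainingCounts",
         representation(singlet = "array", pair = "array",
                        nState = "numeric", pseudocount = "numeric"),
         validity = function(object) {
           if (!identical(dim(object@singlet), c(3L, .WINDOW, .NRES)))
             return("'singlet' must be a 3 x 17 x 21 array")
           if (!identical(dim(object@pair), c(3L, .NPAIRS, .NRES, .NRES)))
             return("'pair' must be a 3 x 136 x 21 x 21 array")
           if (length(object@nState) != 3L || any(object@nState < 0))
             return("'nState' must be 3 nonnegative totals")
           if (any(object@singlet < 0) || any(object@pair < 0))
             return("counts must be nonnegative")
           if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
             return("'pseudocount' must be a positive scalar")
           TRUE
         })

setMethod("show", "TrainingCounts", function(object) {
  cat("TrainingCounts over", sum(object@nState), "residue positions\n")
  cat("  per state:",
      paste(sprintf("%s=%d", .STATES, as.integer(object@nState)),
            collapse = " "), "\n")
  cat("  pseudocount:", object@pseudocount, "\n")
})

#' @rdname TrainingCounts-class
#' @param x A `TrainingCounts`.
#' @return `stateTotals` returns the named per-state position totals.
#' @export
stateTotals <- function(x) {
  stopifnot(is(x, "TrainingCounts"))
  setNames(x@nState, .STATES)
}

# Matrix of all 17-residue windows of a coded sequence, one row per
# position, out-of-range positions reading as the boundary code.
.windowMatrix <- function(codes) {
  n <- length(codes)
  padded <- c(rep(.XCODE, .HALF), codes, rep(.XCODE, .HALF))
  matrix(padded[outer(seq_len(n), 0:(.WINDOW - 1L), `+`)], nrow = n)
}

#' Accumulate training counts from a database
#'
#' For every residue position `t` with state `s`, the 17-residue window
#' centered at `t` (positions outside the sequence read as `X`)
#' contributes 17 singlet increments and 136 pair increments to state
#' `s`'s counts.
#'
#' @param db List of training records, as from [readTrainingDb()] or
#'   [generateDataset()].
#' @param pseudocount Positive smoothing constant stored with the counts.
#' @return A [TrainingCounts-class] object.
#' @export
accumulateCounts <- function(db, pseudocount = 1) {
  if (length(db) == 0L)
    stop("empty training database", call. = FALSE)
  if (pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  W <- do.call(rbind, lapply(db, function(rec) {
    .windowMatrix(residueCodes(rec$sequence))
  }))
  states <- unlist(lapply(db, function(rec) {
    .checkStates(rec$structure, n = length(rec$sequence),
                 what = sprintf("record '%s'", seqId(rec$sequence)))
  }), use.names = FALSE)
  singlet <- array(0, dim = c(3L, .WINDOW, .NRES))
  pair <- array(0, dim = c(3L, .NPAIRS, .NRES, .NRES))
  nState <- numeric(3L)
  for (s in 1:3) {
    rows <- which(states == .STATES[s])
    nState[s] <- length(rows)
    if (!length(rows)) next
    Ws <- W[rows, , drop = FALSE]
    for (m in seq_len(.WINDOW))
      singlet[s, m, ] <- tabulate(Ws[, m] + 1L, nbins = .NRES)
    for (p in seq_len(.NPAIRS)) {
      r1 <- Ws[, .PAIRS[p, 1L] + 1L]
      r2 <- Ws[, .PAIRS[p, 2L] + 1L]
      pair[s, p, , ] <- tabulate(r1 + .NRES * r2 + 1L,
                                 nbins = .NRES * .NRES)
    }
  }
  new("TrainingCounts", singlet = singlet, pair = pair,
      nState = setNames(nState, .STATES), pseudocount = pseudocount)
}
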