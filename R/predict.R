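# Combination weights for the window information sum.  The pairwise and
# directional terms are combined as
#   I_s = (2/17) * sum over the 136 unordered pairs
#       - (15/17) * sum over the 17 singlet terms.
# The coefficients are fixed by a consistency condition: if every pair
# term degenerates to the sum of its two singlet terms, each singlet
# appears in 16 pairs, so (2/17)*16 - 15/17 = 17/17 and the whole
# expression collapses to the plain singlet sum.
.PAIR_W <- 2 / 17
.DIR_W <- 15 / 17

#' Lookup instrumentation counters
#'
#' A mutable counter set recording how many parameter-table addresses a
#' prediction run touched.  One "read" is one table address returning
#' the packed 3-state value vector.  The streaming engine enumerates
#' ordered position pairs, so it performs exactly `272 * N` pair-table
#' reads and `17 * N` directional reads for a sequence of length `N`.
#'
#' @param stats A stats object from `newLookupStats()`.
#' @return `newLookupStats()` returns a fresh counter set;
#'   `lookupStats()` a named list with `pair_reads`, `dir_reads`, and
#'   `residues_processed`.
#' @export
newLookupStats <- function() {
  env <- new.env(parent = emptyenv())
  env$pair_reads <- 0
  env$dir_reads <- 0
  env$residues_processed <- 0
  class(env) <- "LookupStats"
  env
}

#' @rdname newLookupStats
#' @export
lookupStats <- function(stats) {
  stopifnot(inherits(stats, "LookupStats"))
  list(pair_reads = stats$pair_reads,
       dir_reads = stats$dir_reads,
       residues_processed = stats$residues_processed)
}

#' @export
print.LookupStats <- function(x, ...) {
  cat(sprintf("LookupStats: %g pair reads, %g dir reads, %g residues\n",
              x$pair_reads, x$dir_reads, x$residues_processed))
  invisible(x)
}

#' Extract the 17-residue window at a position
#'
#' The window holds the target residue at center index 8 with its eight
#' nearest neighbors on each side; positions beyond either end of the
#' sequence read as the boundary code 20 (`X`).
#'
#' @param seq A [ProteinSequence-class].
#' @param t Target position, 0-based.
#' @return Integer vector of 17 residue codes.
#' @export
extractWindow <- function(seq, t) {
  stopifnot(is(seq, "ProteinSequence"))
  n <- length(seq)
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 0L || t >= n)
    stop(sprintf("position %s out of range 0..%d", t, n - 1L), call. = FALSE)
  pos <- (t - .HALF) + 0:(.WINDOW - 1L)
  codes <- rep(.XCODE, .WINDOW)
  ok <- pos >= 0L & pos < n
  codes[ok] <- residueCodes(seq)[pos[ok] + 1L]
  codes
}

#' Window information sum for one state
#'
#' Reference (naive) evaluation of the per-state information score of a
#' window: `(2/17)` times the sum of the 136 pairwise terms minus
#' `(15/17)` times the sum of the 17 directional terms, in nats.
#'
#' @param window Integer vector of 17 residue codes (see
#'   [extractWindow()]).
#' @param tables An [InformationTables-class] object.
#' @param state One of `"H"`, `"E"`, `"C"`.
#' @return The information sum (a single number).
#' @export
informationSum <- function(window, tables, state) {
  stopifnot(is(tables, "InformationTables"))
  window <- as.integer(window)
  if (length(window) != .WINDOW || any(window < 0L | window >= .NRES))
    stop("window must hold 17 residue codes in 0..20", call. = FALSE)
  s <- match(match.arg(state, .STATES), .STATES)
  v <- .tableValues(tables)
  dirSum <- sum(v$dir[cbind(s, seq_len(.WINDOW), window + 1L)])
  pairSum <- sum(v$pair[cbind(s, seq_len(.NPAIRS),
                              window[.PAIRS[, 1L] + 1L] + 1L,
                              window[.PAIRS[, 2L] + 1L] + 1L)])
  .PAIR_W * pairSum - .DIR_W * dirSum
}

#' Normalize three information sums to state probabilities
#'
#' Exponential (softmax) normalization with a max-shift for overflow
#' safety: `p_s = exp(I_s - max I) / sum_t exp(I_t - max I)`.  The
#' result is invariant under adding a common constant to all three
#' inputs.
#'
#' @param iH,iE,iC Finite information sums, in nats.
#' @return Named numeric vector `(H, E, C)` summing to 1.
#' @examples
#' normalizeInformation(log(2), 0, 0)  # 0.50 0.25 0.25
#' @export
normalizeInformation <- function(iH, iE, iC) {
  x <- c(H = iH, E = iE, C = iC)
  if (!all(is.finite(x)))
    stop("information sums must be finite", call. = FALSE)
  e <- exp(x - max(x))
  e / sum(e)
}

#' Select the predicted state
#'
#' Argmax over the three probabilities; exact ties are broken by the
#' fixed priority H > E > C.
#'
#' @param p Numeric vector of three probabilities in H, E, C order.
#' @return One of `"H"`, `"E"`, `"C"`.
#' @export
selectState <- function(p) {
  stopifnot(length(p) == 3L, all(is.finite(p)))
  .STATES[which.max(p)]
}

# Row-wise softmax of an n x 3 score matrix.
.softmaxRows <- function(I) {
  m <- do.call(pmax, as.data.frame(I))
  e <- exp(I - m)
  p <- e / rowSums(e)
  colnames(p) <- .STATES
  p
}

#' Predict secondary structure for one sequence
#'
#' The prediction stage: for every residue the 17-residue window is
#' scored against the three states' information tables, the three sums
#' are normalized to probabilities, and the largest is selected (ties
#' H > E > C).
#'
#' The default `"streaming"` engine mirrors a table-bank lookup unit: it
#' enumerates *ordered* window-position pairs `(j, k)`, `j != k`,
#' reading one packed pair-table entry per ordered pair with weight
#' `1/17` — algebraically equal to weight `2/17` over unordered pairs —
#' so it issues exactly `17 * 16 = 272` pair-table reads per residue.
#' The `"naive"` engine sums the 136 unordered pairs directly (136 reads
#' per residue); both engines return identical probabilities up to
#' floating-point ordering (within 1e-12).
#'
#' @param seq A [ProteinSequence-class].
#' @param tables An [InformationTables-class] (double precision or
#'   quantized; quantized entries are used at value `int / scale`).
#' @param stats Optional [newLookupStats()] counter set to increment.
#' @param engine `"streaming"` (default) or `"naive"`.
#' @return A list with `states` (character vector over H/E/C) and
#'   `probs` (n x 3 matrix, columns `H`, `E`, `C`, rows summing to 1).
#' @export
predictSequence <- function(seq, tables, stats = NULL,
                            engine = c("streaming", "naive")) {
  stopifnot(is(seq, "ProteinSequence"), is(tables, "InformationTables"))
  engine <- match.arg(engine)
  if (!is.null(stats) && !inherits(stats, "LookupStats"))
    stop("'stats' must come from newLookupStats()", call. = FALSE)
  n <- length(seq)
  v <- .tableValues(tables)
  W <- .windowMatrix(residueCodes(seq))  # n x 17, 0-based codes

  dirAcc <- matrix(0, n, 3L)
  dirv <- as.vector(v$dir)
  for (j in seq_len(.WINDOW)) {
    base <- 3 * ((j - 1L) + .WINDOW * W[, j])
    for (s in 1:3) dirAcc[, s] <- dirAcc[, s] + dirv[base + s]
    if (!is.null(stats)) stats$dir_reads <- stats$dir_reads + n
  }

  pairAcc <- matrix(0, n, 3L)
  pairv <- as.vector(v$pair)
  if (engine == "streaming") {
    # ordered pairs (j, k), j != k: one packed read each, weight 1/17
    for (j in seq_len(.WINDOW)) {
      for (k in seq_len(.WINDOW)) {
        if (j == k) next
        p <- pairIndex(min(j, k) - 1L, max(j, k) - 1L)
        r1 <- W[, min(j, k)]
        r2 <- W[, max(j, k)]
        base <- 3 * (p + .NPAIRS * (r1 + .NRES * r2))
        for (s in 1:3) pairAcc[, s] <- pairAcc[, s] + pairv[base + s]
        if (!is.null(stats)) stats$pair_reads <- stats$pair_reads + n
      }
    }
    I <- (.PAIR_W / 2) * pairAcc - .DIR_W * dirAcc
  } else {
    for (p in seq_len(.NPAIRS)) {
      r1 <- W[, .PAIRS[p, 1L] + 1L]
      r2 <- W[, .PAIRS[p, 2L] + 1L]
      base <- 3 * ((p - 1L) + .NPAIRS * (r1 + .NRES * r2))
      for (s in 1:3) pairAcc[, s] <- pairAcc[, s] + pairv[base + s]
      if (!is.null(stats)) stats$pair_reads <- stats$pair_reads + n
    }
    I <- .PAIR_W * pairAcc - .DIR_W * dirAcc
  }

  if (!is.null(stats))
    stats$residues_processed <- stats$residues_processed + n
  probs <- .softmaxRows(I)
  states <- .STATES[max.col(probs, ties.method = "first")]
  list(states = states, probs = probs)
}
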