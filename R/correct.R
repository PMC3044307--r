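#' Correction-pass configuration
#'
#' Minimum run lengths enforced by the two scanning correction passes.
#' An alpha-helix turn spans about four residues, so helix runs shorter
#' than `minHelixRun` (default 4) are physically implausible; strand
#' runs shorter than `minStrandRun` (default 2) likewise.
#'
#' @param minHelixRun Minimum length of a surviving helix run (>= 1).
#' @param minStrandRun Minimum length of a surviving strand run (>= 1).
#' @return A list of class `CorrectionConfig`.
#' @export
correctionConfig <- function(minHelixRun = 4L, minStrandRun = 2L) {
  minHelixRun <- as.integer(minHelixRun)
  minStrandRun <- as.integer(minStrandRun)
  if (is.na(minHelixRun) || minHelixRun < 1L ||
      is.na(minStrandRun) || minStrandRun < 1L)
    stop("minimum run lengths must be integers >= 1", call. = FALSE)
  structure(list(minHelixRun = minHelixRun, minStrandRun = minStrandRun),
            class = "CorrectionConfig")
}

# Start indices and lengths of maximal runs of `value` in `states`.
.runsOf <- function(states, value) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  keep <- r$values == value
  list(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

#' First correction pass: dissolve short helix runs
#'
#' Every maximal `H` run shorter than `minHelixRun` is dissolved: each
#' residue in it is reassigned to whichever of `E` or `C` has the higher
#' predicted probability at that residue (ties go to `C`).  All other
#' residues are unchanged; this pass never creates an `H`.
#'
#' @param states Character vector over `H`/`E`/`C`.
#' @param probs n x 3 probability matrix (columns `H`, `E`, `C`).
#' @param cfg A [correctionConfig()].
#' @return The corrected state vector.
#' @export
correctionPass1 <- function(states, probs, cfg = correctionConfig()) {
  states <- .checkStates(states)
  probs <- as.matrix(probs)
  if (nrow(probs) != length(states) || ncol(probs) != 3L)
    stop(sprintf("length mismatch: %d states but %d probability rows",
                 length(states), nrow(probs)), call. = FALSE)
  runs <- .runsOf(states, "H")
  short <- which(runs$length < cfg$minHelixRun)
  for (i in short) {
    idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
    states[idx] <- ifelse(probs[idx, 2L] > probs[idx, 3L], "E", "C")
  }
  states
}

#' Second correction pass: remove short strand runs
#'
#' Every maximal `E` run shorter than `minStrandRun` is reassigned to
#' `C`; `H` and `C` residues are unchanged.
#'
#' @inheritParams correctionPass1
#' @return The corrected state vector.
#' @export
correctionPass2 <- function(states, cfg = correctionConfig()) {
  states <- .checkStates(states)
  runs <- .runsOf(states, "E")
  short <- which(runs$length < cfg$minStrandRun)
  for (i in short) {
    idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
    states[idx] <- "C"
  }
  states
}

#' Apply both correction passes
#'
#' `correctionPass2(correctionPass1(states, probs), cfg)`.  Pass 1 never
#' creates an `H` and pass 2 never creates an `H` or `E`, so the
#' composite is idempotent: applying it twice equals applying it once.
#'
#' @inheritParams correctionPass1
#' @return The corrected state vector.
#' @export
applyCorrections <- function(states, probs, cfg = correctionConfig()) {
  correctionPass2(correctionPass1(states, probs, cfg), cfg)
}
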