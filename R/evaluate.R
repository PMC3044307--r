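#' Three-state prediction accuracy (Q3)
#'
#' Percentage of residues whose predicted state matches the reference.
#'
#' @param pred,truth Character vectors over `H`/`E`/`C` of equal length.
#' @return Q3 in `[0, 100]`.
#' @examples
#' q3(c("H", "C"), c("H", "H"))  # 50
#' @export
q3 <- function(pred, truth) {
  pred <- .checkStates(pred, what = "prediction")
  truth <- .checkStates(truth, what = "reference")
  if (length(pred) != length(truth))
    stop(sprintf("length mismatch: %d predicted vs %d reference states",
                 length(pred), length(truth)), call. = FALSE)
  100 * mean(pred == truth)
}

#' Three-state confusion matrix
#'
#' Counts indexed `[true state, predicted state]`; row sums are the
#' per-state reference counts and the total equals the number of
#' residues, so `q3` equals `100 * trace / total`.
#'
#' @inheritParams q3
#' @return A 3 x 3 integer matrix with dimnames `truth` x `pred`.
#' @export
confusionMatrix <- function(pred, truth) {
  pred <- .checkStates(pred, what = "prediction")
  truth <- .checkStates(truth, what = "reference")
  if (length(pred) != length(truth))
    stop(sprintf("length mismatch: %d predicted vs %d reference states",
                 length(pred), length(truth)), call. = FALSE)
  table(truth = factor(truth, levels = .STATES),
        pred = factor(pred, levels = .STATES))
}

#' Dataset-level Q3 over matched records
#'
#' Pools residues over all records (residue-weighted Q3) after matching
#' predictions to reference records by id.
#'
#' @param predictions List of prediction blocks (elements with `id` and
#'   `states`), e.g. from [readPrediction()] or [runPipeline()] results.
#' @param truth List of training records (see [readTrainingDb()]).
#' @return A list with `q3`, `nResidues`, `confusion`, and
#'   `majorityRate` (the percentage of the most common reference state —
#'   the accuracy of always guessing the majority).
#' @export
datasetQ3 <- function(predictions, truth) {
  truthIds <- vapply(truth, function(rec) seqId(rec$sequence), character(1L))
  predIds <- vapply(predictions, function(p) p$id, character(1L))
  missing <- setdiff(predIds, truthIds)
  if (length(missing))
    stop(sprintf("prediction id '%s' has no reference record", missing[1L]),
         call. = FALSE)
  if (length(predictions) == 0L)
    stop("no predictions to evaluate", call. = FALSE)
  predAll <- unlist(lapply(predictions, `[[`, "states"), use.names = FALSE)
  truthAll <- unlist(lapply(predictions, function(p) {
    rec <- truth[[match(p$id, truthIds)]]
    if (length(rec$structure) != length(p$states))
      stop(sprintf("length mismatch for id '%s'", p$id), call. = FALSE)
    rec$structure
  }), use.names = FALSE)
  cm <- confusionMatrix(predAll, truthAll)
  list(q3 = q3(predAll, truthAll),
       nResidues = length(predAll),
       confusion = cm,
       majorityRate = 100 * max(rowSums(cm)) / sum(cm))
}
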