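#' Pipeline configuration
#'
#' Topology knobs for the three-stage prediction pipeline: one
#' prediction engine feeding `nChannels` parallel correction channels
#' through a bounded buffer.
#'
#' @param nChannels Number of parallel correction channels (>= 1,
#'   default 2).
#' @param bufferCapacity Sequences the inter-stage buffer can hold
#'   (>= 1, default 4).
#' @param outputOrder `"fcfs"` (first-come-first-served: results ordered
#'   by completion) or `"input_order"` (results reordered to match the
#'   input, giving byte-identical output files for any channel count).
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nChannels = 2L, bufferCapacity = 4L,
                           outputOrder = c("fcfs", "input_order")) {
  nChannels <- as.integer(nChannels)
  bufferCapacity <- as.integer(bufferCapacity)
  outputOrder <- match.arg(outputOrder)
  if (is.na(nChannels) || nChannels < 1L)
    stop("nChannels must be an integer >= 1", call. = FALSE)
  if (is.na(bufferCapacity) || bufferCapacity < 1L)
    stop("bufferCapacity must be an integer >= 1", call. = FALSE)
  structure(list(nChannels = nChannels, bufferCapacity = bufferCapacity,
                 outputOrder = outputOrder),
            class = "PipelineConfig")
}

# Deterministic discrete-event schedule of the three-stage pipeline.
# Stage costs are proportional to sequence length (the prediction
# overhead for a length-N sequence is fixed; the serial correction scan
# touches each residue once per pass).  Returns completion ordinals.
.scheduleOrdinals <- function(lengths, cfg) {
  n <- length(lengths)
  predCost <- lengths
  corrCost <- 2 * lengths
  channelFree <- numeric(cfg$nChannels)
  enterBuffer <- numeric(n)   # time sequence i is placed in the buffer
  pickup <- numeric(n)        # time a channel takes it out
  finish <- numeric(n)
  predDone <- 0
  for (i in seq_len(n)) {
    # stage 1 runs sequences in input order; it stalls until the buffer
    # slot occupied by sequence i - bufferCapacity has been vacated
    ready <- predDone + predCost[i]
    if (i > cfg$bufferCapacity)
      ready <- max(ready, pickup[i - cfg$bufferCapacity])
    enterBuffer[i] <- ready
    predDone <- ready
    # first-free channel takes the oldest buffered sequence
    c <- which.min(channelFree)
    pickup[i] <- max(enterBuffer[i], channelFree[c])
    finish[i] <- pickup[i] + corrCost[i]
    channelFree[c] <- finish[i]
  }
  order(order(finish, seq_len(n)))  # completion rank, ties by input order
}

#' Run the three-stage prediction pipeline
#'
#' Runs prediction, correction pass 1, and correction pass 2 over a
#' batch of sequences as a data-driven pipeline: one prediction engine
#' feeds `cfg$nChannels` parallel correction channels through a bounded
#' buffer, and finished sequences are written back either
#' first-come-first-served or reordered to input order.  The schedule is
#' a deterministic discrete-event simulation; the result *contents* are
#' identical to the serial path ([predictSequence()] then
#' [applyCorrections()] per sequence) for every channel count and buffer
#' size — only the completion ordinals and, under `"fcfs"`, the result
#' order depend on the topology.
#'
#' @param seqs List of [ProteinSequence-class] objects with distinct
#'   ids.
#' @param tables An [InformationTables-class] object.
#' @param cfg A [pipelineConfig()].
#' @param ccfg A [correctionConfig()].
#' @param stats Optional [newLookupStats()] counter set.
#' @return A list with:
#'   \describe{
#'     \item{results}{One element per sequence: `id`, final `states`,
#'       `probs`, and the completion `ordinal`.}
#'     \item{stats}{The lookup counters (also updated in place when
#'       passed in).}
#'     \item{stageStats}{Named counts of sequences processed by each
#'       stage.}
#'   }
#' @export
runPipeline <- function(seqs, tables, cfg = pipelineConfig(),
                        ccfg = correctionConfig(), stats = newLookupStats()) {
  if (length(seqs) == 0L)
    stop("no input sequences", call. = FALSE)
  stopifnot(all(vapply(seqs, is, logical(1L), "ProteinSequence")),
            is(tables, "InformationTables"),
            inherits(cfg, "PipelineConfig"),
            inherits(ccfg, "CorrectionConfig"))
  ids <- vapply(seqs, seqId, character(1L))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s'", ids[anyDuplicated(ids)]),
         call. = FALSE)
  lengths <- vapply(seqs, length, integer(1L))
  ordinals <- .scheduleOrdinals(lengths, cfg)
  results <- lapply(seq_along(seqs), function(i) {
    pred <- predictSequence(seqs[[i]], tables, stats = stats)
    states <- applyCorrections(pred$states, pred$probs, ccfg)
    list(id = ids[i], states = states, probs = pred$probs,
         ordinal = ordinals[i])
  })
  if (cfg$outputOrder == "fcfs")
    results <- results[order(ordinals)]
  list(results = results,
       stats = stats,
       stageStats = c(predicted = length(seqs),
                      corrected1 = length(seqs),
                      corrected2 = length(seqs)))
}

#' Write pipeline results as a prediction file
#'
#' Concatenates one [writePrediction()] block per result, in the order
#' the pipeline delivered them.
#'
#' @param pipelineOut The list returned by [runPipeline()].
#' @param seqs The input sequences (for the residue letters).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(pipelineOut, seqs, path) {
  ids <- vapply(seqs, seqId, character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  for (res in pipelineOut$results) {
    i <- match(res$id, ids)
    if (is.na(i))
      stop(sprintf("result id '%s' not among the input sequences", res$id),
           call. = FALSE)
    writePrediction(seqs[[i]], res$states, res$probs, con)
  }
  invisible(path)
}
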