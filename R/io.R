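#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; record
#' identifiers are truncated at the first whitespace and every record is
#' checked to be non-empty.  Multi-line sequences are concatenated and
#' record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [ProteinSequence-class] objects.
#' @export
readFasta <- function(path) {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: '%s'", path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L)
    stop(sprintf("no FASTA records in '%s'", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop(sprintf("empty sequence in FASTA record '%s'",
                 ids[which(widths == 0L)[1L]]), call. = FALSE)
  seqs <- as.character(set)
  lapply(seq_along(seqs), function(i) encodeSequence(seqs[[i]], id = ids[[i]]))
}

#' Read a training database of sequence/structure pairs
#'
#' The training database is a plain-text format of three-line records:
#' a `">id"` header, the amino-acid sequence, and a structure line of the
#' same length over `H`/`E`/`C`.  Blank lines are ignored.  This is the
#' training-side stand-in for a database of sequences with experimentally
#' known secondary structure.
#'
#' @param path Path to the training database.
#' @return A list of training records, each a list with elements
#'   `sequence` (a [ProteinSequence-class]) and `structure` (a character
#'   vector over `H`/`E`/`C` of equal length).
#' @seealso [writeTrainingDb()]
#' @export
readTrainingDb <- function(path) {
  if (!file.exists(path))
    stop(sprintf("training database not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop(sprintf("empty training database '%s'", path), call. = FALSE)
  if (length(lines) %% 3L != 0L || !all(startsWith(lines[c(TRUE, FALSE, FALSE)], ">")))
    stop("malformed training database: expected records of exactly 3 lines (>id, sequence, structure)",
         call. = FALSE)
  n <- length(lines) %/% 3L
  lapply(seq_len(n), function(i) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[3L * i - 2L]))
    seq <- encodeSequence(lines[3L * i - 1L], id = id)
    st <- strsplit(lines[3L * i], "", fixed = TRUE)[[1L]]
    st <- .checkStates(st, n = length(seq),
                       what = sprintf("record '%s'", id))
    list(sequence = seq, structure = st)
  })
}

#' Write a training database
#'
#' Inverse of [readTrainingDb()]: emits three-line `>id` / sequence /
#' structure records.
#'
#' @param records A list of training records (see [readTrainingDb()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrainingDb <- function(records, path) {
  stopifnot(length(records) >= 1L)
  lines <- unlist(lapply(records, function(rec) {
    st <- .checkStates(rec$structure, n = length(rec$sequence),
                       what = sprintf("record '%s'", seqId(rec$sequence)))
    c(paste0(">", seqId(rec$sequence)),
      decodeSequence(rec$sequence),
      paste(st, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-residue prediction block
#'
#' Emits a `"# <id>"` header followed by one line per residue with the
#' 1-based position, residue letter, predicted state, and the three state
#' probabilities `pH pE pC` to 4 decimal places, whitespace-separated.
#'
#' @param seq A [ProteinSequence-class].
#' @param states Character vector of predicted states over `H`/`E`/`C`.
#' @param probs Numeric matrix with one row per residue and columns
#'   `H`, `E`, `C`.
#' @param con Output connection or path; an open connection is written to
#'   in place (so blocks for several sequences can be concatenated).
#' @return Invisibly, the character vector of lines written.
#' @export
writePrediction <- function(seq, states, probs, con) {
  stopifnot(is(seq, "ProteinSequence"))
  n <- length(seq)
  states <- .checkStates(states, n = n,
                         what = sprintf("prediction for '%s'", seqId(seq)))
  probs <- as.matrix(probs)
  if (nrow(probs) != n || ncol(probs) != 3L)
    stop(sprintf("length mismatch in prediction for '%s': %d probability rows for %d residues",
                 seqId(seq), nrow(probs), n), call. = FALSE)
  letters <- .ALPHABET[residueCodes(seq) + 1L]
  lines <- c(paste0("# ", seqId(seq)),
             sprintf("%d %s %s %.4f %.4f %.4f",
                     seq_len(n), letters, states,
                     probs[, 1L], probs[, 2L], probs[, 3L]))
  if (inherits(con, "connection")) writeLines(lines, con)
  else writeLines(lines, con)
  invisible(lines)
}

#' Read back a prediction file
#'
#' Parses the format written by [writePrediction()].
#'
#' @param path Path to a prediction file (one or more blocks).
#' @return A list with one element per block: `id`, `residues` (letters),
#'   `states`, and `probs` (n x 3 matrix, columns `H`, `E`, `C`).
#' @export
readPrediction <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- startsWith(lines, "# ")
  if (!any(hdr) || !hdr[1L])
    stop(sprintf("malformed prediction file '%s': expected '# <id>' header", path),
         call. = FALSE)
  block <- cumsum(hdr)
  lapply(split(lines, block), function(chunk) {
    id <- sub("^# ", "", chunk[1L])
    if (length(chunk) < 2L)
      stop(sprintf("empty prediction block '%s'", id), call. = FALSE)
    fields <- do.call(rbind, strsplit(trimws(chunk[-1L]), "[[:space:]]+"))
    probs <- matrix(as.numeric(fields[, 4:6, drop = FALSE]), ncol = 3L,
                    dimnames = list(NULL, .STATES))
    list(id = id,
         residues = fields[, 2L],
         states = .checkStates(fields[, 3L], what = sprintf("block '%s'", id)),
         probs = probs)
  })
}
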