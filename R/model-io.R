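# Binary model format ".gor4" (little-endian):
#   bytes 0-7   magic "GOR4MDL\1"
#   int32       format version (currently 1)
#   int32 x3    window width (17), alphabet size (21), pair count (136)
#   int32       quantized flag (0/1)
#   float64     quantization scale (0 when not quantized)
#   values      dir then pair, state-major (state slowest, then window
#               offset / pair index, then residue codes with the later
#               position's code fastest); float64, or int32 if quantized.

.MODEL_MAGIC <- as.raw(c(0x47, 0x4f, 0x52, 0x34, 0x4d, 0x44, 0x4c, 0x01))
.MODEL_VERSION <- 1L

# value order: residue codes fastest, state slowest
.flattenDir <- function(a) as.vector(aperm(a, c(3L, 2L, 1L)))
.flattenPair <- function(a) as.vector(aperm(a, c(4L, 3L, 2L, 1L)))
.unflattenDir <- function(v) aperm(array(v, dim = c(.NRES, .WINDOW, 3L)), c(3L, 2L, 1L))
.unflattenPair <- function(v) aperm(array(v, dim = c(.NRES, .NRES, .NPAIRS, 3L)), c(4L, 3L, 2L, 1L))

#' Save and load the binary model file
#'
#' `saveModel` writes an [InformationTables-class] object to the
#' little-endian binary `.gor4` format; `loadModel` reads it back.  The
#' round trip is bit-exact for both double-precision and quantized
#' models.
#'
#' @param tables An [InformationTables-class] object.
#' @param path File path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   [InformationTables-class] object.
#' @export
saveModel <- function(tables, path) {
  stopifnot(is(tables, "InformationTables"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.MODEL_MAGIC, con)
  writeBin(c(.MODEL_VERSION, .WINDOW, .NRES, .NPAIRS,
             as.integer(tables@quantized)),
           con, size = 4L, endian = "little")
  writeBin(if (tables@quantized) tables@scale else 0, con,
           size = 8L, endian = "little")
  values <- c(.flattenDir(tables@dir), .flattenPair(tables@pair))
  if (tables@quantized)
    writeBin(as.integer(values), con, size = 4L, endian = "little")
  else
    writeBin(as.numeric(values), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) < 8L || !identical(magic, .MODEL_MAGIC))
    stop(sprintf("'%s' is not a model file (bad magic)", path), call. = FALSE)
  hdr <- readBin(con, "integer", n = 5L, size = 4L, endian = "little")
  if (length(hdr) < 5L)
    stop("unexpected end of model file", call. = FALSE)
  if (hdr[1L] != .MODEL_VERSION)
    stop(sprintf("model format version %d not supported (this reader expects version %d)",
                 hdr[1L], .MODEL_VERSION), call. = FALSE)
  if (!identical(hdr[2:4], c(.WINDOW, .NRES, .NPAIRS)))
    stop(sprintf("unexpected table shape in model file: window %d, alphabet %d, pairs %d",
                 hdr[2L], hdr[3L], hdr[4L]), call. = FALSE)
  quantized <- hdr[5L] == 1L
  scale <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
  if (length(scale) < 1L)
    stop("unexpected end of model file", call. = FALSE)
  nDir <- 3L * .WINDOW * .NRES
  nPair <- 3L * .NPAIRS * .NRES * .NRES
  values <- if (quantized)
    readBin(con, "integer", n = nDir + nPair, size = 4L, endian = "little")
  else
    readBin(con, "numeric", n = nDir + nPair, size = 8L, endian = "little")
  if (length(values) < nDir + nPair)
    stop("unexpected end of model file", call. = FALSE)
  new("InformationTables",
      dir = .unflattenDir(values[seq_len(nDir)]),
      pair = .unflattenPair(values[nDir + seq_len(nPair)]),
      quantized = quantized,
      scale = if (quantized) scale else NA_real_)
}
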