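# Residue alphabet: the 20 canonical amino acids in alphabetical order
# (codes 0..19) followed by 'X' (code 20), which stands for any
# non-canonical letter and for window positions beyond the sequence ends.
# All codes fit in 5 bits, matching a 5-bit binary sequence encoding.
.ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
               "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
.XCODE <- 20L
.NRES <- 21L
.STATES <- c("H", "E", "C")

#' The 21-symbol residue alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order (codes
#' 0 to 19) plus the boundary/unknown symbol `"X"` (code 20).  The code of
#' a symbol is its zero-based position in this vector.
#'
#' @return A character vector of 21 single letters.
#' @examples
#' residueAlphabet()
#' @export
residueAlphabet <- function() .ALPHABET

#' The three secondary-structure states
#'
#' @return `c("H", "E", "C")`: helix, extended (beta strand), coil.
#' @export
structureStates <- function() .STATES

#' An encoded protein sequence
#'
#' Holds a record identifier and the residue codes (integers 0..20) of a
#' protein sequence under the 21-symbol alphabet of [residueAlphabet()].
#'
#' @slot id Record identifier.
#' @slot codes Integer vector of residue codes, each in 0..20.
#' @seealso [encodeSequence()], [decodeSequence()]
#' @export
setClass("ProteinSequence",
         representation(id = "character", codes = "integer"),
         validity = function(object) {
           if (length(object@id) != 1L)
             return("'id' must be a single string")
           if (length(object@codes) < 1L)
             return("a ProteinSequence must contain at least one residue")
           if (anyNA(object@codes) ||
               any(object@codes < 0L | object@codes >= .NRES))
             return("residue codes must lie in 0..20")
           TRUE
         })

#' @describeIn ProteinSequence Number of residues.
#' @param x A `ProteinSequence`.
#' @export
setMethod("length", "ProteinSequence", function(x) length(x@codes))

setMethod("show", "ProteinSequence", function(object) {
  n <- length(object@codes)
  prev <- paste(.ALPHABET[utils::head(object@codes, 40L) + 1L], collapse = "")
  if (n > 40L) prev <- paste0(prev, "...")
  cat(sprintf("ProteinSequence '%s': %d residues\n  %s\n",
              object@id, n, prev))
})

#' @rdname ProteinSequence
#' @param x A `ProteinSequence`.
#' @return `seqId` returns the record identifier; `residueCodes` the
#'   zero-based integer codes.
#' @export
seqId <- function(x) {
  stopifnot(is(x, "ProteinSequence"))
  x@id
}

#' @rdname ProteinSequence
#' @export
residueCodes <- function(x) {
  stopifnot(is(x, "ProteinSequence"))
  x@codes
}

#' Encode a raw amino-acid string
#'
#' Uppercases the input, removes whitespace, and maps each letter to its
#' residue code: the 20 canonical amino acids map to 0..19 in alphabetical
#' order (`A` = 0, `C` = 1, ..., `Y` = 19); any other letter (`B`, `J`,
#' `O`, `U`, `Z`, `X` and other ambiguity codes) maps to the unknown code
#' 20.  Non-letter characters are rejected.
#'
#' @param raw A character string of amino-acid letters.
#' @param id Record identifier to attach (default `""`).
#' @return A [ProteinSequence-class] object.
#' @examples
#' residueCodes(encodeSequence("ACDY"))  # 0 1 2 19
#' @export
encodeSequence <- function(raw, id = "") {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- gsub("[[:space:]]", "", raw)
  if (!nzchar(raw))
    stop("empty sequence", call. = FALSE)
  chars <- strsplit(toupper(raw), "", fixed = TRUE)[[1L]]
  bad <- grep("[^A-Z]", chars)
  if (length(bad))
    stop(sprintf("non-letter character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  codes <- match(chars, .ALPHABET[1:20]) - 1L
  codes[is.na(codes)] <- .XCODE
  new("ProteinSequence", id = as.character(id), codes = codes)
}

#' Decode a protein sequence back to letters
#'
#' Inverse of [encodeSequence()] on strings over the 21-symbol alphabet.
#'
#' @param x A [ProteinSequence-class] or an integer vector of codes.
#' @return A single character string.
#' @export
decodeSequence <- function(x) {
  codes <- if (is(x, "ProteinSequence")) x@codes else as.integer(x)
  stopifnot(all(codes >= 0L & codes < .NRES))
  paste(.ALPHABET[codes + 1L], collapse = "")
}

# Validate a vector of structure states; returns it as character.
.checkStates <- function(states, n = NULL, what = "structure") {
  states <- as.character(states)
  bad <- which(!states %in% .STATES)
  if (length(bad))
    stop(sprintf("invalid state '%s' at position %d in %s",
                 states[bad[1L]], bad[1L], what), call. = FALSE)
  if (!is.null(n) && length(states) != n)
    stop(sprintf("length mismatch in %s: %d states for %d residues",
                 what, length(states), n), call. = FALSE)
  states
}
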