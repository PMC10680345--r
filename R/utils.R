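# Internal sequence helpers shared across modules.

IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "N",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors; IUPAC ambiguity letters are complemented per the
#' standard code.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Validate that a sequence only uses IUPAC DNA letters; error names the first
# offending position.
check_dna_alphabet <- function(sequence) {
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")),
                 toupper(sequence))
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d",
                 substr(sequence, bad, bad), bad), call. = FALSE)
  }
  invisible(TRUE)
}

# Circular substring: 1-based inclusive, end may be < start (wrap through the
# origin). Sequence assumed upper-case.
circular_substr <- function(sequence, start, end, wraps = FALSE) {
  n <- nchar(sequence)
  stopifnot(start >= 1L, start <= n, end >= 1L, end <= n)
  if (!wraps) {
    substr(sequence, start, end)
  } else {
    paste0(substr(sequence, start, n), substr(sequence, 1L, end))
  }
}

# Split a sequence into single characters.
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
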