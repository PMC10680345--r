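# FASTA I/O: thin wrappers over Biostrings, returning plain named character
# vectors (ids as names), case-folded to upper.

#' Read a FASTA file
#'
#' @param path FASTA file (any line width).
#' @return named character vector of upper-case sequences; empty file gives
#'   an empty vector. Duplicated ids raise a warning.
#' @export
read_fasta <- function(path) {
  if (file.size(path) %in% c(0L, NA)) return(stats::setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(), character()))
  ids <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicated FASTA ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param entries named character vector (names become FASTA ids).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, width = 70L) {
  stopifnot(!is.null(names(entries)) || length(entries) == 0L)
  set <- Biostrings::BStringSet(toupper(entries))
  names(set) <- names(entries)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
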