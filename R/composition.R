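# Nucleotide composition and strand-skew statistics.
#
# AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C), computed over
# unambiguous bases only. Skews are strand statistics: reverse-complementing
# a sequence negates both while leaving the A+T content unchanged.

#' Count bases in a sequence
#'
#' @param sequence nucleotide string over the IUPAC alphabet (U is counted
#'   with T; other ambiguity letters are tallied separately and excluded
#'   from composition denominators).
#' @return object of class `base_counts`: list with `a`, `c`, `g`, `t`,
#'   `ambiguous` and `total_unambiguous`.
#' @export
count_bases <- function(sequence) {
  sequence <- toupper(sequence)
  check_dna_alphabet(sequence)
  tab <- table(factor(seq_chars(chartr("U", "T", sequence)),
                      levels = IUPAC_LETTERS))
  out <- list(a = unname(tab[["A"]]), c = unname(tab[["C"]]),
              g = unname(tab[["G"]]), t = unname(tab[["T"]]))
  out$ambiguous <- nchar(sequence) - out$a - out$c - out$g - out$t
  out$total_unambiguous <- out$a + out$c + out$g + out$t
  structure(out, class = "base_counts")
}

#' A+T content as a percentage
#'
#' @param counts a [count_bases()] result (or any list with `a`,`c`,`g`,`t`).
#' @return `100 * (A + T) / (A + C + G + T)`; `NA` when no unambiguous base
#'   is present.
#' @export
at_content <- function(counts) {
  tot <- counts$a + counts$c + counts$g + counts$t
  if (tot == 0L) return(NA_real_)
  100 * (counts$a + counts$t) / tot
}

#' AT-skew: (A - T)/(A + T)
#' @inheritParams at_content
#' @return value in \[-1, 1\]; `NA` when A + T = 0.
#' @export
at_skew <- function(counts) {
  d <- counts$a + counts$t
  if (d == 0L) return(NA_real_)
  (counts$a - counts$t) / d
}

#' GC-skew: (G - C)/(G + C)
#' @inheritParams at_content
#' @return value in \[-1, 1\]; `NA` when G + C = 0.
#' @export
gc_skew <- function(counts) {
  d <- counts$g + counts$c
  if (d == 0L) return(NA_real_)
  (counts$g - counts$c) / d
}

#' A+T content at the three codon positions
#'
#' Pools complete codons across the supplied coding-sense sequences (each
#' read in frame from its first base; trailing incomplete codons are
#' dropped) and returns the A+T percentage at codon positions 1-3.
#'
#' @param pcg_sequences character vector of coding-sense PCG sequences.
#' @return named numeric `c(P1=, P2=, P3=)`; `NA`s on empty input.
#' @export
codon_position_composition <- function(pcg_sequences) {
  pcg_sequences <- pcg_sequences[nchar(pcg_sequences) >= 3L]
  if (length(pcg_sequences) == 0L) {
    return(c(P1 = NA_real_, P2 = NA_real_, P3 = NA_real_))
  }
  pos_seq <- function(p) {
    paste(vapply(pcg_sequences, function(s) {
      nc <- 3L * (nchar(s) %/% 3L)
      chars <- seq_chars(substr(s, 1L, nc))
      paste(chars[seq(p, nc, by = 3L)], collapse = "")
    }, character(1)), collapse = "")
  }
  out <- vapply(1:3, function(p) at_content(count_bases(pos_seq(p))),
                numeric(1))
  stats::setNames(out, c("P1", "P2", "P3"))
}

REGION_LEVELS <- c("whole", "PCGs", "rrnL", "rrnS", "tRNA", "CR")

# Concatenated sequence of a named region, coding-sense or plus-strand.
# Gene regions double-count overlapping nucleotides (each gene contributes
# its full span), matching how published region lengths sum per-gene
# lengths.
region_sequence <- function(genome, region, sense = c("coding", "plus")) {
  sense <- match.arg(sense)
  f <- switch(region,
    whole = NULL,
    PCGs = features_of_class(genome, "PCG"),
    rrnL = genome$features[genome$features$name == "rrnL", , drop = FALSE],
    rrnS = genome$features[genome$features$name == "rrnS", , drop = FALSE],
    tRNA = features_of_class(genome, "tRNA"),
    CR   = features_of_class(genome, "CR"),
    stop("unknown region: ", region))
  if (region == "whole") return(genome$sequence)
  if (is.null(f) || nrow(f) == 0L) return(NULL)
  paste(vapply(seq_len(nrow(f)), function(i) {
    ft <- f[i, ]
    if (sense == "plus") {
      circular_substr(genome$sequence, ft$start, ft$end, ft$wraps_origin)
    } else {
      extract_feature_sequence(genome, ft)
    }
  }, character(1)), collapse = "")
}

#' Per-region composition and skew summary
#'
#' One row per region (whole genome, all PCGs, rrnL, rrnS, all tRNAs, CR)
#' with length, A+T%, AT-skew and GC-skew. Published comparative tables mix
#' strand conventions, so three are available: `"coding"` computes every
#' gene region on its coding-sense concatenation; `"plus"` uses the
#' deposited plus strand throughout; the default `"report"` uses the plus
#' strand for the whole genome and CR and coding sense for the gene
#' classes.
#'
#' @param genome an annotated [mito_genome()].
#' @param convention `"report"`, `"coding"` or `"plus"` (see above).
#' @return data.frame with columns `region`, `length`, `at_percent`,
#'   `at_skew`, `gc_skew` (full precision; see [format_region_summary()]
#'   for table-style rounding). Absent regions are omitted with a warning.
#' @export
region_summary <- function(genome,
                           convention = c("report", "coding", "plus")) {
  convention <- match.arg(convention)
  rows <- lapply(REGION_LEVELS, function(region) {
    sense <- switch(convention,
      plus = "plus",
      coding = "coding",
      report = if (region %in% c("whole", "CR")) "plus" else "coding")
    s <- region_sequence(genome, region, sense)
    if (is.null(s)) return(NULL)
    cb <- count_bases(s)
    data.frame(region = region, length = nchar(s),
               at_percent = at_content(cb), at_skew = at_skew(cb),
               gc_skew = gc_skew(cb), stringsAsFactors = FALSE)
  })
  absent <- REGION_LEVELS[vapply(rows, is.null, logical(1))]
  if (length(absent)) {
    warning("region(s) absent from annotation: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a region summary for presentation
#'
#' Percentages to one decimal, skews to three, matching the precision of
#' published comparative composition tables.
#'
#' @param summary a [region_summary()] data.frame.
#' @return data.frame with rounded columns.
#' @export
format_region_summary <- function(summary) {
  summary$at_percent <- round(summary$at_percent, 1)
  summary$at_skew <- round(summary$at_skew, 3)
  summary$gc_skew <- round(summary$gc_skew, 3)
  summary
}
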