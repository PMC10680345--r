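# Codon-level analyses under the invertebrate mitochondrial genetic code
# (NCBI translation table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp; stops are
# TAA and TAG): codon extraction, start/stop classification including
# incomplete (polyadenylation-completed) stops, codon usage, RSCU and
# amino-acid frequencies.

AA1_TO_3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' The invertebrate mitochondrial genetic code
#'
#' NCBI translation table 5 as a named character vector (DNA codons to
#' one-letter amino acids, `*` for the stop codons TAA/TAG), sourced from
#' [Biostrings::getGeneticCode()].
#'
#' @return named character vector of length 64.
#' @export
invertebrate_mito_code <- function() {
  code <- Biostrings::getGeneticCode("5")
  stats::setNames(as.character(code), names(code))
}

MITO_STOPS <- c("TAA", "TAG")

#' Split a coding sequence into codons
#'
#' @param coding_sequence coding-sense nucleotide string.
#' @param codon_start reading-frame offset (1-3), as in GenBank
#'   `/codon_start`.
#' @return list with `codons` (character vector of triplets) and
#'   `incomplete_tail` (trailing 0-2 bases).
#' @export
extract_codons <- function(coding_sequence, codon_start = 1L) {
  coding_sequence <- toupper(coding_sequence)
  s <- substring(coding_sequence, codon_start)
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon after offset",
                   call. = FALSE)
  k <- n %/% 3L
  starts <- seq(1L, by = 3L, length.out = k)
  list(codons = substring(s, starts, starts + 2L),
       incomplete_tail = substring(s, 3L * k + 1L))
}

#' Classify start and stop codons of a protein-coding gene
#'
#' The start codon is the first triplet, flagged canonical iff it matches
#' `ATN`. The stop is the final complete codon when it is TAA/TAG;
#' otherwise a trailing incomplete codon of `T` or `TA` is reported as the
#' incomplete-stop marker `"T-"` / `"TA-"` (completed to TAA by
#' post-transcriptional polyadenylation). Anything else is flagged
#' `no_stop_found` rather than raising an error.
#'
#' @inheritParams extract_codons
#' @param gene gene label carried into the report.
#' @return one-row data.frame (`gene_codon_report`): `gene`, `length`,
#'   `start_codon`, `start_canonical`, `stop_codon`, `n_complete_codons`,
#'   `n_internal_stops`, `no_stop_found`.
#' @export
classify_start_stop <- function(coding_sequence, codon_start = 1L,
                                gene = NA_character_) {
  ec <- extract_codons(coding_sequence, codon_start)
  codons <- ec$codons
  tail <- ec$incomplete_tail
  start_codon <- codons[1]
  stop_codon <- NA_character_
  no_stop <- FALSE
  terminal_is_stop <- FALSE
  if (nzchar(tail)) {
    if (tail %in% c("T", "TA")) stop_codon <- paste0(tail, "-")
    else no_stop <- TRUE
  } else if (codons[length(codons)] %in% MITO_STOPS) {
    stop_codon <- codons[length(codons)]
    terminal_is_stop <- TRUE
  } else {
    no_stop <- TRUE
  }
  internal <- codons[-c(1L, if (terminal_is_stop) length(codons))]
  data.frame(gene = gene, length = nchar(coding_sequence),
             start_codon = start_codon,
             start_canonical = grepl("^AT[ACGT]$", start_codon),
             stop_codon = stop_codon,
             n_complete_codons = length(codons),
             n_internal_stops = sum(internal %in% MITO_STOPS),
             no_stop_found = no_stop, stringsAsFactors = FALSE)
}

#' Translate a coding sequence under the invertebrate mitochondrial code
#'
#' @param coding_sequence coding-sense nucleotide string of complete codons.
#' @param codon_start reading-frame offset (1-3).
#' @return amino-acid string (`*` for stops, `X` for ambiguity-containing
#'   codons).
#' @export
translate_mito <- function(coding_sequence, codon_start = 1L) {
  codons <- extract_codons(coding_sequence, codon_start)$codons
  code <- invertebrate_mito_code()
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Pooled codon usage over the annotated protein-coding genes
#'
#' Pools complete codons of all PCGs in coding sense (honouring each gene's
#' `codon_start`); the terminal complete stop codon of a gene and any
#' incomplete tail are excluded from the counts.
#'
#' @param genome an annotated [mito_genome()], or a character vector of
#'   coding-sense PCG sequences.
#' @return object of class `codon_profile`: list with `counts` (named
#'   64-vector), `family` (codon to amino acid), `rscu` (`NULL` until
#'   [rscu()] is applied) and `total_nonstop_codons`.
#' @export
codon_usage <- function(genome) {
  code <- invertebrate_mito_code()
  if (inherits(genome, "mito_genome")) {
    f <- features_of_class(genome, "PCG")
    missing <- setdiff(PCG_NAMES, f$name)
    if (length(missing)) {
      warning("missing PCG(s): ", paste(missing, collapse = ", "),
              call. = FALSE)
    }
    seqs <- vapply(seq_len(nrow(f)),
                   function(i) extract_feature_sequence(genome, f[i, ]),
                   character(1))
    offsets <- f$codon_start
  } else {
    seqs <- toupper(genome)
    offsets <- rep(1L, length(seqs))
  }
  counts <- stats::setNames(integer(length(code)), names(code))
  for (i in seq_along(seqs)) {
    codons <- extract_codons(seqs[i], offsets[i])$codons
    if (codons[length(codons)] %in% MITO_STOPS) {
      codons <- codons[-length(codons)]
    }
    codons <- codons[codons %in% names(counts)]  # drop ambiguous triplets
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(counts = counts, family = code, rscu = NULL,
                 total_nonstop_codons =
                   sum(counts[!names(counts) %in% MITO_STOPS])),
            class = "codon_profile")
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F: `RSCU(c) = count(c) * |F| /
#' sum(count over F)`. Families follow the invertebrate mitochondrial code;
#' stop codons are excluded. Unused families get RSCU 0 for all members and
#' are listed in the attribute `zero_families`.
#'
#' @param profile a [codon_usage()] profile.
#' @return the profile with `rscu` filled.
#' @export
rscu <- function(profile) {
  stopifnot(inherits(profile, "codon_profile"))
  counts <- profile$counts
  fam <- profile$family
  vals <- stats::setNames(numeric(length(counts)), names(counts))
  zero <- character()
  for (aa in setdiff(unique(fam), "*")) {
    members <- names(fam)[fam == aa]
    tot <- sum(counts[members])
    if (tot == 0) {
      zero <- c(zero, aa)
      vals[members] <- 0
    } else {
      vals[members] <- counts[members] * length(members) / tot
    }
  }
  vals[names(fam)[fam == "*"]] <- NA_real_
  profile$rscu <- vals
  attr(profile, "zero_families") <- zero
  profile
}

#' Amino-acid usage ranking
#'
#' Aggregates codon counts per amino acid over non-stop codons, sorted by
#' descending count with ties broken alphabetically.
#'
#' @param profile a [codon_usage()] profile.
#' @return data.frame with `amino_acid` (three-letter), `aa` (one-letter)
#'   and `count`.
#' @export
amino_acid_frequency <- function(profile) {
  stopifnot(inherits(profile, "codon_profile"))
  keep <- profile$family != "*"
  agg <- tapply(profile$counts[keep], profile$family[keep], sum)
  out <- data.frame(aa = names(agg),
                    amino_acid = unname(AA1_TO_3[names(agg)]),
                    count = as.integer(agg), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$amino_acid), c("amino_acid", "aa",
                                                  "count")]
  rownames(out) <- NULL
  out
}

#' Per-gene start/stop/length table for a genome
#'
#' Applies [classify_start_stop()] to every annotated PCG, in genome order.
#'
#' @param genome an annotated [mito_genome()].
#' @return data.frame of `gene_codon_report` rows.
#' @export
pcg_codon_reports <- function(genome) {
  f <- features_of_class(genome, "PCG")
  out <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    classify_start_stop(extract_feature_sequence(genome, f[i, ]),
                        codon_start = f$codon_start[i], gene = f$name[i])
  }))
  rownames(out) <- NULL
  out
}
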