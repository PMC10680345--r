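# Published comparison values for the three Abrus leafhopper mitogenomes
# (GenBank MZ274046 A. daozhenensis, MZ274047 A. yunshanensis,
# MK033020/NC_045238 A. expansivus). These printed tables serve two roles:
# defaults for the synthetic generator, and inputs to desk-scale arithmetic
# checks (summing per-gene lengths, deriving non-stop codon totals).

ABRUS_SPECIES <- c("A_daozhenensis", "A_yunshanensis", "A_expansivus")

#' Published per-PCG start/stop/length table for the Abrus mitogenomes
#'
#' @param species one of `"A_daozhenensis"`, `"A_yunshanensis"`,
#'   `"A_expansivus"`, or `"all"`.
#' @return data.frame with `species`, `gene`, `start_codon`, `stop_codon`
#'   (`"T-"` marks the incomplete stop of cox2), `length`.
#' @export
abrus_pcg_table <- function(species = "all") {
  gene <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
            "nad5", "nad4", "nad4l", "nad6", "cob", "nad1")
  dao <- data.frame(
    species = "A_daozhenensis", gene = gene,
    start_codon = c("ATT", "ATG", "ATA", "ATA", "ATG", "ATG", "ATT",
                    "ATT", "ATG", "ATT", "ATT", "ATG", "ATA"),
    stop_codon = c("TAG", "TAA", "T-", "TAA", "TAA", "TAA", "TAG",
                   "TAG", "TAA", "TAA", "TAA", "TAA", "TAA"),
    length = c(975L, 1539L, 679L, 153L, 654L, 780L, 354L, 1674L, 1308L,
               276L, 483L, 1137L, 933L),
    stringsAsFactors = FALSE)
  yun <- dao
  yun$species <- "A_yunshanensis"
  yun$stop_codon[yun$gene == "cox3"] <- "TAG"
  exp <- dao
  exp$species <- "A_expansivus"
  exp$start_codon[exp$gene %in% c("cox1", "nad6")] <- "ATA"
  exp$stop_codon[exp$gene == "nad3"] <- "TAA"
  exp$stop_codon[exp$gene == "nad4l"] <- "TAG"
  exp$length[exp$gene == "nad4"] <- 1305L
  exp$length[exp$gene == "nad6"] <- 477L
  out <- rbind(dao, yun, exp)
  if (species != "all") {
    stopifnot(species %in% ABRUS_SPECIES)
    out <- out[out$species == species, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Published genome-level summary values for the Abrus mitogenomes
#'
#' Whole-genome size and composition, region lengths, reported overlap and
#' spacer summaries, and reported non-stop codon totals.
#'
#' @return data.frame, one row per species.
#' @export
abrus_genome_table <- function() {
  data.frame(
    species = ABRUS_SPECIES,
    accession = c("MZ274046", "MZ274047", "MK033020"),
    genome_length = c(16391L, 15768L, 15904L),
    at_percent = c(76.2, 76.3, 74.7),
    at_skew = c(0.091, 0.097, 0.095),
    gc_skew = c(-0.144, -0.161, -0.138),
    pcg_length = c(10945L, 10945L, 10936L),
    rrnL_length = c(1204L, 1203L, 1204L),
    rrnS_length = c(745L, 743L, 756L),
    trna_length = c(1441L, 1437L, 1436L),
    cr_length = c(2035L, 1947L, 1545L),
    cr_at_percent = c(82.5, 82.4, 82.2),
    cr_at_skew = c(0.011, 0.015, 0.041),
    cr_gc_skew = c(-0.103, -0.119, -0.107),
    nonstop_codons_reported = c(3636L, 3636L, 3625L),
    n_overlap_junctions = c(11L, 12L, 12L),
    total_overlap_bp = c(36L, 36L, 29L),
    n_spacers = c(7L, 8L, 8L),
    longest_spacer_bp = c(38L, 39L, 18L),
    stringsAsFactors = FALSE)
}

#' Reported gene-junction overlaps shared by the Abrus mitogenomes
#'
#' Per-junction overlap sizes in bp (as negative gaps), keyed
#' `"upstream|downstream"`. `NA` marks a junction reported for some species
#' only.
#'
#' @param species species id (see [abrus_pcg_table()]).
#' @return named integer vector of negative gaps.
#' @export
abrus_overlap_gaps <- function(species = "A_daozhenensis") {
  stopifnot(species %in% ABRUS_SPECIES)
  # columns: daozhenensis / yunshanensis / expansivus
  tab <- list(
    "trnI|trnQ"   = c(3L, 3L, 1L),
    "nad2|trnW"   = c(8L, 8L, 8L),
    "trnD|atp8"   = c(7L, 7L, 7L),
    "atp8|atp6"   = c(NA, NA, 1L),
    "trnG|nad3"   = c(2L, 2L, 1L),
    "trnA|trnR"   = c(1L, 1L, 1L),
    "trnR|trnN"   = c(1L, 1L, 1L),
    "trnN|trnS1"  = c(4L, 4L, 3L),
    "trnS1|trnE"  = c(NA, NA, 1L),
    "nad5|trnH"   = c(1L, 1L, NA),
    "trnH|nad4"   = c(7L, 7L, 4L),
    "trnP|nad6"   = c(1L, 1L, 1L),
    "cob|trnS2"   = c(1L, 1L, 1L))
  k <- match(species, ABRUS_SPECIES)
  v <- vapply(tab, `[`, integer(1), k)
  -v[!is.na(v)]
}

#' Derived non-stop codon total from the published per-gene table
#'
#' Applies the package's counting rule to the printed lengths and stop
#' types: complete codons are `length %/% 3` per gene (the 1-2 bp
#' incomplete tail is dropped), and each gene ending in a complete TAA/TAG
#' contributes one terminal stop codon that is excluded from usage counts.
#'
#' @param species species id.
#' @return integer count of non-stop codons.
#' @export
abrus_nonstop_codon_total <- function(species = "A_daozhenensis") {
  tab <- abrus_pcg_table(species)
  complete <- sum(tab$length %/% 3L)
  terminal_stops <- sum(!grepl("-$", tab$stop_codon))
  complete - terminal_stops
}
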