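# Codon extraction, start/stop classification, translation table 5, codon
# usage, RSCU and amino-acid ranking.

test_that("extract_codons splits into triplets plus incomplete tail", {
  expect_equal(extract_codons("ATGAAAT"),
               list(codons = c("ATG", "AAA"), incomplete_tail = "T"))
  expect_equal(extract_codons("ATGTAA"),
               list(codons = c("ATG", "TAA"), incomplete_tail = ""))
  expect_equal(extract_codons("GATGTAA", codon_start = 2)$codons,
               c("ATG", "TAA"))
  expect_error(extract_codons("AT"), "codon")
  # identity: 3 * n_codons + |tail| = length, over random lengths
  set.seed(3)
  for (len in sample(3:40, 10)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    ec <- extract_codons(s)
    expect_equal(3L * length(ec$codons) + nchar(ec$incomplete_tail), len)
  }
})

test_that("start/stop classification handles complete, incomplete and missing stops", {
  r <- classify_start_stop("ATGAAATAA", gene = "x")
  expect_equal(r$start_codon, "ATG")
  expect_true(r$start_canonical)
  expect_equal(r$stop_codon, "TAA")
  expect_equal(r$n_internal_stops, 0L)
  expect_false(r$no_stop_found)

  r2 <- classify_start_stop("ATAAAAT")
  expect_equal(r2$start_codon, "ATA")
  expect_equal(r2$stop_codon, "T-")

  r3 <- classify_start_stop("ATGAAAAAA")  # ends in Lys, no stop
  expect_true(r3$no_stop_found)
  expect_true(is.na(r3$stop_codon))

  r4 <- classify_start_stop("ATGTAATAA")  # internal TAA before terminal
  expect_equal(r4$n_internal_stops, 1L)

  r5 <- classify_start_stop("CTGAAATAA")  # non-ATN start
  expect_false(r5$start_canonical)
})

test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_mito("ATA"), "M")
  expect_equal(translate_mito("AGA"), "S")
  expect_equal(translate_mito("AGG"), "S")
  expect_equal(translate_mito("TGA"), "W")
  expect_equal(translate_mito("TAA"), "*")
  expect_equal(translate_mito("ATGANA"), "MX")  # ambiguity codon -> X
  # cross-check against the Biostrings translator on a random frame
  set.seed(7)
  codons <- sample(setdiff(names(invertebrate_mito_code()),
                           c("TAA", "TAG")), 50, replace = TRUE)
  s <- paste(codons, collapse = "")
  ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("5")))
  expect_equal(translate_mito(s), ref)
})

test_that("codon usage pools PCGs and excludes terminal stops and tails", {
  prof <- codon_usage("ATGTAA")
  expect_equal(unname(prof$counts["ATG"]), 1L)
  expect_equal(prof$total_nonstop_codons, 1L)

  out <- default_synthetic()
  prof2 <- codon_usage(out$genome)
  expect_equal(prof2$total_nonstop_codons, 3636L)
  gt <- out$ground_truth$codon_counts
  expect_equal(prof2$counts[names(gt)], gt[names(gt)])
  expect_equal(sum(prof2$counts), sum(gt))
  # per-gene identity: 3 * n_complete + |tail| = length
  reports <- pcg_codon_reports(out$genome)
  expect_equal(nrow(reports), 13L)
  tail_len <- ifelse(grepl("-$", reports$stop_codon),
                     nchar(sub("-$", "", reports$stop_codon)), 0L)
  expect_equal(3L * reports$n_complete_codons + tail_len, reports$length)
  expect_equal(sum(reports$n_internal_stops), 0L)
  # usage total = complete codons minus the terminal complete stops
  expect_equal(prof2$total_nonstop_codons,
               sum(reports$n_complete_codons) - sum(tail_len == 0L))
  expect_warning(codon_usage(tiny_genome("ATGAAATAA", list(
    gene_feature("nad2", 1, 9)))), "missing PCG")
})

test_that("RSCU satisfies its definition and family conservation", {
  # Lys family {AAA:3, AAG:1}: RSCU = 1.5 / 0.5
  gene <- "ATGAAAAAAAAAAAGTAA"
  prof <- rscu(codon_usage(gene))
  expect_equal(unname(prof$rscu["AAA"]), 1.5)
  expect_equal(unname(prof$rscu["AAG"]), 0.5)
  # uniform family -> all 1
  uni <- rscu(codon_usage("ATGAAAAAGTAA"))
  expect_equal(unname(uni$rscu[c("AAA", "AAG")]), c(1, 1))
  # unused families are 0 and flagged
  expect_true("G" %in% attr(prof, "zero_families"))
  expect_equal(unname(prof$rscu["GGA"]), 0)

  prof2 <- rscu(codon_usage(default_synthetic()$genome))
  fam <- prof2$family
  nonzero_means <- c()
  for (aa in setdiff(unique(fam), "*")) {
    members <- names(fam)[fam == aa]
    if (sum(prof2$counts[members]) == 0) next
    expect_equal(sum(prof2$rscu[members]), length(members), info = aa)
    nonzero_means <- c(nonzero_means, prof2$rscu[members])
  }
  expect_equal(mean(nonzero_means), 1)
})

test_that("RSCU agrees with the seqinr oracle on code-invariant families", {
  # families identical between the standard and invertebrate mito codes
  # (Ser/Arg/Ile/Met/Trp differ and are excluded)
  out <- default_synthetic()
  f <- out$genome$features
  pcgs <- f[f$gene_class == "PCG", ]
  pooled <- paste(vapply(seq_len(nrow(pcgs)), function(i) {
    s <- extract_feature_sequence(out$genome, pcgs[i, ])
    ec <- extract_codons(s)
    cods <- ec$codons
    if (cods[length(cods)] %in% c("TAA", "TAG")) cods <- cods[-length(cods)]
    paste(cods, collapse = "")
  }, character(1)), collapse = "")
  ref <- seqinr::uco(seqinr::s2c(tolower(pooled)), index = "rscu")
  prof <- rscu(codon_usage(out$genome))
  shared_aas <- c("K", "N", "D", "E", "H", "Q", "Y", "C", "F", "V", "P",
                  "T", "A", "G", "L")
  codons <- names(prof$family)[prof$family %in% shared_aas]
  expect_equal(unname(prof$rscu[codons]),
               unname(ref[tolower(codons)]),
               tolerance = 1e-10)
})

test_that("amino-acid ranking aggregates counts with alphabetical ties", {
  prof <- codon_usage("ATGTAA")
  af <- amino_acid_frequency(prof)
  expect_equal(af$amino_acid[af$count > 0], "Met")
  # hand-built: 3x Lys, 3x Asn, 1x Phe -> Asn before Lys on the tie
  prof2 <- codon_usage("ATGAAAAAAAAGAATAATAACTTTTAA")
  af2 <- amino_acid_frequency(prof2)
  top <- af2[af2$count > 0, ]
  expect_equal(top$amino_acid, c("Asn", "Lys", "Met", "Phe"))
  expect_equal(top$count, c(3L, 3L, 1L, 1L))
})
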