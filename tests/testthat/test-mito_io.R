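# GenBank/FASTA I/O, name canonicalization and feature extraction.

test_that("gene names are canonicalized across annotation dialects", {
  cases <- list(
    list(raw = "tRNA-Ser", ac = "GCT", want = "trnS1"),
    list(raw = "tRNA-Ser", ac = "TGA", want = "trnS2"),
    list(raw = "tRNA-Leu(CUN)", ac = NA_character_, want = "trnL1"),
    list(raw = "tRNA-Leu", ac = "TAA", want = "trnL2"),
    list(raw = "nad2", ac = NA_character_, want = "nad2"),
    list(raw = "COIII", ac = NA_character_, want = "cox3"),
    list(raw = "COI", ac = NA_character_, want = "cox1"),
    list(raw = "ND4L", ac = NA_character_, want = "nad4l"),
    list(raw = "CYTB", ac = NA_character_, want = "cob"),
    list(raw = "16S ribosomal RNA", ac = NA_character_, want = "rrnL"),
    list(raw = "12S rRNA", ac = NA_character_, want = "rrnS"),
    list(raw = "D-loop", ac = NA_character_, want = "CR"),
    list(raw = "A+T-rich region", ac = NA_character_, want = "CR"),
    list(raw = "tRNA-Ala", ac = NA_character_, want = "trnA"),
    list(raw = "trnW", ac = NA_character_, want = "trnW"))
  for (cs in cases) {
    got <- canonicalize_gene_name(cs$raw, cs$ac)
    expect_equal(as.character(got), cs$want, info = cs$raw)
    expect_true(attr(got, "canonical"), info = cs$raw)
  }
  # unmappable: kept, flagged; bare tRNA-Ser without anticodon is ambiguous
  for (raw in c("ORF-A", "tRNA-Ser")) {
    odd <- canonicalize_gene_name(raw)
    expect_identical(as.character(odd), raw)
    expect_false(attr(odd, "canonical"))
  }
})

test_that("minimal GenBank records parse: simple and origin-spanning joins", {
  gb <- c(
    "LOCUS       TEST01           12 bp    DNA     linear INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..12",
    "     CDS             1..9",
    '                     /gene="nad2"',
    "ORIGIN",
    "        1 atgaaatagg ct",
    "//")
  tf <- withr::local_tempfile(lines = gb, fileext = ".gb")
  g <- read_genbank(tf)
  expect_equal(genome_length(g), 12L)
  expect_false(g$circular)
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$features$name, "nad2")
  expect_equal(feature_lengths(g), 9L)

  gb2 <- c(
    "LOCUS       TEST02           30 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     misc_feature    join(25..30,1..4)",
    '                     /note="control region"',
    "ORIGIN",
    paste("        1", paste(rep("atgca", 6), collapse = " ")),
    "//")
  tf2 <- withr::local_tempfile(lines = gb2, fileext = ".gb")
  g2 <- read_genbank(tf2)
  f <- g2$features
  expect_true(f$wraps_origin)
  expect_equal(f$gene_class, "CR")
  expect_equal(feature_lengths(g2), 10L)  # 6 + 4 across the origin
})

test_that("GenBank parse errors and warnings are informative", {
  no_origin <- c("LOCUS       X  5 bp DNA linear", "//")
  tf <- withr::local_tempfile(lines = no_origin)
  expect_error(read_genbank(tf), "ORIGIN")

  out_of_range <- c(
    "LOCUS       X            6 bp    DNA     linear INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             2..9",
    '                     /gene="nad2"',
    "ORIGIN",
    "        1 acgtac",
    "//")
  tf2 <- withr::local_tempfile(lines = out_of_range)
  expect_error(read_genbank(tf2), "coordinate")

  odd_name <- c(
    "LOCUS       X            9 bp    DNA     linear INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    '                     /gene="ORF-oddball"',
    "ORIGIN",
    "        1 atgaaataa",
    "//")
  tf3 <- withr::local_tempfile(lines = odd_name)
  expect_warning(g <- read_genbank(tf3), "ORF-oddball")
  expect_equal(g$features$name, "ORF-oddball")  # kept under raw name
})

test_that("write_genbank/read_genbank round-trips a synthetic genome", {
  g <- default_synthetic()$genome
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)
  expect_identical(g2$sequence, g$sequence)
  cols <- c("name", "gene_class", "start", "end", "strand", "wraps_origin")
  f1 <- g$features[order(g$features$start), cols]
  f2 <- g2$features[order(g2$features$start), cols]
  rownames(f1) <- rownames(f2) <- NULL
  expect_identical(f2, f1)

  # wrapping CR survives the round trip as a join-location
  gw <- generate_mitogenome(synthetic_spec(seed = 101L,
                                           origin_in_cr = TRUE))$genome
  tfw <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gw, tfw)
  gw2 <- read_genbank(tfw)
  expect_identical(gw2$sequence, gw$sequence)
  cr <- gw2$features[gw2$features$name == "CR", ]
  expect_true(cr$wraps_origin)
  expect_equal(feature_lengths(gw2, cr), 2035L)

  # an annotation-free genome still writes and re-reads
  g0 <- mito_genome("ACGTACGT", record_id = "BARE")
  tf0 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g0, tf0)
  expect_identical(read_genbank(tf0)$sequence, "ACGTACGT")
})

test_that("FASTA round-trips, case-folds and warns on duplicate ids", {
  tf <- withr::local_tempfile(lines = c(">x", "acgt"))
  expect_identical(read_fasta(tf), c(x = "ACGT"))

  entries <- c(a = "ACGTACGTACGT", b = strrep("ATGC", 50))
  tf2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(entries, tf2, width = 60L)
  expect_identical(read_fasta(tf2), entries)

  tf3 <- withr::local_tempfile(lines = c(">a", "AAAA", ">a", "CCCC"))
  expect_warning(read_fasta(tf3), "duplicated")
})

test_that("extract_feature_sequence honours strand and origin wrap", {
  g <- tiny_genome("ATGCGG", list(
    gene_feature("nad2", 1, 4, strand = "J"),
    gene_feature("nad3", 1, 4, strand = "N", raw_name = "nad3b"),
    gene_feature("CR", 5, 2, strand = "J", wraps_origin = TRUE)))
  expect_identical(extract_feature_sequence(g, "nad2"), "ATGC")
  expect_identical(extract_feature_sequence(g, "nad3"), "GCAT")
  expect_identical(extract_feature_sequence(g, "CR"), "GGAT")
  g_lin <- tiny_genome("ATGCGG", list(gene_feature("nad2", 1, 4)),
                       circular = FALSE)
  wrapped <- gene_feature("CR", 5, 2, wraps_origin = TRUE)
  expect_error(extract_feature_sequence(g_lin, wrapped), "circular")
})

test_that("extraction is symmetric under genome reverse complement", {
  set.seed(5)
  L <- 60L
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
             collapse = "")
  for (k in 1:10) {
    st <- sample.int(L - 10L, 1)
    en <- st + sample.int(10L, 1)
    strand <- sample(c("J", "N"), 1)
    g <- tiny_genome(s, list(gene_feature("nad2", st, en, strand = strand)))
    # mirrored feature on the reverse-complemented genome
    g_rc <- tiny_genome(reverse_complement(s), list(
      gene_feature("nad2", L - en + 1L, L - st + 1L,
                   strand = if (strand == "J") "N" else "J")))
    expect_identical(extract_feature_sequence(g_rc, "nad2"),
                     extract_feature_sequence(g, "nad2"))
  }
})
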