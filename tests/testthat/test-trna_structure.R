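# Dot-bracket parsing, cloverleaf arm segmentation and base-pair tallies.

test_that("dot-bracket parsing recovers the pair list", {
  s <- parse_dot_bracket("GGGAAACCC", "(((...)))")
  expect_equal(s$pairs, matrix(c(1L, 2L, 3L, 9L, 8L, 7L), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))))
  s2 <- parse_dot_bracket("GGAAUC", "((..))")
  expect_equal(unname(s2$pairs), matrix(c(1L, 2L, 6L, 5L), ncol = 2))
  expect_equal(nrow(parse_dot_bracket("ACGU", "....")$pairs), 0L)
  expect_error(parse_dot_bracket("ACGU", "(..."), "position 1")
  expect_error(parse_dot_bracket("ACGU", "..))"), "position 3")
  expect_error(parse_dot_bracket("ACGU", "..."), "lengths")
  expect_error(parse_dot_bracket("ACGU", "..x."), "position 3")
  # T is normalized to U
  expect_equal(parse_dot_bracket("ACGT", "....")$sequence, "ACGU")
})

test_that("parse -> serialize -> parse round-trips the pair list", {
  gen <- generate_trna_structures(seed = 2)
  for (s in gen$structures[1:5]) {
    s2 <- parse_dot_bracket(s$sequence, to_dot_bracket(s), s$trna_name)
    expect_equal(s2$pairs, s$pairs)
  }
})

test_that("arms are segmented positionally, including missing arms", {
  gen <- generate_trna_structures(seed = 4,
                                  dropout = list(trnS1 = "DHU",
                                                 trnG = "TpsiC"))
  by_name <- stats::setNames(gen$structures,
                             vapply(gen$structures,
                                    function(s) s$trna_name, character(1)))
  full <- classify_arms(by_name[["trnA"]])
  expect_true(all(full$arms$present))
  expect_equal(full$arms$stem_pairs,
               c(7L, 4L, 5L, 5L))  # acceptor, DHU, anticodon, TpsiC

  s1 <- classify_arms(by_name[["trnS1"]])
  expect_false(s1$arms$present[s1$arms$arm == "DHU"])
  expect_true(all(s1$arms$present[s1$arms$arm != "DHU"]))

  gly <- classify_arms(by_name[["trnG"]])
  expect_false(gly$arms$present[gly$arms$arm == "TpsiC"])
  expect_true(all(gly$arms$present[gly$arms$arm != "TpsiC"]))

  # anticodon read from the middle of the anticodon loop
  expect_equal(full$anticodon_triplet, "UGC")   # trnA
  expect_equal(s1$anticodon_triplet, "GCU")     # trnS1, AGN family

  # a bare hairpin is not a cloverleaf
  hairpin <- classify_arms(parse_dot_bracket("GGGAAACCC", "(((...)))"))
  expect_true(isTRUE(attr(hairpin, "non_cloverleaf")))
})

test_that("pair types split into Watson-Crick, wobble and mismatch", {
  wc <- pair_type_tally(parse_dot_bracket("GGGAAACCC", "(((...)))"))
  expect_equal(wc, c(watson_crick = 3L, gu_wobble = 0L, mismatch = 0L))
  gu <- pair_type_tally(parse_dot_bracket("GGGAAACCU", "(((...)))"))
  expect_equal(unname(gu["gu_wobble"]), 1L)
  mm <- pair_type_tally(parse_dot_bracket("AGGAAACCA", "(((...)))"))
  expect_equal(unname(mm["mismatch"]), 1L)  # A-A closing pair
  # conservation: categories partition the pair list
  gen <- generate_trna_structures(seed = 8, gu_rate = 0.2)
  for (s in gen$structures) {
    tally <- pair_type_tally(s)
    expect_equal(sum(tally), nrow(s$pairs))
  }
})

test_that("injected wobble pairs are recovered exactly", {
  gen0 <- generate_trna_structures(seed = 12, gu_rate = 0)
  expect_equal(sum(vapply(gen0$structures,
                          function(s) pair_type_tally(s)[["gu_wobble"]],
                          integer(1))), 0L)
  gen <- generate_trna_structures(seed = 12, gu_rate = 0.08)
  measured <- sum(vapply(gen$structures,
                         function(s) pair_type_tally(s)[["gu_wobble"]],
                         integer(1)))
  expect_equal(measured, attr(gen$ground_truth, "gu_total"))
  expect_equal(sum(gen$ground_truth$gu_pairs), measured)
})

test_that("per-tRNA summary joins annotation and structures", {
  out <- default_synthetic()
  gen <- generate_trna_structures(seed = 6)
  tab <- summarize_trnas(out$genome, gen$structures)
  expect_equal(nrow(tab), 22L)
  expect_true(all(tab$has_structure))
  expect_true(all(tab$length >= 61 & tab$length <= 76))
  expect_equal(attr(tab, "min_length"), min(tab$length))
  expect_equal(sum(!tab$DHU), 1L)  # trnS1 only
  expect_false(tab$DHU[tab$name == "trnS1"])
  expect_equal(sum(tab$length), 1441L)
  # annotation-only table when no structures are given
  tab0 <- summarize_trnas(out$genome)
  expect_false(any(tab0$has_structure))
  expect_true(all(is.na(tab0$gu_wobble)))
  # unmatched structure -> warning row
  stray <- generate_trna_structures(seed = 6,
                                    trna_names = "trnA")$structures
  stray[[1]]$trna_name <- "trnZ"
  expect_warning(tabz <- summarize_trnas(out$genome, stray), "trnZ")
  expect_true("trnZ" %in% tabz$name)
})

test_that("MITOS-style structure files round-trip", {
  gen <- generate_trna_structures(seed = 14)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_trna_structures(gen$structures, tf)
  back <- read_trna_structures(tf)
  expect_equal(length(back), 22L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$trna_name, gen$structures[[i]]$trna_name)
    expect_equal(back[[i]]$sequence, gen$structures[[i]]$sequence)
    expect_equal(back[[i]]$pairs, gen$structures[[i]]$pairs)
  }
  expect_error(read_trna_structures(withr::local_tempfile(
    lines = c(">x", "ACGU"))), "blocks of 3")
})
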