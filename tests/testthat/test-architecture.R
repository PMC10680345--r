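# Junction gaps/overlaps, control region, strand tallies, gene order and
# breakpoint distances.

test_that("junction gaps follow the sign convention", {
  s <- strrep("ATGCA", 6)  # 30 bp circle
  g <- tiny_genome(s, list(gene_feature("trnI", 1, 10),
                           gene_feature("trnQ", 11, 20)))
  j <- junctions(g)
  expect_equal(j$gap_bp[j$upstream == "trnI"], 0L)  # abutting
  g2 <- tiny_genome(s, list(gene_feature("trnI", 1, 10),
                            gene_feature("trnQ", 8, 20)))
  j2 <- junctions(g2)
  expect_equal(j2$gap_bp[j2$upstream == "trnI"], -3L)  # bases 8..10 shared
  # the wrap-around junction closes the circle
  expect_equal(j2$gap_bp[j2$upstream == "trnQ"], 30L - 20L + 1L - 1L)
  expect_error(junctions(tiny_genome(s, list(gene_feature("trnI", 1, 4)))),
               "2 features")
})

test_that("default synthetic genome reproduces the published junction geometry", {
  out <- default_synthetic()
  j <- junctions(out$genome)
  expect_equal(j$gap_bp[j$upstream == "trnD" & j$downstream == "atp8"],
               -7L)
  ov <- overlap_summary(j)
  expect_equal(ov$n_overlap_junctions, 11L)
  expect_equal(ov$total_overlap_bp, 36L)
  expect_equal(ov$max_overlap_bp, 8L)
  sp <- spacer_summary(j)
  expect_equal(sp$n_spacers, 7L)
  expect_equal(sp$longest$upstream, "trnC")
  expect_equal(sp$longest$downstream, "trnY")
  expect_equal(sp$longest$bp, 38L)
  # every realized gap equals the requested one
  gt <- out$ground_truth$junction_gaps
  merged <- merge(j, gt, by = c("upstream", "downstream"))
  expect_equal(nrow(merged), 38L)
  expect_equal(merged$gap_bp.x, merged$gap_bp.y)
})

test_that("overlap/spacer summaries on constructed gap sets", {
  abut <- generate_mitogenome(synthetic_spec(
    seed = 5, junction_gaps = zero_gap_overrides()))
  j <- junctions(abut$genome)
  ov <- overlap_summary(j)
  expect_equal(ov, list(n_overlap_junctions = 0L, total_overlap_bp = 0L,
                        max_overlap_bp = 0L))
  sp <- spacer_summary(j)
  expect_equal(sp$n_spacers, 0L)
  expect_null(sp$longest)

  gaps <- zero_gap_overrides()
  gaps[c("trnA|trnR", "trnD|atp8", "nad2|trnW")] <- c(-1L, -7L, -8L)
  gaps[c("trnQ|trnM", "trnC|trnY")] <- c(5L, 39L)
  mix <- generate_mitogenome(synthetic_spec(seed = 5,
                                            junction_gaps = gaps))
  jm <- junctions(mix$genome)
  ovm <- overlap_summary(jm)
  expect_equal(ovm$n_overlap_junctions, 3L)
  expect_equal(ovm$total_overlap_bp, 16L)
  expect_equal(ovm$max_overlap_bp, 8L)
  spm <- spacer_summary(jm)
  expect_equal(spm$longest$bp, 39L)
  expect_equal(spm$longest$upstream, "trnC")
})

test_that("length conservation closes the circle on synthetic genomes", {
  for (seed in c(101L, 17L)) {
    out <- generate_mitogenome(synthetic_spec(seed = seed))
    g <- out$genome
    gene_sum <- sum(feature_lengths(g))
    gap_sum <- sum(out$ground_truth$junction_gaps$gap_bp)
    expect_equal(gene_sum + gap_sum, genome_length(g))
    # and via the measured junction table
    j <- junctions(g)
    expect_equal(gene_sum + sum(j$gap_bp), genome_length(g))
  }
})

test_that("junction gaps are invariant under origin rotation", {
  out <- default_synthetic()
  j0 <- junctions(out$genome)
  for (shift in c(1L, 5000L, 16000L)) {
    jr <- junctions(rotate_origin(out$genome, shift))
    expect_equal(jr$gap_bp, j0$gap_bp)
    expect_equal(jr$upstream, j0$upstream)
  }
})

test_that("control region is located between rrnS and trnI", {
  out <- default_synthetic()
  cr <- locate_control_region(out$genome)
  expect_equal(cr$length, 2035L)
  # synthesized when unannotated: strip the CR feature and re-locate
  g <- out$genome
  g$features <- g$features[g$features$name != "CR", ]
  cr2 <- locate_control_region(g)
  expect_equal(cr2$length, 2035L)
  expect_equal(cr2$start, cr$start)
  # wrapped CR
  gw <- generate_mitogenome(synthetic_spec(seed = 101L,
                                           origin_in_cr = TRUE))$genome
  gw$features <- gw$features[gw$features$name != "CR", ]
  crw <- locate_control_region(gw)
  expect_equal(crw$length, 2035L)
  expect_true(crw$wraps_origin)
  # degenerate: rrnS abuts trnI
  g0 <- tiny_genome(strrep("ACGT", 10),
                    list(gene_feature("rrnS", 31, 40, strand = "N"),
                         gene_feature("trnI", 1, 10)))
  expect_warning(cr0 <- locate_control_region(g0), "abuts")
  expect_equal(cr0$length, 0L)
  expect_error(locate_control_region(tiny_genome("ACGTACGT", list(
    gene_feature("trnI", 1, 4)))), "rrnS")
})

test_that("strand tallies reproduce the ancestral arrangement", {
  st <- strand_tally(default_synthetic()$genome)
  expect_equal(st[st$gene_class == "tRNA", c("n_J", "n_N")],
               data.frame(n_J = 14L, n_N = 8L), ignore_attr = TRUE)
  expect_equal(st[st$gene_class == "PCG", c("n_J", "n_N")],
               data.frame(n_J = 9L, n_N = 4L), ignore_attr = TRUE)
  expect_equal(st[st$gene_class == "rRNA", c("n_J", "n_N")],
               data.frame(n_J = 0L, n_N = 2L), ignore_attr = TRUE)
  g1 <- tiny_genome("ATGAAATAAG", list(gene_feature("nad2", 1, 9,
                                                    strand = "N")))
  st1 <- strand_tally(g1)
  expect_equal(st1$n_N[st1$gene_class == "PCG"], 1L)
})

test_that("gene order is recovered, rotated to trnI", {
  out <- default_synthetic()
  ord <- gene_order(out$genome)
  anc <- ancestral_gene_order()
  expect_equal(ord$name, anc$name)
  expect_equal(ord$strand, anc$strand)
  # a shuffled annotation order is recovered as generated
  shuffled <- anc[c(1:4, 6, 5, 7:37), ]  # swap trnW <-> trnC
  out2 <- generate_mitogenome(synthetic_spec(seed = 9,
                                             gene_order = shuffled))
  expect_equal(gene_order(out2$genome)$name, shuffled$name)
  dup <- tiny_genome(strrep("ACGT", 10),
                     list(gene_feature("trnI", 1, 5),
                          gene_feature("trnI", 11, 15)))
  expect_error(gene_order(dup), "duplicate")
})

test_that("breakpoint distance matches a brute-force adjacency oracle", {
  anc <- ancestral_gene_order()
  expect_equal(breakpoint_distance(anc, anc), 0L)
  swapped <- anc[c(1:4, 6, 5, 7:37), ]
  expect_equal(breakpoint_distance(anc, swapped), 2L)
  expect_equal(breakpoint_distance(swapped, anc), 2L)
  set.seed(23)
  for (trial in 1:100) {
    pa <- anc[sample.int(37), ]
    pb <- if (trial %% 3 == 0) anc else anc[sample.int(37), ]
    d <- breakpoint_distance(pa, pb)
    expect_equal(d, brute_force_breakpoints(pa$name, pb$name))
    expect_equal(breakpoint_distance(pb, pa), d)  # symmetry
  }
  # rotation invariance and the zero case
  rot <- anc[c(10:37, 1:9), ]
  expect_equal(breakpoint_distance(anc, rot), 0L)
  expect_error(breakpoint_distance(anc, anc[1:36, ]), "differ")
})

test_that("signed breakpoint distance sees inversions", {
  anc <- ancestral_gene_order()
  inv <- anc
  inv$strand[5] <- ifelse(anc$strand[5] == "J", "N", "J")  # flip trnW
  expect_equal(breakpoint_distance(anc, inv), 0L)
  expect_equal(breakpoint_distance(anc, inv, signed = TRUE), 2L)
})

test_that("rearrangement detection names the displaced tRNA cluster", {
  rr <- detect_rearrangement(gene_order(default_synthetic()$genome))
  expect_equal(rr$distance, 0L)
  expect_equal(nrow(rr$broken_adjacencies), 0L)
  # trnC-trnW-trnY variant of the trnW-trnC-trnY cluster
  anc <- ancestral_gene_order()
  variant <- anc[c(1:4, 6, 5, 7:37), ]
  rr2 <- detect_rearrangement(variant)
  expect_equal(rr2$distance, 2L)
  expect_true(all(c("trnW", "trnC") %in% rr2$displaced_genes))
  one <- structure(data.frame(name = "trnI", strand = "J"),
                   class = c("gene_order", "data.frame"))
  expect_equal(detect_rearrangement(one, one)$distance, 0L)
})
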