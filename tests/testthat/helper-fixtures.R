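# Shared fixtures: tiny hand-built genomes and a cached default synthetic
# genome (generation is deterministic, so one instance serves many tests).

tiny_genome <- function(sequence, features, circular = TRUE) {
  mito_genome(sequence, do.call(rbind, features), record_id = "tiny",
              circular = circular)
}

default_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_mitogenome(synthetic_spec(seed = 101L))
    cache
  }
})

# zero out every default junction gap (the published overlaps plus the
# generator's default spacers)
zero_gap_overrides <- function() {
  keys <- c(names(abrus_overlap_gaps("A_daozhenensis")),
            "trnQ|trnM", "trnY|cox1", "cox2|trnK", "nad3|trnA",
            "trnE|trnF", "trnT|trnP", "trnC|trnY")
  stats::setNames(rep(0L, length(keys)), keys)
}

# independent brute-force breakpoint oracle: count adjacencies of a absent
# from b by naive pairwise comparison of unordered circular neighbours
brute_force_breakpoints <- function(a, b) {
  adj <- function(g) {
    n <- length(g)
    lapply(seq_len(n), function(i) sort(c(g[i], g[if (i < n) i + 1 else 1])))
  }
  aa <- adj(a)
  bb <- adj(b)
  sum(vapply(aa, function(p) {
    !any(vapply(bb, function(q) identical(p, q), logical(1)))
  }, logical(1)))
}
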