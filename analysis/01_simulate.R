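#!/usr/bin/env Rscript
# Step 1: generate the three Abrus-like synthetic mitogenomes (one per
# species preset, under the published gene lengths, junction geometry and
# composition targets) plus tRNA secondary structures, and write all
# fixtures under results/synthetic/.

suppressPackageStartupMessages(library(mitocomp))

seed0 <- 2026L
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

species <- c("A_daozhenensis", "A_yunshanensis", "A_expansivus")
# reduced tRNAs: trnS1 lacks the DHU arm everywhere; in the
# A. expansivus mitogenome trnG additionally lacks the TpsiC arm
dropouts <- list(
  A_daozhenensis = list(trnS1 = "DHU"),
  A_yunshanensis = list(trnS1 = "DHU"),
  A_expansivus = list(trnS1 = "DHU", trnG = "TpsiC"))

for (i in seq_along(species)) {
  sp <- species[i]
  out <- generate_mitogenome(synthetic_spec(seed = seed0 + i, species = sp))
  g <- out$genome
  write_genbank(g, file.path(out_dir, paste0(sp, ".gb")))
  write_fasta(stats::setNames(g$sequence, g$record_id),
              file.path(out_dir, paste0(sp, ".fasta")))
  jsonlite::write_json(out$ground_truth,
                       file.path(out_dir, paste0(sp, "_ground_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  ts <- generate_trna_structures(seed = seed0 + i,
                                 dropout = dropouts[[sp]])
  write_trna_structures(ts$structures,
                        file.path(out_dir, paste0(sp, "_trna.txt")))
  utils::write.table(ts$ground_truth,
                     file.path(out_dir, paste0(sp, "_trna_ground_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d bp, %d features, %d tRNA structures (G-U pairs: %d)\n",
              g$record_id, genome_length(g), nrow(g$features),
              length(ts$structures), attr(ts$ground_truth, "gu_total")))
}
cat("fixtures written to", out_dir, "\n")
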