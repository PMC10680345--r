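# Comparative report over one or more genomes: the orchestration layer
# that assembles every per-genome analysis into the standard comparative
# tables (composition/skew per region, per-PCG start/stop/length, junction
# tables, codon usage/RSCU, amino-acid frequencies, gene order vs the
# ancestral arrangement, tRNA structure summaries).

#' Compare one or more annotated mitogenomes
#'
#' Runs the full analysis over each genome and collects comparative
#' tables. Sections degrade gracefully (with warnings) for partially
#' annotated genomes; genomes appear in the order given.
#'
#' @param genomes a [mito_genome()] or list of them.
#' @param structures optional named list (by genome `record_id`) of
#'   `cloverleaf` structure lists, as from [read_trna_structures()].
#' @param reference_order gene order used for rearrangement detection.
#' @return object of class `comparative_report`: list of data.frames
#'   `composition`, `pcg_report`, `junctions`, `junction_summary`,
#'   `codon_table`, `aa_frequency`, `gene_order`, `trna_summary` (may be
#'   `NULL`). All numbers are kept at full precision; rounding happens in
#'   [write_report()].
#' @export
compare_genomes <- function(genomes, structures = NULL,
                            reference_order = ancestral_gene_order()) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L)
  ids <- vapply(genomes, function(g) g$record_id, character(1))

  with_id <- function(id, df) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    cbind(data.frame(genome = id, stringsAsFactors = FALSE), df)
  }
  section <- function(fn) {
    do.call(rbind, lapply(seq_along(genomes), function(i) {
      out <- tryCatch(fn(genomes[[i]], ids[i]),
                      error = function(e) {
                        warning(ids[i], ": ", conditionMessage(e),
                                call. = FALSE)
                        NULL
                      })
      with_id(ids[i], out)
    }))
  }

  composition <- section(function(g, id) region_summary(g))
  pcg_report <- section(function(g, id) {
    if (!any(g$features$gene_class == "PCG")) return(NULL)
    pcg_codon_reports(g)
  })
  junc <- section(function(g, id) junctions(g))
  junction_summary <- section(function(g, id) {
    j <- junctions(g)
    ov <- overlap_summary(j)
    sp <- spacer_summary(j)
    cr <- tryCatch(locate_control_region(g)$length,
                   error = function(e) NA_integer_)
    data.frame(n_overlap_junctions = ov$n_overlap_junctions,
               total_overlap_bp = ov$total_overlap_bp,
               max_overlap_bp = ov$max_overlap_bp,
               n_spacers = sp$n_spacers,
               total_spacer_bp = sp$total_spacer_bp,
               longest_spacer_bp = if (is.null(sp$longest)) NA_integer_
                 else sp$longest$bp,
               longest_spacer_junction = if (is.null(sp$longest))
                 NA_character_ else paste(sp$longest$upstream,
                                          sp$longest$downstream,
                                          sep = "-"),
               cr_length = cr, stringsAsFactors = FALSE)
  })
  codon_table <- section(function(g, id) {
    if (!any(g$features$gene_class == "PCG")) return(NULL)
    prof <- rscu(codon_usage(g))
    data.frame(codon = names(prof$counts),
               amino_acid = unname(prof$family),
               count = unname(prof$counts),
               rscu = unname(prof$rscu), stringsAsFactors = FALSE)
  })
  aa_frequency <- section(function(g, id) {
    if (!any(g$features$gene_class == "PCG")) return(NULL)
    amino_acid_frequency(codon_usage(g))
  })
  order_section <- section(function(g, id) {
    if (nrow(g$features[g$features$gene_class != "CR", ]) < 2L) {
      return(NULL)
    }
    ord <- gene_order(g)
    rr <- detect_rearrangement(ord, reference_order)
    data.frame(order = paste(ord$name, collapse = ","),
               breakpoint_distance = rr$distance,
               displaced_genes = paste(rr$displaced_genes,
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  trna_summary <- NULL
  if (!is.null(structures)) {
    trna_summary <- section(function(g, id) {
      summarize_trnas(g, structures[[id]] %||% list())
    })
  }

  structure(list(composition = composition, pcg_report = pcg_report,
                 junctions = junc, junction_summary = junction_summary,
                 codon_table = codon_table, aa_frequency = aa_frequency,
                 gene_order = order_section,
                 trna_summary = trna_summary),
            class = "comparative_report")
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("<comparative_report>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  $%s: %d rows x %d cols\n", nm, nrow(x[[nm]]),
                ncol(x[[nm]])))
  }
  invisible(x)
}

#' Write a comparative report to disk
#'
#' One TSV (header row, tab-separated) or JSON file per section. Both
#' formats round percentages to one decimal and skews/RSCU to three
#' decimals (presentation precision of the published comparative tables),
#' so the two encodings carry identical numbers; full precision lives in
#' the [compare_genomes()] object itself.
#'
#' @param report a [compare_genomes()] result.
#' @param dir output directory (created if needed).
#' @param format `"tsv"`, `"json"`, or both.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, format = "tsv") {
  stopifnot(inherits(report, "comparative_report"),
            all(format %in% c("tsv", "json")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(report)) {
    df <- report[[nm]]
    if (is.null(df)) next
    for (col in intersect(c("at_percent"), names(df))) {
      df[[col]] <- round(df[[col]], 1)
    }
    for (col in intersect(c("at_skew", "gc_skew", "rscu"), names(df))) {
      df[[col]] <- round(df[[col]], 3)
    }
    if ("tsv" %in% format) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
    if ("json" %in% format) {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(df, p, dataframe = "rows", digits = NA,
                           na = "null")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
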