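# Seeded synthetic mitogenome generator.
#
# Emulates a circular insect mitogenome with the 37-gene ancestral order:
# configurable composition and strand skews, PCGs with ATN starts, complete
# TAA/TAG or incomplete (T) stops and no internal stops, junction overlaps
# realized as shared sequence, an A+T-rich control region with tandem
# repeats, and a GroundTruth record of the realized (not target) values for
# every downstream statistic.

# standard insect mitochondrial anticodons, DNA alphabet, coding sense
TRNA_ANTICODONS <- c(
  trnI = "GAT", trnQ = "TTG", trnM = "CAT", trnW = "TCA", trnC = "GCA",
  trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
  trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
  trnL1 = "TAG", trnV = "TAC")

DEFAULT_TRNA_LENGTHS <- c(
  trnI = 66L, trnQ = 69L, trnM = 68L, trnW = 65L, trnC = 62L, trnY = 66L,
  trnL2 = 64L, trnK = 72L, trnD = 65L, trnG = 61L, trnA = 67L, trnR = 64L,
  trnN = 66L, trnS1 = 68L, trnE = 63L, trnF = 65L, trnH = 69L, trnT = 61L,
  trnP = 67L, trnS2 = 70L, trnL1 = 62L, trnV = 61L)

# spacers chosen once so that, with the published overlaps (-36 bp) and
# region lengths, the default circle closes at exactly 16,391 bp
DEFAULT_SPACER_GAPS <- c(
  "trnQ|trnM" = 1L, "trnY|cox1" = 2L, "cox2|trnK" = 1L, "nad3|trnA" = 3L,
  "trnE|trnF" = 8L, "trnT|trnP" = 4L, "trnC|trnY" = 38L)

#' Specification for a synthetic mitogenome
#'
#' Defaults emulate the *A. daozhenensis* mitogenome: published per-gene
#' lengths and start/stop codons, published junction overlaps, an A+T
#' content of 76.2% with AT-skew 0.091 and GC-skew -0.144, and a 2,035 bp
#' control region at 82.5% A+T. Any field can be overridden.
#'
#' @param seed integer RNG seed; generation is deterministic given the
#'   spec.
#' @param species preset for gene lengths and start/stop codons
#'   (`"A_daozhenensis"` default, `"A_yunshanensis"`, `"A_expansivus"`).
#' @param gene_lengths named integer overrides for gene/CR lengths.
#' @param gene_order a `gene_order` (default [ancestral_gene_order()]).
#' @param junction_gaps named integer overrides, keyed
#'   `"upstream|downstream"`; negative = overlap, positive = spacer.
#'   Junctions not named default to the published overlaps/spacers (0
#'   elsewhere).
#' @param at_fraction,at_skew,gc_skew genome-wide base-composition targets
#'   for randomly drawn sequence.
#' @param cr_at_fraction,cr_at_skew,cr_gc_skew control-region composition
#'   targets.
#' @param cr_repeat_unit_bp,cr_repeat_copies tandem repeat embedded at the
#'   start of the control region.
#' @param origin_in_cr rotate the finished genome so the sequence origin
#'   falls inside the control region (CR then wraps the origin).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, species = "A_daozhenensis",
                           gene_lengths = NULL,
                           gene_order = ancestral_gene_order(),
                           junction_gaps = NULL,
                           at_fraction = NULL, at_skew = NULL,
                           gc_skew = NULL,
                           cr_at_fraction = NULL, cr_at_skew = NULL,
                           cr_gc_skew = NULL,
                           cr_repeat_unit_bp = 54L, cr_repeat_copies = 3L,
                           origin_in_cr = FALSE) {
  stopifnot(species %in% ABRUS_SPECIES)
  gtab <- abrus_genome_table()
  grow <- gtab[gtab$species == species, ]
  ptab <- abrus_pcg_table(species)

  lens <- c(stats::setNames(ptab$length, ptab$gene),
            rrnL = grow$rrnL_length, rrnS = grow$rrnS_length,
            DEFAULT_TRNA_LENGTHS, CR = grow$cr_length)
  if (!is.null(gene_lengths)) lens[names(gene_lengths)] <- gene_lengths

  gaps <- c(abrus_overlap_gaps(species), DEFAULT_SPACER_GAPS)
  gaps["trnC|trnY"] <- grow$longest_spacer_bp  # published per species
  if (!is.null(junction_gaps)) gaps[names(junction_gaps)] <- junction_gaps

  spec <- structure(list(
    seed = as.integer(seed), species = species,
    gene_lengths = lens, gene_order = gene_order,
    junction_gaps = gaps,
    starts = stats::setNames(ptab$start_codon, ptab$gene),
    stops = stats::setNames(ptab$stop_codon, ptab$gene),
    at_fraction = (at_fraction %||% (grow$at_percent / 100)),
    at_skew = (at_skew %||% grow$at_skew),
    gc_skew = (gc_skew %||% grow$gc_skew),
    cr_at_fraction = (cr_at_fraction %||% (grow$cr_at_percent / 100)),
    cr_at_skew = (cr_at_skew %||% grow$cr_at_skew),
    cr_gc_skew = (cr_gc_skew %||% grow$cr_gc_skew),
    cr_repeat_unit_bp = as.integer(cr_repeat_unit_bp),
    cr_repeat_copies = as.integer(cr_repeat_copies),
    origin_in_cr = isTRUE(origin_in_cr)), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  lens <- spec$gene_lengths
  if (any(lens <= 0L)) stop("gene lengths must be positive", call. = FALSE)
  for (p in c("at_fraction", "cr_at_fraction")) {
    if (spec[[p]] <= 0 || spec[[p]] >= 1) {
      stop(p, " must lie in (0, 1)", call. = FALSE)
    }
  }
  for (p in c("at_skew", "gc_skew", "cr_at_skew", "cr_gc_skew")) {
    if (abs(spec[[p]]) >= 1) {
      stop(p, " must lie in (-1, 1): both bases of each pair are required",
           call. = FALSE)
    }
  }
  for (g in names(spec$stops)) {
    mod <- lens[[g]] %% 3L
    want <- switch(spec$stops[[g]], "T-" = 1L, "TA-" = 2L, 0L)
    if (mod != want) {
      stop(sprintf(
        "gene %s: length %d (mod 3 = %d) inconsistent with stop '%s'",
        g, lens[[g]], mod, spec$stops[[g]]), call. = FALSE)
    }
  }
  walk <- c(spec$gene_order$name, "CR")
  for (key in names(spec$junction_gaps)) {
    gap <- spec$junction_gaps[[key]]
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (!all(pair %in% walk)) next
    if (gap < 0L && -gap >= min(lens[pair])) {
      stop("overlap at ", key, " is as long as a flanking gene",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# per-base probabilities solving the (AT fraction, AT-skew, GC-skew)
# targets: p_A = at(1+sAT)/2, p_T = at(1-sAT)/2, p_G = gc(1+sGC)/2,
# p_C = gc(1-sGC)/2
base_probs <- function(at, s_at, s_gc) {
  c(A = at * (1 + s_at) / 2, T = at * (1 - s_at) / 2,
    G = (1 - at) * (1 + s_gc) / 2, C = (1 - at) * (1 - s_gc) / 2)
}

draw_bases <- function(n, probs) {
  if (n == 0L) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# composition targets apply to the deposited plus strand; an N-strand gene
# drawn in coding sense therefore uses the complemented probabilities
complement_probs <- function(p) {
  c(A = unname(p["T"]), T = unname(p["A"]),
    G = unname(p["C"]), C = unname(p["G"]))
}

# a PCG coding sequence: fixed start codon, internal codons drawn from the
# composition target and rejection-filtered against TAA/TAG, and either a
# complete stop codon or a truncated T/TA tail
build_pcg_seq <- function(len, start_codon, stop_codon, probs) {
  tail <- switch(stop_codon, "T-" = "T", "TA-" = "TA", "")
  n_complete <- (len - nchar(tail)) %/% 3L
  n_internal <- n_complete - 1L - (if (tail == "") 1L else 0L)
  internals <- character(n_internal)
  for (i in seq_len(n_internal)) {
    repeat {
      cod <- paste(draw_bases(3L, probs), collapse = "")
      if (!cod %in% MITO_STOPS) break
    }
    internals[i] <- cod
  }
  paste0(start_codon, paste(internals, collapse = ""),
         if (tail == "") stop_codon else tail)
}

# control region: tandem repeats of a drawn unit, then random A+T-rich fill
build_cr_seq <- function(len, unit_bp, copies, probs) {
  unit <- paste(draw_bases(min(unit_bp, len), probs), collapse = "")
  rep_part <- strtrim(strrep(unit, copies), len)
  fill <- paste(draw_bases(len - nchar(rep_part), probs), collapse = "")
  paste0(rep_part, fill)
}

# local helpers used for GroundTruth bookkeeping, deliberately independent
# of the analysis modules
rc_inline <- function(s) {
  paste(rev(seq_chars(chartr("ACGT", "TGCA", s))), collapse = "")
}
count_inline <- function(s) {
  tab <- table(factor(seq_chars(s), levels = c("A", "C", "G", "T")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic given the spec (one RNG stream seeded from `spec$seed`;
#' the caller's RNG state is left untouched). Junction gaps are realized
#' exactly: overlapping genes share sequence (protein-coding genes are
#' written last so their start/stop architecture wins inside overlaps, and
#' the result is re-checked — an overlap that cannot satisfy both flanking
#' genes is an error). The GroundTruth records realized counts from the
#' emitted sequence, not the sampling targets.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (a [mito_genome()]) and `ground_truth` (list:
#'   `gene_table`, `junction_gaps`, `region_counts`, `codon_counts`,
#'   `strand_tally`, `gene_order`, `genome_length`, `cr`).
#' @export
generate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  ord <- spec$gene_order
  walk <- c(ord$name, "CR")
  strands <- c(stats::setNames(ord$strand, ord$name), CR = "J")
  lens <- spec$gene_lengths
  gap_of <- function(up, down) {
    key <- paste(up, down, sep = "|")
    if (key %in% names(spec$junction_gaps)) {
      spec$junction_gaps[[key]]
    } else 0L
  }

  # coordinates: walk the circle from trnI at position 1
  n_feat <- length(walk)
  start <- integer(n_feat)
  end <- integer(n_feat)
  pos <- 1L
  for (i in seq_len(n_feat)) {
    start[i] <- pos
    end[i] <- pos + lens[[walk[i]]] - 1L
    if (i < n_feat) pos <- end[i] + gap_of(walk[i], walk[i + 1L]) + 1L
  }
  L <- end[n_feat] + gap_of(walk[n_feat], walk[1L])
  if (any(start < 1L) || any(end > L)) {
    stop("infeasible spec: junction gaps push a feature off the circle",
         call. = FALSE)
  }

  probs <- base_probs(spec$at_fraction, spec$at_skew, spec$gc_skew)
  cr_probs <- base_probs(spec$cr_at_fraction, spec$cr_at_skew,
                         spec$cr_gc_skew)

  chars <- rep(NA_character_, L)
  write_gene <- function(i, coding) {
    s <- if (strands[[walk[i]]] == "N") rc_inline(coding) else coding
    chars[start[i]:end[i]] <<- seq_chars(s)
  }
  classes <- c(stats::setNames(
    ifelse(ord$name %in% PCG_NAMES, "PCG",
           ifelse(ord$name %in% RRNA_NAMES, "rRNA", "tRNA")), ord$name),
    CR = "CR")
  # pass 1: unconstrained regions; pass 2: PCGs, whose codon architecture
  # must survive inside overlaps
  for (i in seq_len(n_feat)) {
    g <- walk[i]
    if (classes[[g]] == "PCG") next
    if (g == "CR") {
      write_gene(i, build_cr_seq(lens[[g]], spec$cr_repeat_unit_bp,
                                 spec$cr_repeat_copies, cr_probs))
    } else {
      # drawn directly on the plus strand so the strand-skew target is
      # realized regardless of the gene's own strand
      chars[start[i]:end[i]] <- draw_bases(lens[[g]], probs)
    }
  }
  for (i in seq_len(n_feat)) {
    g <- walk[i]
    if (classes[[g]] != "PCG") next
    p <- if (strands[[walk[i]]] == "N") complement_probs(probs) else probs
    write_gene(i, build_pcg_seq(lens[[g]], spec$starts[[g]],
                                spec$stops[[g]], p))
  }
  chars[is.na(chars)] <- draw_bases(sum(is.na(chars)), probs)
  sequence <- paste(chars, collapse = "")

  # verify PCG architecture survived overlap writes
  slice <- function(i) {
    s <- substr(sequence, start[i], end[i])
    if (strands[[walk[i]]] == "N") rc_inline(s) else s
  }
  for (i in seq_len(n_feat)) {
    g <- walk[i]
    if (classes[[g]] != "PCG") next
    s <- slice(i)
    tail_len <- lens[[g]] %% 3L
    cods <- substring(s, seq(1L, lens[[g]] - tail_len, 3L),
                      seq(3L, lens[[g]] - tail_len, 3L))
    ok_start <- cods[1] == spec$starts[[g]]
    ok_stop <- if (tail_len > 0L) {
      substring(s, lens[[g]] - tail_len + 1L) ==
        sub("-", "", spec$stops[[g]])
    } else cods[length(cods)] == spec$stops[[g]]
    internal <- cods[-c(1L, if (tail_len == 0L) length(cods))]
    if (!ok_start || !ok_stop || any(internal %in% MITO_STOPS)) {
      stop("infeasible spec: overlap constraints broke the codon ",
           "architecture of ", g, call. = FALSE)
    }
  }

  features <- do.call(rbind, lapply(seq_len(n_feat), function(i) {
    g <- walk[i]
    gene_feature(g, start[i], end[i], strand = strands[[g]],
                 gene_class = classes[[g]],
                 anticodon = if (g %in% names(TRNA_ANTICODONS)) {
                   TRNA_ANTICODONS[[g]]
                 } else NA_character_)
  }))
  genome <- mito_genome(sequence, features,
                        record_id = sprintf("SYN%s_s%d",
                                            sub("^A_", "", spec$species),
                                            spec$seed),
                        organism = paste("synthetic",
                                         sub("_", " ", spec$species)),
                        circular = TRUE, source = "synthetic")
  if (spec$origin_in_cr) {
    cr_i <- n_feat
    genome <- rotate_origin(genome,
                            start[cr_i] + lens[["CR"]] %/% 2L)
    start <- genome$features$start[match(walk, genome$features$name)]
    end <- genome$features$end[match(walk, genome$features$name)]
  }

  ground_truth <- build_ground_truth(genome, spec, walk, strands, classes,
                                     gap_of)
  list(genome = genome, ground_truth = ground_truth)
}

#' Rotate the origin of a circular genome
#'
#' Moves the sequence origin `shift` bases downstream; feature coordinates
#' follow, and features straddling the new origin become wrapping
#' features. Gap/overlap geometry and all composition statistics are
#' invariant under rotation.
#'
#' @param genome a circular [mito_genome()].
#' @param shift number of bases to rotate by (0 to length-1).
#' @return the rotated [mito_genome()].
#' @export
rotate_origin <- function(genome, shift) {
  stopifnot(genome$circular)
  L <- genome_length(genome)
  shift <- shift %% L
  if (shift == 0L) return(genome)
  sequence <- paste0(substr(genome$sequence, shift + 1L, L),
                     substr(genome$sequence, 1L, shift))
  f <- genome$features
  # a wrapping feature's end already sits left of its start, so the same
  # modular shift applies to both coordinates
  f$start <- ((f$start - shift - 1L) %% L) + 1L
  f$end <- ((f$end - shift - 1L) %% L) + 1L
  f$wraps_origin <- f$start > f$end
  genome$sequence <- sequence
  genome$features <- f
  validate_mito_genome(genome)
  genome
}

build_ground_truth <- function(genome, spec, walk, strands, classes,
                               gap_of) {
  sequence <- genome$sequence
  L <- nchar(sequence)
  f <- genome$features
  idx <- match(walk, f$name)
  slice <- function(i) {
    ft <- f[idx[i], ]
    s <- if (ft$wraps_origin) {
      paste0(substr(sequence, ft$start, L), substr(sequence, 1L, ft$end))
    } else {
      substr(sequence, ft$start, ft$end)
    }
    if (ft$strand == "N") rc_inline(s) else s
  }
  coding <- vapply(seq_along(walk), function(i) slice(i), character(1))
  names(coding) <- walk

  pcg <- walk[classes[walk] == "PCG"]
  codon_counts <- integer()
  starts_seen <- stops_seen <- character()
  for (g in pcg) {
    s <- coding[[g]]
    tail_len <- nchar(s) %% 3L
    cods <- substring(s, seq(1L, nchar(s) - tail_len, 3L),
                      seq(3L, nchar(s) - tail_len, 3L))
    starts_seen[g] <- cods[1]
    stops_seen[g] <- if (tail_len > 0L) {
      paste0(substring(s, nchar(s) - tail_len + 1L), "-")
    } else cods[length(cods)]
    if (tail_len == 0L) cods <- cods[-length(cods)]
    tab <- table(cods)
    codon_counts[setdiff(names(tab), names(codon_counts))] <- 0L
    codon_counts[names(tab)] <- codon_counts[names(tab)] +
      as.integer(tab)
  }

  region_seq <- list(
    whole = sequence,
    PCGs = paste(coding[pcg], collapse = ""),
    rrnL = coding[["rrnL"]], rrnS = coding[["rrnS"]],
    tRNA = paste(coding[walk[classes[walk] == "tRNA"]], collapse = ""),
    CR = coding[["CR"]])
  region_counts <- lapply(region_seq, count_inline)

  jg <- data.frame(
    upstream = walk,
    downstream = c(walk[-1], walk[1]),
    gap_bp = vapply(seq_along(walk), function(i) {
      gap_of(walk[i], walk[c(seq_along(walk)[-1], 1L)][i])
    }, integer(1)), stringsAsFactors = FALSE)

  list(
    genome_length = L,
    gene_table = data.frame(
      name = walk, gene_class = unname(classes[walk]),
      strand = unname(strands[walk]),
      start = f$start[idx], end = f$end[idx],
      length = unname(spec$gene_lengths[walk]),
      start_codon = unname(starts_seen[walk])[match(walk, walk)],
      stop_codon = unname(stops_seen[walk])[match(walk, walk)],
      stringsAsFactors = FALSE),
    junction_gaps = jg,
    region_counts = region_counts,
    codon_counts = codon_counts,
    strand_tally = lapply(split(strands[walk], classes[walk]),
                          function(s) c(n_J = sum(s == "J"),
                                        n_N = sum(s == "N"))),
    gene_order = spec$gene_order,
    cr = list(length = spec$gene_lengths[["CR"]],
              repeat_unit_bp = spec$cr_repeat_unit_bp,
              repeat_copies = spec$cr_repeat_copies))
}

#' Generate synthetic tRNA cloverleaf structures with ground truth
#'
#' Builds canonical four-arm cloverleafs (acceptor stem 7 bp; DHU stem 4 bp
#' / loop 7; anticodon stem 5 bp / loop 7 carrying the standard anticodon;
#' TpsiC stem 5 bp / loop 7), 74 nt each, with requested arms replaced by
#' an unpaired loop (68 nt). Each base pair is a G-U wobble with
#' probability `gu_rate`, otherwise Watson-Crick; the realized wobble count
#' is recorded as ground truth.
#'
#' @param seed integer RNG seed.
#' @param dropout named list/character: tRNA name to arm to drop ("DHU" or
#'   "TpsiC"), e.g. `list(trnS1 = "DHU")` (the default, the standard
#'   reduced serine tRNA).
#' @param gu_rate per-pair probability of a G-U wobble pair.
#' @param trna_names tRNAs to build (default all 22).
#' @return list with `structures` (list of `cloverleaf`) and `ground_truth`
#'   (data.frame `trna`, `dropped_arm`, `n_pairs`, `gu_pairs`; attribute
#'   `gu_total`).
#' @export
generate_trna_structures <- function(seed = 1L,
                                     dropout = list(trnS1 = "DHU"),
                                     gu_rate = 0.05,
                                     trna_names = TRNA_NAMES) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  structures <- list()
  gt <- data.frame(trna = character(), dropped_arm = character(),
                   n_pairs = integer(), gu_pairs = integer(),
                   stringsAsFactors = FALSE)
  for (nm in trna_names) {
    drop_arm <- dropout[[nm]] %||% NA_character_
    built <- build_cloverleaf(nm, TRNA_ANTICODONS[[nm]], gu_rate, drop_arm)
    structures[[nm]] <- built$structure
    gt <- rbind(gt, data.frame(trna = nm, dropped_arm = drop_arm,
                               n_pairs = built$n_pairs,
                               gu_pairs = built$gu_pairs,
                               stringsAsFactors = FALSE))
  }
  attr(gt, "gu_total") <- sum(gt$gu_pairs)
  list(structures = unname(structures), ground_truth = gt)
}

# draw one base pair; returns c(left, right) and whether it is a wobble
draw_pair <- function(gu_rate) {
  if (stats::runif(1) < gu_rate) {
    p <- sample(list(c("G", "U"), c("U", "G")), 1L)[[1]]
    list(pair = p, gu = TRUE)
  } else {
    p <- sample(list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G")),
                1L, prob = c(0.4, 0.4, 0.1, 0.1))[[1]]
    list(pair = p, gu = FALSE)
  }
}

draw_loop <- function(n) {
  sample(c("A", "U", "G", "C"), n, replace = TRUE,
         prob = c(0.4, 0.35, 0.1, 0.15))
}

build_cloverleaf <- function(name, anticodon, gu_rate, drop_arm) {
  gu <- 0L
  n_pairs <- 0L
  stem <- function(k) {
    left <- character(k)
    right <- character(k)
    for (i in seq_len(k)) {
      d <- draw_pair(gu_rate)
      left[i] <- d$pair[1]
      right[k - i + 1L] <- d$pair[2]
      if (d$gu) gu <<- gu + 1L
      n_pairs <<- n_pairs + k * 0L + 1L
    }
    list(left = left, right = right)
  }
  arm <- function(stem_n, loop_chars) {
    s <- stem(stem_n)
    list(seq = c(s$left, loop_chars, s$right),
         db = c(rep("(", stem_n), rep(".", length(loop_chars)),
                rep(")", stem_n)))
  }
  flat <- function(n) list(seq = draw_loop(n), db = rep(".", n))

  ac_loop <- draw_loop(7L)
  ac_rna <- seq_chars(chartr("T", "U", anticodon))
  ac_loop[3:5] <- ac_rna
  dhu <- if (identical(drop_arm, "DHU")) flat(9L) else arm(4L, draw_loop(7L))
  tpsic <- if (identical(drop_arm, "TpsiC")) flat(9L) else
    arm(5L, draw_loop(7L))
  anticodon_arm <- arm(5L, ac_loop)
  acc <- stem(7L)
  inner_seq <- c(draw_loop(2L), dhu$seq, draw_loop(1L), anticodon_arm$seq,
                 draw_loop(4L), tpsic$seq)
  inner_db <- c(rep(".", 2L), dhu$db, ".", anticodon_arm$db,
                rep(".", 4L), tpsic$db)
  seq <- paste(c(acc$left, inner_seq, acc$right, draw_loop(4L)),
               collapse = "")
  db <- paste(c(rep("(", 7L), inner_db, rep(")", 7L), rep(".", 4L)),
              collapse = "")
  list(structure = parse_dot_bracket(seq, db, name = name),
       n_pairs = n_pairs, gu_pairs = gu)
}
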