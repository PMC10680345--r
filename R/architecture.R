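# Gene architecture on the circle: junction gaps/overlaps, control-region
# location, strand tallies, gene-order encoding and breakpoint distances
# against the ancestral insect arrangement.

#' Junctions between consecutive features on the circle
#'
#' Features are sorted by start position; for each consecutive pair
#' (including the wrap-around pair on circular genomes) the gap is
#' `downstream start - upstream end - 1`: negative values are overlaps of
#' `|gap|` bp, zero is abutting, positive values are intergenic spacers.
#' Junctions flanking the control region are flagged `cr_adjacent` and
#' excluded from overlap/spacer summaries; a feature fully contained in its
#' predecessor is flagged `containment` with `gap_bp = NA`. When trnI is
#' annotated the rows are rotated to start at it, the conventional first
#' gene of the ancestral order.
#'
#' @param genome an annotated [mito_genome()] with at least 2 features.
#' @return data.frame with `upstream`, `downstream`, `gap_bp`,
#'   `cr_adjacent`, `containment`.
#' @export
junctions <- function(genome) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  n <- nrow(f)
  if (n < 2L) stop("need at least 2 features", call. = FALSE)
  L <- genome_length(genome)
  rows <- lapply(seq_len(n), function(i) {
    up <- f[i, ]
    down <- f[if (i < n) i + 1L else 1L, ]
    wrap_junction <- i == n
    contained <- !wrap_junction && !up$wraps_origin &&
      !down$wraps_origin && down$end <= up$end
    gap <- if (contained) {
      NA_integer_
    } else if (!wrap_junction || up$wraps_origin) {
      # a wrapping upstream feature already ends past the origin, so the
      # closing junction uses plain coordinates
      down$start - up$end - 1L
    } else {
      (L - up$end) + down$start - 1L
    }
    data.frame(upstream = up$name, downstream = down$name, gap_bp = gap,
               cr_adjacent = up$gene_class == "CR" ||
                 down$gene_class == "CR",
               containment = contained, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  i0 <- match("trnI", out$upstream)
  if (!is.na(i0) && i0 > 1L) {
    out <- out[c(i0:nrow(out), 1:(i0 - 1L)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Overlap summary over gene-gene junctions
#'
#' Counts junctions with negative gaps, excluding CR-flanking and
#' containment junctions.
#'
#' @param junctions a [junctions()] table.
#' @return list with `n_overlap_junctions`, `total_overlap_bp`,
#'   `max_overlap_bp`.
#' @export
overlap_summary <- function(junctions) {
  j <- junctions[!junctions$cr_adjacent & !junctions$containment &
                   !is.na(junctions$gap_bp) & junctions$gap_bp < 0L, ,
                 drop = FALSE]
  list(n_overlap_junctions = nrow(j),
       total_overlap_bp = sum(abs(j$gap_bp)),
       max_overlap_bp = if (nrow(j)) max(abs(j$gap_bp)) else 0L)
}

#' Intergenic-spacer summary over gene-gene junctions
#'
#' Counts junctions with positive gaps (CR-flanking and containment
#' junctions excluded); the longest spacer reports its flanking genes, ties
#' broken by first occurrence in junction order (which starts at trnI).
#'
#' @param junctions a [junctions()] table.
#' @return list with `n_spacers`, `total_spacer_bp`, `longest` (list of
#'   `upstream`, `downstream`, `bp`; `NULL` when there is no spacer).
#' @export
spacer_summary <- function(junctions) {
  j <- junctions[!junctions$cr_adjacent & !junctions$containment &
                   !is.na(junctions$gap_bp) & junctions$gap_bp > 0L, ,
                 drop = FALSE]
  longest <- NULL
  if (nrow(j)) {
    k <- which.max(j$gap_bp)
    longest <- list(upstream = j$upstream[k], downstream = j$downstream[k],
                    bp = j$gap_bp[k])
  }
  list(n_spacers = nrow(j), total_spacer_bp = sum(j$gap_bp),
       longest = longest)
}

#' Locate the control region
#'
#' Returns the annotated CR feature when present; otherwise synthesizes the
#' region spanning from the base after rrnS to the base before trnI
#' (circularly), the standard CR location in insect mitogenomes.
#'
#' @param genome an annotated [mito_genome()].
#' @return one-row feature data.frame with an extra `length` column; a
#'   degenerate (0 bp) region yields `NA` coordinates, length 0 and a
#'   warning.
#' @export
locate_control_region <- function(genome) {
  cr <- features_of_class(genome, "CR")
  if (nrow(cr) >= 1L) {
    out <- cr[1L, , drop = FALSE]
    out$length <- feature_lengths(genome, out)
    rownames(out) <- NULL
    return(out)
  }
  f <- genome$features
  rrnS <- f[f$name == "rrnS", , drop = FALSE]
  trnI <- f[f$name == "trnI", , drop = FALSE]
  if (nrow(rrnS) == 0L || nrow(trnI) == 0L) {
    stop("cannot locate control region: rrnS or trnI missing",
         call. = FALSE)
  }
  L <- genome_length(genome)
  start <- rrnS$end[1] %% L + 1L
  end <- (trnI$start[1] - 2L) %% L + 1L
  wraps <- start > end
  len <- if (wraps) (L - start + 1L) + end else end - start + 1L
  # rrnS abutting trnI on the circle leaves no room for a CR
  if ((rrnS$end[1] %% L) + 1L == trnI$start[1]) {
    warning("no control region: rrnS abuts trnI", call. = FALSE)
    out <- gene_feature("CR", 1L, 1L, strand = "J", gene_class = "CR")
    out$start <- NA_integer_
    out$end <- NA_integer_
    out$length <- 0L
    return(out)
  }
  out <- gene_feature("CR", start, end, strand = "J", gene_class = "CR",
                      wraps_origin = wraps)
  out$length <- len
  out
}

#' Strand tallies per gene class
#'
#' @param genome an annotated [mito_genome()].
#' @return data.frame with `gene_class`, `n_J`, `n_N`.
#' @export
strand_tally <- function(genome) {
  f <- genome$features
  classes <- intersect(c("PCG", "tRNA", "rRNA", "CR", "other"),
                       unique(f$gene_class))
  out <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(gene_class = cl,
               n_J = sum(f$gene_class == cl & f$strand == "J"),
               n_N = sum(f$gene_class == cl & f$strand == "N"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Circular gene order of a genome
#'
#' Genes (CR excluded) in circular order by start coordinate, rotated to
#' begin at trnI when present.
#'
#' @param genome an annotated [mito_genome()].
#' @return a `gene_order` (data.frame of `name`, `strand`).
#' @export
gene_order <- function(genome) {
  f <- genome$features[genome$features$gene_class != "CR", , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  if (anyDuplicated(f$name)) {
    stop("duplicate gene names: ",
         paste(unique(f$name[duplicated(f$name)]), collapse = ", "),
         call. = FALSE)
  }
  i0 <- match("trnI", f$name)
  if (!is.na(i0) && i0 > 1L) {
    f <- f[c(i0:nrow(f), 1:(i0 - 1L)), , drop = FALSE]
  }
  new_gene_order(f$name, f$strand)
}

# Canonical adjacency keys of a circular order. Strand-blind: unordered
# gene pair. Signed: oriented adjacency, identified with its reverse
# complement.
adjacency_keys <- function(order, signed = FALSE) {
  g <- order$name
  s <- order$strand
  n <- length(g)
  nxt <- if (n == 1L) 1L else c(2:n, 1L)
  vapply(seq_len(n), function(i) {
    j <- nxt[i]
    if (!signed) {
      paste(sort(c(g[i], g[j])), collapse = "|")
    } else {
      flip <- c(J = "N", N = "J")
      fwd <- paste(g[i], s[i], g[j], s[j], sep = "|")
      rev <- paste(g[j], flip[[s[j]]], g[i], flip[[s[i]]], sep = "|")
      min(fwd, rev)
    }
  }, character(1))
}

#' Breakpoint distance between two circular gene orders
#'
#' Number of gene adjacencies of `order_a` absent from `order_b`. The
#' default is strand-blind (adjacency = unordered gene pair), zero iff the
#' circular orders are rotations/reflections of each other; `signed = TRUE`
#' scores oriented adjacencies (an adjacency and its reverse complement are
#' identified), so inversions also count.
#'
#' @param order_a,order_b `gene_order` objects (or annotated
#'   [mito_genome()]s) over the same gene set.
#' @param signed use the strand-aware variant?
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(order_a, order_b, signed = FALSE) {
  order_a <- as_gene_order(order_a)
  order_b <- as_gene_order(order_b)
  dif <- c(setdiff(order_a$name, order_b$name),
           setdiff(order_b$name, order_a$name))
  if (length(dif)) {
    stop("gene sets differ: ", paste(unique(dif), collapse = ", "),
         call. = FALSE)
  }
  sum(!adjacency_keys(order_a, signed) %in% adjacency_keys(order_b, signed))
}

as_gene_order <- function(x) {
  if (inherits(x, "gene_order")) x else gene_order(x)
}

#' Rearrangements of a genome relative to a reference order
#'
#' @param genome an annotated [mito_genome()] or a `gene_order`.
#' @param reference_order reference `gene_order` (default ancestral insect
#'   order).
#' @param signed passed to [breakpoint_distance()].
#' @return list with `distance`, `broken_adjacencies` (data.frame
#'   `upstream`/`downstream`, empty when the orders agree) and
#'   `displaced_genes`.
#' @export
detect_rearrangement <- function(genome,
                                 reference_order = ancestral_gene_order(),
                                 signed = FALSE) {
  ord <- as_gene_order(genome)
  ref <- as_gene_order(reference_order)
  d <- breakpoint_distance(ord, ref, signed = signed)
  keys <- adjacency_keys(ord, signed)
  broken <- !keys %in% adjacency_keys(ref, signed)
  n <- nrow(ord)
  nxt <- if (n == 1L) 1L else c(2:n, 1L)
  ba <- data.frame(upstream = ord$name[broken],
                   downstream = ord$name[nxt][broken],
                   stringsAsFactors = FALSE)
  list(distance = d, broken_adjacencies = ba,
       displaced_genes = sort(unique(c(ba$upstream, ba$downstream))))
}
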