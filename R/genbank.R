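# GenBank flat-file reader/writer for annotated mitogenomes.
#
# A deliberately small parser: LOCUS, ORGANISM, the FEATURES table (simple,
# complement() and join() locations, including origin-spanning joins on
# circular molecules) and the ORIGIN sequence block. Feature keys CDS, tRNA,
# rRNA, misc_feature and D-loop are kept ("gene" and "source" entries
# duplicate these and are skipped); anything labelled as a control region,
# D-loop or A+T-rich region is classed CR.

FEATURE_KEY_CLASS <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       misc_feature = "CR", `D-loop` = "CR")

#' Read a GenBank flat file into a `mito_genome`
#'
#' @param path path to a GenBank flat file with an ORIGIN sequence block.
#' @param dialect optional gene-name alias overrides, passed to
#'   [canonicalize_gene_name()].
#' @return a [mito_genome()]; unrecognizable gene names are kept under their
#'   raw label and reported via a collected [warning()] (also attached as
#'   attribute `name_warnings`).
#' @export
read_genbank <- function(path, dialect = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("not a GenBank file: no LOCUS line",
                                  call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i[1]]), "[[:space:]]+")[[1]]
  record_id <- locus[2]
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  org_i <- grep("^ {0,2}ORGANISM", lines)
  organism <- if (length(org_i)) {
    trimws(sub("^ {0,2}ORGANISM[[:space:]]*", "", lines[org_i[1]]))
  } else ""

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) {
    stop("parse error: missing ORIGIN block in ", path, call. = FALSE)
  }
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else
    length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  features <- empty_features()
  name_warnings <- character()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    entries <- split_feature_entries(block)
    for (e in entries) {
      parsed <- parse_feature_entry(e, n, circular, dialect)
      if (is.null(parsed)) next
      features <- rbind(features, parsed$feature)
      name_warnings <- c(name_warnings, parsed$warning)
    }
  }
  if (nrow(features)) {
    bad <- features$start < 1L | features$start > n |
      features$end < 1L | features$end > n
    if (any(bad)) {
      stop(sprintf("coordinate error: feature '%s' outside [1, %d]",
                   features$name[bad][1], n), call. = FALSE)
    }
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (length(name_warnings)) {
    warning("non-canonical gene name(s) kept as-is: ",
            paste(unique(name_warnings), collapse = ", "), call. = FALSE)
  }
  g <- mito_genome(sequence, features, record_id = record_id,
                   organism = organism, circular = circular, source = path)
  attr(g, "name_warnings") <- unique(name_warnings)
  g
}

# Group the FEATURES block into one character vector per feature entry.
# A new entry starts with a feature key at column 6; continuation and
# qualifier lines are indented further.
split_feature_entries <- function(block) {
  starts <- grep("^ {5}[A-Za-z]", block)
  if (length(starts) == 0L) return(list())
  ends <- c(starts[-1] - 1L, length(block))
  Map(function(s, e) block[s:e], starts, ends)
}

parse_feature_entry <- function(entry, n, circular, dialect) {
  head <- strsplit(trimws(entry[1]), "[[:space:]]+")[[1]]
  key <- head[1]
  if (!key %in% names(FEATURE_KEY_CLASS)) return(NULL)
  # location may continue over lines until the first qualifier line
  qual_start <- grep("^[[:space:]]+/", entry)
  loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(entry)
  loc <- paste0(head[2],
                if (loc_end >= 2L)
                  paste(trimws(entry[2:loc_end]), collapse = "") else "")
  loc_parsed <- parse_location(loc, n)

  quals <- parse_qualifiers(entry[-seq_len(loc_end)])
  anticodon <- NA_character_
  if (!is.null(quals$anticodon)) {
    m <- regmatches(quals$anticodon,
                    regexpr("seq:[A-Za-z]+", quals$anticodon))
    if (length(m)) anticodon <- toupper(sub("seq:", "", m))
  }
  raw_name <- quals$gene %||% quals$product %||% quals$note %||% key
  canon <- canonicalize_gene_name(raw_name, anticodon, dialect)
  gene_class <- unname(FEATURE_KEY_CLASS[key])
  name <- as.character(canon)
  warn <- NULL
  if (gene_class == "CR") {
    name <- "CR"  # D-loop / control region / A+T-rich region dialects
  } else if (!isTRUE(attr(canon, "canonical"))) {
    warn <- raw_name
  }
  codon_start <- as.integer(quals$codon_start %||% "1")
  feat <- gene_feature(name, loc_parsed$start, loc_parsed$end,
                       strand = loc_parsed$strand, gene_class = gene_class,
                       wraps_origin = loc_parsed$wraps,
                       codon_start = codon_start, anticodon = anticodon,
                       raw_name = raw_name)
  list(feature = feat, warning = warn)
}

parse_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  txt <- trimws(lines)
  # merge continuation lines (not starting with "/") into prior qualifier
  out <- character()
  for (l in txt) {
    if (startsWith(l, "/") || length(out) == 0L) out <- c(out, l)
    else out[length(out)] <- paste(out[length(out)], l)
  }
  quals <- list()
  for (l in out) {
    m <- regmatches(l, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', l))[[1]]
    if (length(m) == 3L) quals[[m[2]]] <- m[3]
  }
  quals
}

# Parse a GenBank location string into start/end/strand/wraps on an n-bp
# (possibly circular) molecule.
parse_location <- function(loc, n) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- t(vapply(segs, parse_simple_range, integer(2)))
    if (nrow(rng) >= 2L && rng[1, 1] > rng[nrow(rng), 2] &&
        rng[nrow(rng), 1] == 1L) {
      wraps <- TRUE
      start <- rng[1, 1]
      end <- rng[nrow(rng), 2]
    } else {
      start <- min(rng[, 1])
      end <- max(rng[, 2])
    }
  } else {
    r <- parse_simple_range(loc)
    start <- r[1]
    end <- r[2]
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

parse_simple_range <- function(x) {
  parts <- strsplit(x, "..", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)  # single-base location
  as.integer(parts[c(1, 2)])
}

#' Write a `mito_genome` as a GenBank flat file
#'
#' Emits LOCUS, ORGANISM, a FEATURES table (PCGs as CDS, tRNA/rRNA under
#' their keys, CR as misc_feature annotated "control region") and the ORIGIN
#' block. Origin-wrapping features are written as `join(start..L,1..end)`;
#' N-strand features as `complement(...)`. The result re-reads to an
#' equivalent genome.
#'
#' @param genome a [mito_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  validate_mito_genome(genome)
  n <- genome_length(genome)
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %-16s %d bp    DNA     %s INV",
     genome$record_id, n, if (genome$circular) "circular" else "linear")
  wl("DEFINITION  %s mitochondrion.",
     if (nzchar(genome$organism)) genome$organism else genome$record_id)
  wl("  ORGANISM  %s",
     if (nzchar(genome$organism)) genome$organism else "unknown organism")
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", n)
  if (nzchar(genome$organism)) {
    wl("                     /organism=\"%s\"", genome$organism)
  }
  f <- genome$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      key <- switch(f$gene_class[i], PCG = "CDS", tRNA = "tRNA",
                    rRNA = "rRNA", CR = "misc_feature", "misc_feature")
      loc <- if (f$wraps_origin[i]) {
        sprintf("join(%d..%d,1..%d)", f$start[i], n, f$end[i])
      } else {
        sprintf("%d..%d", f$start[i], f$end[i])
      }
      if (f$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
      wl("     %-16s%s", key, loc)
      if (f$gene_class[i] == "CR") {
        wl("                     /note=\"control region\"")
      } else {
        wl("                     /gene=\"%s\"", f$name[i])
      }
      if (f$gene_class[i] == "PCG" && f$codon_start[i] != 1L) {
        wl("                     /codon_start=%d", f$codon_start[i])
      }
      if (!is.na(f$anticodon[i])) {
        wl("                     /anticodon=(pos:complement,aa:Xxx,seq:%s)",
           tolower(f$anticodon[i]))
      }
    }
  }
  wl("ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wl("%9d %s", p, tolower(paste(tens, collapse = " ")))
  }
  writeLines("//", con)
  invisible(path)
}
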