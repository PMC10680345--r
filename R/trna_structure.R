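# tRNA secondary structures are consumed as sequence + dot-bracket text
# (MITOS-style output), segmented into the cloverleaf arms (acceptor, DHU,
# anticodon, TpsiC), and base-pair types tallied (Watson-Crick, G-U wobble,
# mismatch). No folding is performed here.

ARM_NAMES <- c("acceptor", "DHU", "anticodon", "TpsiC")

#' Parse a dot-bracket secondary structure
#'
#' @param sequence nucleotide string (DNA or RNA; normalized internally to
#'   RNA, i.e. T becomes U).
#' @param structure dot-bracket string of the same length, using `.`, `(`
#'   and `)`.
#' @param name tRNA label carried through.
#' @return object of class `cloverleaf`: list with `trna_name`, `sequence`
#'   (U-normalized), `pairs` (two-column matrix of 1-based paired
#'   positions, i < j) and `arms` (`NULL` until [classify_arms()]).
#' @export
parse_dot_bracket <- function(sequence, structure, name = NA_character_) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  chars <- seq_chars(structure)
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    stop(sprintf("parse error: unexpected character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  stack <- integer()
  pairs <- matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("parse error: unmatched ')' at position %d", k),
             call. = FALSE)
      }
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    stop(sprintf("parse error: unmatched '(' at position %d",
                 stack[length(stack)]), call. = FALSE)
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(trna_name = name, sequence = sequence, pairs = pairs,
                 arms = NULL, anticodon_triplet = NA_character_),
            class = "cloverleaf")
}

#' Serialize a parsed structure back to dot-bracket
#'
#' @param structure a `cloverleaf`.
#' @return dot-bracket string.
#' @export
to_dot_bracket <- function(structure) {
  chars <- rep(".", nchar(structure$sequence))
  chars[structure$pairs[, 1]] <- "("
  chars[structure$pairs[, 2]] <- ")"
  paste(chars, collapse = "")
}

# Group the (nested) pair list into helices: runs of stacked pairs
# (i+1, j-1). Returns a list of pair-index vectors, 5'->3' by outer i.
find_helices <- function(pairs) {
  if (nrow(pairs) == 0L) return(list())
  helices <- list()
  cur <- 1L
  for (k in seq_len(nrow(pairs))[-1]) {
    prev <- cur[length(cur)]
    if (pairs[k, 1] == pairs[prev, 1] + 1L &&
        pairs[k, 2] == pairs[prev, 2] - 1L) {
      cur <- c(cur, k)
    } else {
      helices[[length(helices) + 1L]] <- cur
      cur <- k
    }
  }
  helices[[length(helices) + 1L]] <- cur
  helices
}

#' Segment a parsed tRNA structure into cloverleaf arms
#'
#' The outermost stem is the acceptor arm; hairpin stem-loops inside it are
#' assigned DHU, anticodon and TpsiC in 5' to 3' order (standard cloverleaf
#' topology). With only two inner stem-loops, the missing arm is identified
#' by position: loops sitting late in the molecule imply a missing DHU arm,
#' loops sitting early a missing TpsiC arm. The anticodon triplet is read
#' as the middle three bases of the anticodon loop when that loop has at
#' least 7 bases.
#'
#' @param structure a `cloverleaf` from [parse_dot_bracket()].
#' @return the structure with `arms` filled: data.frame with `arm`,
#'   `present`, `stem_pairs`, `loop_length`; attribute `non_cloverleaf` is
#'   set when no inner stem-loop exists. Structures with more than three
#'   inner stem-loops are flagged via attribute `extra_stem_loops`.
#' @export
classify_arms <- function(structure) {
  pairs <- structure$pairs
  n <- nchar(structure$sequence)
  helices <- find_helices(pairs)
  # hairpins: helices enclosing no other helix
  spans <- lapply(helices, function(h) {
    c(min(pairs[h, 1]), max(pairs[h, 2]))
  })
  encloses <- function(a, b) a[1] < b[1] && a[2] > b[2]
  is_hairpin <- vapply(seq_along(helices), function(i) {
    !any(vapply(seq_along(helices), function(j) {
      i != j && encloses(spans[[i]], spans[[j]])
    }, logical(1)))
  }, logical(1))
  hp <- which(is_hairpin)
  hp <- hp[order(vapply(spans[hp], `[`, numeric(1), 1))]
  # acceptor: helices enclosing every hairpin
  acc <- which(vapply(seq_along(helices), function(i) {
    length(hp) > 0L && all(vapply(hp, function(j) {
      i != j && encloses(spans[[i]], spans[[j]])
    }, logical(1)))
  }, logical(1)))
  arms <- data.frame(arm = ARM_NAMES, present = FALSE, stem_pairs = 0L,
                     loop_length = NA_integer_, stringsAsFactors = FALSE)
  out <- structure
  # a cloverleaf needs an enclosing acceptor stem with stem-loops inside it
  if (length(hp) == 0L || length(acc) == 0L) {
    out$arms <- arms
    attr(out, "non_cloverleaf") <- TRUE
    return(out)
  }
  arms$present[arms$arm == "acceptor"] <- TRUE
  arms$stem_pairs[arms$arm == "acceptor"] <- sum(lengths(helices[acc]))
  hairpin_info <- lapply(hp, function(i) {
    h <- helices[[i]]
    inner <- pairs[h[length(h)], ]
    list(stem_pairs = length(h),
         loop_start = inner[1] + 1L, loop_end = inner[2] - 1L,
         loop_length = inner[2] - inner[1] - 1L,
         mid = (spans[[i]][1] + spans[[i]][2]) / 2)
  })
  slot_names <- c("DHU", "anticodon", "TpsiC")
  assign <- assign_arm_slots(hairpin_info, spans, acc, n)
  if (length(hp) > 3L) attr(out, "extra_stem_loops") <- length(hp) - 3L
  for (k in seq_along(assign)) {
    slot <- slot_names[assign[k]]
    if (is.na(slot)) next
    info <- hairpin_info[[k]]
    arms$present[arms$arm == slot] <- TRUE
    arms$stem_pairs[arms$arm == slot] <- info$stem_pairs
    arms$loop_length[arms$arm == slot] <- info$loop_length
    if (slot == "anticodon" && info$loop_length >= 7L) {
      off <- info$loop_start + (info$loop_length - 3L) %/% 2L
      out$anticodon_triplet <- substr(structure$sequence, off, off + 2L)
    }
  }
  out$arms <- arms
  out
}

# Map hairpins (in 5'->3' order) onto the three inner-arm slots.
# 3 hairpins -> DHU, anticodon, TpsiC in order; 2 -> drop either DHU or
# TpsiC, whichever placement better matches the expected relative
# positions (~1/4, 1/2, 3/4 of the region inside the acceptor stem);
# 1 -> anticodon; >3 -> first/second/last.
assign_arm_slots <- function(hairpin_info, spans, acc, n) {
  k <- length(hairpin_info)
  if (k >= 3L) {
    out <- rep(NA_integer_, k)
    out[1] <- 1L
    out[2] <- 2L
    out[k] <- 3L
    return(out)
  }
  if (k == 1L) return(2L)
  lo <- 1L
  hi <- n
  if (length(acc)) {
    lo <- min(vapply(spans[acc], `[`, numeric(1), 1))
    hi <- max(vapply(spans[acc], `[`, numeric(1), 2))
  }
  rel <- vapply(hairpin_info, function(x) (x$mid - lo) / (hi - lo),
                numeric(1))
  expected <- c(0.25, 0.5, 0.75)
  cost_missing_dhu <- sum(abs(rel - expected[2:3]))
  cost_missing_tpsic <- sum(abs(rel - expected[1:2]))
  if (cost_missing_dhu < cost_missing_tpsic) c(2L, 3L) else c(1L, 2L)
}

#' Tally base-pair types of a structure
#'
#' A-U and G-C (either orientation) count as Watson-Crick, G-U/U-G as
#' wobble pairs, anything else (U-U, A-A, C-U, A-G, A-C...) as a mismatch.
#'
#' @param structure a `cloverleaf`.
#' @return named integer vector `c(watson_crick=, gu_wobble=, mismatch=)`.
#' @export
pair_type_tally <- function(structure) {
  chars <- seq_chars(structure$sequence)
  out <- c(watson_crick = 0L, gu_wobble = 0L, mismatch = 0L)
  if (nrow(structure$pairs) == 0L) return(out)
  for (k in seq_len(nrow(structure$pairs))) {
    b <- sort(chars[structure$pairs[k, ]])
    key <- paste(b, collapse = "")
    if (key %in% c("AU", "CG")) out["watson_crick"] <-
        out["watson_crick"] + 1L
    else if (key == "GU") out["gu_wobble"] <- out["gu_wobble"] + 1L
    else out["mismatch"] <- out["mismatch"] + 1L
  }
  out
}

#' Per-tRNA structure summary for a genome
#'
#' Joins annotated tRNA features with parsed structures (matched by name)
#' into one table; arm presence and pair-type columns are filled where a
#' structure is available.
#'
#' @param genome an annotated [mito_genome()].
#' @param structures list of `cloverleaf` objects (may be empty).
#' @return data.frame with one row per annotated tRNA (plus warning rows
#'   for structures without a matching annotation): `name`, `length`,
#'   `strand`, `has_structure`, arm-presence columns, pair-type counts and
#'   `anticodon`; attributes `min_length`/`max_length` give the annotated
#'   length range.
#' @export
summarize_trnas <- function(genome, structures = list()) {
  f <- features_of_class(genome, "tRNA")
  lens <- feature_lengths(genome, f)
  by_name <- stats::setNames(structures,
                             vapply(structures, function(s) s$trna_name,
                                    character(1)))
  unmatched <- setdiff(names(by_name), f$name)
  if (length(unmatched)) {
    warning("structure(s) without matching annotation: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  row_for <- function(name, len, strand) {
    s <- by_name[[name]]
    base <- data.frame(name = name, length = len, strand = strand,
                       has_structure = !is.null(s),
                       acceptor = NA, DHU = NA, anticodon_arm = NA,
                       TpsiC = NA, watson_crick = NA_integer_,
                       gu_wobble = NA_integer_, mismatch = NA_integer_,
                       anticodon = NA_character_, stringsAsFactors = FALSE)
    if (is.null(s)) return(base)
    if (is.null(s$arms)) s <- classify_arms(s)
    tally <- pair_type_tally(s)
    base$acceptor <- s$arms$present[s$arms$arm == "acceptor"]
    base$DHU <- s$arms$present[s$arms$arm == "DHU"]
    base$anticodon_arm <- s$arms$present[s$arms$arm == "anticodon"]
    base$TpsiC <- s$arms$present[s$arms$arm == "TpsiC"]
    base$watson_crick <- tally[["watson_crick"]]
    base$gu_wobble <- tally[["gu_wobble"]]
    base$mismatch <- tally[["mismatch"]]
    base$anticodon <- s$anticodon_triplet
    base
  }
  out <- do.call(rbind, c(
    lapply(seq_len(nrow(f)), function(i) {
      row_for(f$name[i], lens[i], f$strand[i])
    }),
    lapply(unmatched, function(nm) {
      r <- row_for(nm, NA_integer_, NA_character_)
      r$length <- nchar(by_name[[nm]]$sequence)
      r
    })))
  rownames(out) <- NULL
  attr(out, "min_length") <- if (nrow(f)) min(lens) else NA_integer_
  attr(out, "max_length") <- if (nrow(f)) max(lens) else NA_integer_
  out
}

#' Read MITOS-style tRNA structure text
#'
#' Plain text, three lines per tRNA: name (optionally prefixed with `>`),
#' sequence, dot-bracket. Blank lines are ignored.
#'
#' @param path input file.
#' @return list of parsed `cloverleaf` structures.
#' @export
read_trna_structures <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L) {
    stop("malformed structure file: expected blocks of 3 lines",
         call. = FALSE)
  }
  lapply(seq(1L, length(lines), by = 3L), function(i) {
    parse_dot_bracket(lines[i + 1L], lines[i + 2L],
                      name = sub("^>", "", lines[i]))
  })
}

#' Write tRNA structures in MITOS-style text
#'
#' @param structures list of `cloverleaf` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trna_structures <- function(structures, path) {
  lines <- unlist(lapply(structures, function(s) {
    c(paste0(">", s$trna_name), s$sequence, to_dot_bracket(s))
  }))
  writeLines(lines, path)
  invisible(path)
}
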