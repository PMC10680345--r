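# Gene-name canonicalization: annotation files spell the same 37 genes in
# many dialects (COI/COX1/cox1, ND2/nad2, 16S/l-rRNA/rrnL, tRNA-Ser/trnS...).
# Everything downstream works on one canonical vocabulary.

AA3_TO_1 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
              gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
              leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
              ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

# alias table keyed on a normalized form (lower case, alphanumerics only)
default_dialect_table <- function() {
  c(
    coi = "cox1", co1 = "cox1", cox1 = "cox1", coxi = "cox1",
    cytochromecoxidasesubunit1 = "cox1", cytochromecoxidasesubuniti = "cox1",
    coii = "cox2", co2 = "cox2", cox2 = "cox2", coxii = "cox2",
    cytochromecoxidasesubunit2 = "cox2", cytochromecoxidasesubunitii = "cox2",
    coiii = "cox3", co3 = "cox3", cox3 = "cox3", coxiii = "cox3",
    cytochromecoxidasesubunit3 = "cox3",
    cytochromecoxidasesubunitiii = "cox3",
    nd1 = "nad1", nad1 = "nad1", nadhdehydrogenasesubunit1 = "nad1",
    nd2 = "nad2", nad2 = "nad2", nadhdehydrogenasesubunit2 = "nad2",
    nd3 = "nad3", nad3 = "nad3", nadhdehydrogenasesubunit3 = "nad3",
    nd4 = "nad4", nad4 = "nad4", nadhdehydrogenasesubunit4 = "nad4",
    nd4l = "nad4l", nad4l = "nad4l", nadhdehydrogenasesubunit4l = "nad4l",
    nd5 = "nad5", nad5 = "nad5", nadhdehydrogenasesubunit5 = "nad5",
    nd6 = "nad6", nad6 = "nad6", nadhdehydrogenasesubunit6 = "nad6",
    cytb = "cob", cob = "cob", cytochromeb = "cob",
    atp6 = "atp6", atpase6 = "atp6", atpsynthasef0subunit6 = "atp6",
    atp8 = "atp8", atpase8 = "atp8", atpsynthasef0subunit8 = "atp8",
    rrnl = "rrnL", lrrna = "rrnL", `16s` = "rrnL", `16srrna` = "rrnL",
    `16sribosomalrna` = "rrnL", largesubunitribosomalrna = "rrnL",
    rrn16 = "rrnL",
    rrns = "rrnS", srrna = "rrnS", `12s` = "rrnS", `12srrna` = "rrnS",
    `12sribosomalrna` = "rrnS", smallsubunitribosomalrna = "rrnS",
    rrn12 = "rrnS",
    controlregion = "CR", dloop = "CR", atrichregion = "CR", cr = "CR",
    putativecontrolregion = "CR", noncodingregion = "CR")
}

# Anticodon (DNA, coding sense of the tRNA) -> serine/leucine isoacceptor.
SL_BY_ANTICODON <- c(GCT = "trnS1", TCT = "trnS1",  # AGN family
                     TGA = "trnS2",                  # UCN family
                     TAG = "trnL1",                  # CUN family
                     TAA = "trnL2")                  # UUR family

normalize_label <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Canonicalize a mitochondrial gene name
#'
#' Maps common annotation dialects onto the canonical 37-gene vocabulary
#' (see [canonical_gene_names()]): e.g. `COI`/`COX1` to `cox1`, `ND2` to
#' `nad2`, `16S`/`l-rRNA` to `rrnL`, `D-loop`/`A+T-rich region` to `CR`.
#' Serine and leucine tRNAs are disambiguated by anticodon: the AGN-decoding
#' serine (anticodon GCT/TCT) is `trnS1`, the UCN serine (TGA) `trnS2`, the
#' CUN leucine (TAG) `trnL1` and the UUR leucine (TAA) `trnL2`.
#'
#' @param raw_name annotation label (e.g. from `/gene` or `/product`).
#' @param anticodon optional anticodon triplet (DNA or RNA alphabet) used to
#'   resolve trnS/trnL; ignored otherwise.
#' @param dialect optional named character vector extending/overriding the
#'   built-in alias table (names are matched after lower-casing and removal
#'   of non-alphanumerics).
#' @return canonical label, with attribute `canonical` (logical). Unmappable
#'   names are returned unchanged with `canonical = FALSE`.
#' @export
canonicalize_gene_name <- function(raw_name, anticodon = NA_character_,
                                   dialect = NULL) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L, nzchar(raw_name))
  tab <- default_dialect_table()
  if (!is.null(dialect)) tab[normalize_label(names(dialect))] <- dialect
  key <- normalize_label(raw_name)
  if (key %in% names(tab)) {
    return(structure(unname(tab[key]), canonical = TRUE))
  }
  if (startsWith(key, "trn")) {
    rest <- substring(key, 4L)
    # "trna" may be a tRNA-Xxx prefix ("trnaser") or trnA followed by
    # nothing; try the un-stripped tail first so "trnala" resolves to Ala.
    cands <- unique(c(rest,
                      if (startsWith(rest, "a")) substring(rest, 2L)))
    for (tail in cands) {
      cand <- resolve_trna(tail, anticodon, key)
      if (!is.na(cand)) return(structure(cand, canonical = TRUE))
    }
  }
  structure(raw_name, canonical = FALSE)
}

resolve_trna <- function(tail, anticodon, key) {
  if (!nzchar(tail)) return(NA_character_)
  idx <- regmatches(tail, regexpr("[12]", tail))
  base <- gsub("[12]", "", tail)
  one <- NA_character_
  if (base %in% names(AA3_TO_1)) {
    one <- AA3_TO_1[[base]]
  } else if (substr(base, 1L, 3L) %in% names(AA3_TO_1)) {
    one <- AA3_TO_1[[substr(base, 1L, 3L)]]
  } else if (nchar(base) == 1L && toupper(base) %in% unname(AA3_TO_1)) {
    one <- toupper(base)
  }
  if (is.na(one)) return(NA_character_)
  if (!one %in% c("S", "L")) return(paste0("trn", one))
  if (length(idx) == 1L && nzchar(idx)) return(paste0("trn", one, idx))
  # codon-family tags carried in the raw label, e.g. "tRNA-Ser(AGN)"
  fam <- c(agn = "trnS1", ucn = "trnS2", ucu = "trnS1", gcu = "trnS1",
           cun = "trnL1", uur = "trnL2")
  for (tag in names(fam)) {
    if (grepl(tag, key, fixed = TRUE) &&
        substr(fam[[tag]], 4L, 4L) == one) {
      return(fam[[tag]])
    }
  }
  if (!is.na(anticodon)) {
    ac <- chartr("Uu", "Tt", toupper(anticodon))
    if (ac %in% names(SL_BY_ANTICODON)) {
      cand <- SL_BY_ANTICODON[[ac]]
      if (substr(cand, 4L, 4L) == one) return(cand)
    }
  }
  NA_character_
}
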