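---
title: "Comparative mitogenomics with mitocomp: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The analysis

Insect mitochondrial genomes are small circular molecules (~14-17 kb)
carrying a near-invariant inventory of 37 genes — 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs — plus one long non-coding, A+T-rich control
region (CR). Comparative mitogenomics summarizes a set of annotated
genomes through a standard battery of statistics: base composition and
strand skews per region, codon usage and relative synonymous codon usage
(RSCU) under the invertebrate mitochondrial genetic code, start/stop codon
architecture, gene overlaps and intergenic spacers around the circle,
strand distribution, gene order relative to the ancestral insect
arrangement, and tRNA cloverleaf structure features. `mitocomp` implements
that battery over GenBank-annotated genomes, with a seeded synthetic
genome generator so that every stage is testable without downloads. The
defaults throughout emulate the three *Abrus* leafhopper mitogenomes
(GenBank MZ274046, MZ274047, MK033020/NC_045238), whose published
per-gene lengths, junction geometry and composition provide the reference
values.

## Strand conventions

Coordinates are 1-based inclusive on the deposited plus strand, as in
GenBank; circular features may span the origin (`wraps_origin`), stored as
`join(start..L,1..end)` locations. The **J strand** is defined as the plus
strand of the deposited sequence and **N** as its complement, the standard
majority/minority convention for leafhopper mitogenomes. A feature's
*coding-sense* sequence is the plus-strand slice for J, the reverse
complement for N.

Skews are strand statistics,

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C},$$

so reverse-complementing a region negates both while leaving A+T content
unchanged. Published comparative tables rarely state which strand each
region's skew was computed on, and the rRNA/tRNA skew signs are only
reproducible under one convention. `region_summary()` therefore exposes
three conventions: `"plus"` (everything on the deposited strand),
`"coding"` (every gene region in coding sense), and the default
`"report"` (plus strand for the whole genome and CR, coding sense for the
PCG/rRNA/tRNA classes), so either reading of a published table can be
checked. Gene-class concatenations deliberately double-count overlapping
nucleotides — each gene contributes its full span — because published
region lengths (e.g. the 10,945 bp PCG total) are sums of per-gene
lengths that include overlaps. Ambiguity letters are excluded from all
composition numerators and denominators; empty denominators yield `NA`,
never zero.

## Codon-level rules

Translation uses NCBI table 5 (invertebrate mitochondrial: AGA/AGG = Ser,
ATA = Met, TGA = Trp; stops TAA/TAG), taken from
`Biostrings::getGeneticCode("5")`. Start codons are canonical iff `ATN`.
Stops are classified as the final complete codon when it is TAA/TAG;
otherwise a trailing `T` or `TA` is reported as the incomplete-stop marker
`T-`/`TA-` — these truncated stops are completed to TAA by
post-transcriptional polyadenylation, the standard reading of a PCG whose
length is not a multiple of 3 (cox2 here, 679 bp ≡ 1 mod 3). Anything
else is flagged `no_stop_found` rather than silently coerced.

Codon usage pools complete codons over all PCGs in coding sense, honouring
GenBank `codon_start` offsets, and **excludes terminal complete stop
codons and incomplete tails**. This rule is what makes the published
non-stop codon total internally consistent: 10,945 bp of PCGs with 12
complete stops and one 1-bp tail give (10,945 − 36 − 1)/3 = 3,636. The
analogous published total for the third genome (3,625) is not derivable
from its own per-gene lengths under any simple stop rule ((10,936 −
37)/3 = 3,633); the package documents rather than reproduces it, and no
test anchors on it.

RSCU for codon $c$ in synonymous family $F$ is
$\mathrm{RSCU}(c) = |F| \cdot n_c / \sum_{c' \in F} n_{c'}$; families with
zero usage get RSCU 0 and are flagged. Family sums then equal family
sizes, and the mean RSCU over codons of non-empty families is exactly 1 —
both are enforced as tests.

## Junctions, control region and gene order

Features sorted by start on the circle define junctions; the gap is
`downstream_start − upstream_end − 1` (negative = overlap, 0 = abutting,
positive = spacer), with the wrap-around junction corrected for the
origin. Overlap and spacer summaries use strict sign classes and exclude
the two CR-flanking junctions (published overlap/spacer counts cover
gene-gene junctions only, with the CR as its own region) and any feature
fully contained in its predecessor (so the circle-length identity — gene
lengths plus gaps equals genome length — stays meaningful). The CR is
returned as annotated, or synthesized as the span between rrnS and trnI,
its conserved location in these genomes.

Gene order is the circular sequence of the 37 genes (CR excluded) by
start coordinate, rotated to trnI. The breakpoint distance counts
adjacencies of one circular order absent from the other; the default is
strand-blind (unordered gene pairs — published comparisons discuss order,
not inversions), with a strand-aware variant (`signed = TRUE`) that
identifies an oriented adjacency with its reverse complement, so pure
inversions are visible to it. The strand-blind distance is symmetric,
rotation-invariant, and zero iff the circular orders agree up to
rotation/reflection; tests verify it against a brute-force adjacency
oracle on 100 random permutations of the 37-gene order.

## tRNA structures

Secondary structures are *consumed*, not predicted: MITOS-style text
(name / sequence / dot-bracket) is parsed into a nested pair list. Stacked
pairs form helices; hairpin helices inside the outermost (acceptor) stem
are assigned to the DHU, anticodon and TψC arms in 5′→3′ order. When only
two inner stem-loops exist, the missing arm is identified positionally:
the two observed loop midpoints are matched against the expected relative
positions (~¼, ½, ¾ of the region inside the acceptor stem), and
whichever of DHU/TψC fits worse is declared absent — this reproduces the
biologically expected calls (trnS1 lacking the DHU arm; a trnG variant
lacking the TψC arm). A structure with no enclosing stem or no inner
stem-loop is flagged non-cloverleaf; more than three inner stem-loops
(a paired variable loop, rare) is flagged, with the first/second/last
assigned. Pair types: A-U/G-C are Watson-Crick, G-U/U-G wobble, all else
mismatch; the three classes always partition the pair list. The published
per-genome G-U totals (35/36/26) refer to the MITOS foldings of the real
records and are only reproducible when those files are supplied; the test
suite exercises the tally on synthetic structures with known injected
wobble counts.

## The synthetic generator

`synthetic_spec()`/`generate_mitogenome()` define the study conditions:

* **Gene inventory and order** — the ancestral insect arrangement (as in
  *Drosophila yakuba*), with its strand assignments (14 J / 8 N tRNAs,
  9 J / 4 N PCGs, both rRNAs on N).
* **Lengths** — published per-gene PCG lengths (10,945 bp total for the
  default preset), rRNA and CR lengths per species. Per-tRNA lengths are
  not published individually; the defaults are a fixed vector in
  61–76 bp chosen once to sum to the published 1,441 bp tRNA total.
* **Junction geometry** — the published overlaps (e.g. trnD-atp8 = −7,
  nad2-trnW = −8; 11 junctions, 36 bp for the default preset) and the
  published longest spacer (trnC-trnY; 38/39/18 bp by species). The
  remaining six spacers are not individually published; the defaults
  (1, 1, 2, 3, 4, 8 bp at fixed junctions) were chosen once so the
  circle-length identity closes at exactly the published 16,391 bp for
  the default preset.
* **Composition** — per-base probabilities solve the targets
  analytically: $p_A = \mathrm{at}(1+s_{AT})/2$,
  $p_T = \mathrm{at}(1-s_{AT})/2$, $p_G = (1-\mathrm{at})(1+s_{GC})/2$,
  $p_C = (1-\mathrm{at})(1-s_{GC})/2$, with targets 76.2% A+T, AT-skew
  0.091, GC-skew −0.144 (the comparative-table values for the default
  preset; the CR uses its own 82.5%/0.011/−0.103). Targets apply to the
  deposited plus strand, so N-strand PCGs draw their codons from the
  complemented probabilities.
* **PCG architecture** — fixed published start codons, published stop
  types (complete TAA/TAG or T tail), internal codons rejection-filtered
  against TAA/TAG. Rejection removes two AT-rich triplets, which slightly
  depresses realized A+T and AT-skew relative to target — hence the
  GroundTruth records *realized* counts from the emitted sequence, and
  tolerance-based tests use them.
* **Overlaps as shared sequence** — one sequence, two features, as real
  records encode overlap. Unconstrained regions (tRNA/rRNA/CR) are
  written first and PCGs second, so codon architecture wins inside
  overlaps; afterwards every PCG is re-extracted and re-checked, and a
  spec whose overlaps cannot satisfy both flanking genes errors rather
  than emitting a broken genome. (The one PCG-PCG overlap among the
  published junctions, atp8-atp6 by 1 bp, is consistent: TA**A**
  overlapping **A**TG.)
* **Determinism** — one RNG stream seeded from `spec$seed`; the caller's
  RNG state is saved and restored.

`generate_trna_structures()` builds canonical 74-nt cloverleafs (acceptor
7 bp; DHU 4 bp/loop 7; anticodon 5 bp/loop 7 carrying the standard
anticodon; TψC 5 bp/loop 7), drops requested arms (68 nt), and injects
G-U wobble pairs at a configurable rate, recording the realized count.

### What the generator does and does not emulate

It reproduces the *architectural* and *marginal-composition* features the
analyses consume: lengths, order, strands, junction geometry, stop types,
region-level A+T and skews, CR repeats, reduced tRNA arms. It does **not**
emulate position-specific codon structure: codons are drawn iid from the
marginal base distribution, so the published codon-position A+T pattern
(P1 78.1 / P2 71.1 / P3 72.9, averaged over the three real genomes) and
the real amino-acid ranking (Ile/Met/Asn/Lys most frequent) do not emerge
— synthetic profiles are dominated by the 6-codon Leu/Ser families, as
expected under uniform draws. Passing tests therefore demonstrate correct
*computation* of codon-position composition and amino-acid ranking (via
hand-computed and ground-truth cases), not recovery of those published
values. Likewise there is no phylogenetic correlation between the three
species presets and no substitution model.

## Numerical and interface choices

* Percentages are reported raw and rounded to one decimal only at the
  presentation layer (`format_region_summary()`, `write_report()`); skews
  and RSCU to three decimals — the precision of the published tables.
  `write_report()` applies the same rounding to its TSV and JSON outputs
  so the two encodings carry identical numbers; full precision lives in
  the `compare_genomes()` object.
* Undefined ratios (empty regions, absent base pairs) are `NA` markers,
  never 0.
* Gene-name canonicalization uses an embedded dialect table (extensible
  per call via `dialect =`); serine/leucine tRNAs are disambiguated by
  anticodon (GCT/TCT → trnS1, TGA → trnS2, TAG → trnL1, TAA → trnL2).
  Unmappable names are kept raw and flagged, with a collected warning.
* Spacer ties are broken by first occurrence in junction order starting
  from trnI; amino-acid ranking ties alphabetically.
* The default genome preset does not place the CR across the origin
  (whether the real 2,035 bp CR spans the deposited origin is not
  stated in the published record description); `origin_in_cr = TRUE`
  generates the wrapped layout, and the parser and all downstream
  statistics handle both (junction gaps are rotation-invariant, enforced
  by test).

## Problem sizes

The test suite and acceptance script run at the study's own scale: full
16.4 kb genomes (single genomes for exact integer statistics; 20 seeded
genomes for composition/skew parameter recovery, where the mean A+T is
required within ±0.5 of target and per-genome AT-skew within ±0.05), 100
random 37-gene permutations for the breakpoint oracle, and 22-structure
tRNA sets. One genome generates in well under a second.

## Known limitations

* GenBank parsing covers the feature repertoire of mitogenome records
  (simple/complement/join locations, standard qualifiers); it is not a
  general GenBank parser (no multi-record files, no contig/assembly
  records).
* Annotation is consumed, never inferred: there is no gene finding, no
  MITOS invocation, no RNA folding.
* Rearrangement reporting is descriptive (broken adjacencies); no event
  inference (inversion/DCJ distances).
* CR tandem repeats are generated, not detected.
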