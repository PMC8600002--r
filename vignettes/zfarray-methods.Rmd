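---
title: "Genotyping minisatellite zinc-finger arrays from long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping minisatellite zinc-finger arrays from long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfarray)
```

## The problem

The DNA-binding domain of human PRDM9 is a tandem array of C2H2 zinc
fingers, each encoded by an 84-bp repeat unit; a PRDM9 *allele* is defined
by the sequence of this array. The array is a minisatellite: hypervariable,
highly repetitive, and refractory to short-read sequencing. zfarray
re-implements a long-read amplicon strategy for this locus: the array plus
670 bp of upstream and 137 bp of downstream flanking sequence is amplified
(1,899 bp for the 13-finger reference allele, whose array is
13 × 84 = 1,092 bp), dual-barcoded (8 inner primer barcodes × 96 outer PCR
barcodes = 768 addressable samples), sequenced with long reads, and the
diploid genotype of each individual is inferred in silico.

The hard parts are (i) PCR slippage, which yields abundant amplicons with
gained or lost repeat units, and (ii) alleles that differ by a single
nucleotide at equal array length. Slippage is handled *after* sequencing:
only reads carrying an uninterrupted, contiguous finger array between the
two fixed genomic flanks are retained, and a set of frequency rules over the
observed array lengths decides which one or two lengths are the true
haplotypes. Single-nucleotide heterozygotes are resolved by consensus
phasing.

## Read processing

**Demultiplexing.** Reads carry an outer then an inner barcode at the 5'
end (reverse complements at the 3' end). A read is assigned if and only if
exactly one (outer, inner) pair matches within Hamming budgets — 1 mismatch
for the 12-nt inner barcodes, 2 for the outer barcodes — searching both
orientations; ambiguous reads are binned as unassigned. The budgets are our
re-expression of the score cutoffs used by the vendor demultiplexers the
original workflow delegated to.

**Flank anchoring.** The 252-nt sequences immediately flanking the array
are located by Smith–Waterman local alignment (match +2, mismatch −3, gap
open −5, extend −2 — BLAST-like defaults; the primary implementation is an
Rcpp kernel, cross-checked in the test suite against
`Biostrings::pairwiseAlignment`). A hit must reach 75% identity over the
aligned span and cover at least half the anchor; how much of the printed
flank must align is not pinned down by the assay description, and
full-anchor local alignment with these floors is our reading. For speed the
search is seeded with exact 16-mers of the anchor and verified on a window;
a full-read alignment is the fallback (`find_flank(full_fallback = )`).
Strand is resolved as the orientation in which both flanks occur in order.
Reads lacking either flank, with disordered flanks, or whose inter-flank
interval cannot be tiled are rejected with a reason code.

**Unit tiling.** The inter-flank interval is decomposed greedily 5'→3' into
84-nt units by aligning catalog fingers at each offset. We use a *fitting*
alignment (finger anchored at both ends, read end free) rather than a free
local alignment so that sequencing errors at unit boundaries stay inside the
unit instead of creating spurious inter-unit gaps; the original pipeline's
BLAST step (word size 7, e-value 1) is re-expressed as a per-unit acceptance
gate of ≥ 50% of the 84 positions aligned at ≥ 75% identity. Read deletions
are padded with `N` to keep every unit 84 long — so all reads of the same
unit count are positionally aligned "for free" — and read insertions are
dropped; a contiguity requirement (no unmatched sequence between units,
`gap_tolerance` 0) enforces the "contiguous array" filter. Slippage products
pass extraction by design; they are *real* arrays of the wrong length, and
the length rules remove them.

## Diploid genotype inference

Individuals with fewer than 100 retained reads are not genotyped. The
observed unit-count frequencies (f_i ≥ f_j ≥ f_k, ties broken toward the
smaller count) are pushed through five rules processed consecutively:

| # | condition | haplotype lengths |
|---|-----------|-------------------|
| 1 | single observed length | (i, i) |
| 2 | f_i + f_j ≥ 0.7 and f_i / f_j < 2 | (i, j) |
| 3 | f_i + f_j ≥ 0.7 and f_i / f_j < 3 and f_j / f_k > 2 | (i, j) |
| 4 | f_i + f_j ≥ 0.7 and f_i / f_j > 3 | (i, i) |
| 5 | f_i ≥ 0.7 | (i, i) |

The strict/non-strict operators are taken verbatim, so a ratio of exactly 3
escapes rules 3 and 4 and can only be called by rule 5; with fewer than
three observed lengths f_k = 0 and f_j / f_k is treated as infinite. No rule
satisfied means no call. A brute-force tracer of the printed table is kept
in the test suite and checked against the implementation on 10⁴ random
tables.

Reads at the called length(s) are retained. When the two haplotype lengths
differ, each length's reads give a consensus directly (per position: modal
base among non-N observations; consensus frequency f_c = modal count /
non-N depth); an allele whose consensus has any f_c < 0.6 is discarded as
unreliable. When both haplotypes have the same length, the pooled consensus
is computed first: if every position has f_c ≥ 0.7 the individual is called
homozygous. Otherwise each read is restricted to the positions with
f_c < 0.7, pairwise Hamming distances are computed (N excluded pairwise),
and complete-linkage hierarchical clustering (`stats::hclust`) is cut at
the cluster count n ∈ [1, 19] minimising the mean within-cluster pairwise
distance, pooled over clusters. This objective is degenerate — once every
cluster is internally identical the mean is 0 for all larger n — so ties go
to the smallest n, singletons contribute no pairs, and cluster counts with
no within-cluster pairs at all are excluded; the two largest clusters are
taken as haplotypes, each requiring at least two supporting reads and a
full-length consensus with all f_c ≥ 0.7. The 0.6 floor applies only on the
unequal-length path and the 0.7 floor on the equal-length path, matching
the order in which the original procedure states them. The pipeline is
deterministic: reads are sorted by identifier before consensus and no step
draws random numbers.

Individuals where one haplotype passes and the other fails are retained
with per-allele qc flags (`qc = "partial"`) rather than dropped; the source
procedure does not say which was done, and retaining flagged partial calls
preserves information.

## Nomenclature

Fingers carry two-character codes; a consensus unit absent from the catalog
is minted a novel code `!A` … `!Z`, extended `!a` … `!z`, `!0` … `!9`, then
numbered (`!10`, …) so the space cannot be exhausted by simulation. Alleles
absent from the catalog are named `M1`, `M2`, … in discovery order (the
original indices' ordering across individuals is not documented; discovery
order is assumed). Variants from donor studies use five-part names,
`Av:c:0065:M2S:A-L20` = A-derived variant, complex, index 65, man 2 sperm,
parental genotype A/L20, with short form `Av:0065`. Allele equality is
defined on the DNA sequence, not the name; two names with identical DNA
raise a validation warning.

## A-type / C-type classification

Each C2H2 finger contacts DNA mainly through the residues at helix
positions −1, 3 and 6. The offsets of these residues within the 28-residue
unit are derived by anchoring on the conserved zinc-coordinating histidine
pair near the unit's C-terminus (first histidine at helix position 7, so
the contacts sit 8, 4 and 1 residues before it); they are config-overridable
and recorded in the output. An allele's profile is its ordered list of
3-residue tokens, one per finger. The similarity of a query to a reference
(PRDM9-A or PRDM9-C) is the global alignment score of the token lists —
match 1, mismatch 0, gap −0.5 — normalised by the reference's finger count;
the query is labelled by the better reference when that similarity reaches
0.5, else `untyped` (exact ties are also `untyped`). The alignment operates
on arbitrary token strings, so it is implemented directly rather than
through a biological-alphabet aligner. Scoring against the full reference
token list (not only fingers known to contact DNA) is a choice; the
alternative would restrict the reference profile to its documented binding
segment. The scheme is reflexive (self-similarity 1) and depends only on
residues, not on finger codes.

Cohort statistics use standard machinery: per-type array-length medians
with a two-sided Wilcoxon rank-sum test (normal approximation, continuity
and tie correction; `stats::wilcox.test`); allele frequencies as counts
over 2N with Clopper–Pearson 99% intervals (`stats::binom.test`; the
interval method behind the published "99% C.I." is unstated, and the exact
binomial is the conservative default); heterozygosity as the fraction of
qc-pass individuals with differing allele sequences; trio consistency as a
partition check of the child's pair against the parents' pairs; and
cross-set concordance as the fraction of individuals whose unordered allele
pairs agree, reported per zygosity category and overall.

## Template-switch derivation

A child allele is *derivable* from an ordered pair of parental alleles when
it can be written as alternating fragments of the two parents: the first
fragment is a prefix of the starting parent, the last runs to the 3' end of
the active parent, every fragment is longer than 15 nt (i.e. ≥ 16 — "longer
than" is read strictly), and consecutive fragments come from different
parents. A self-pair models a homozygous donor. The greedy engine
reproduces the published procedure — always take the longest match, first
anchored at the parent's 5' end, then anywhere in the alternate parent,
from both starting parents, unlimited switches (a configurable cap, default
50, guards runtime) — with ties between equally long matches broken to the
leftmost parent position. The procedure's step 3 says "longest common
subsequence"; we implement longest exact common *substring* anchored at the
child's current 5' end, which is the only reading under which the
re-concatenated fragments reproduce the child exactly (the package's path
validity invariant, fuzzed over 10³ instances in the tests).

Because the greedy engine is a heuristic, an exact dynamic program
(`min_switches_dp`) computes the true minimum switch count over all
admissible segmentations (breadth-first search over child-prefix × active-
parent states, using per-position maximal-extension tables). The tests
assert greedy ≥ dp everywhere and equality on planted recombinants whose
junctions lie in unique context. Catalog scans classify each child as
uni-parental, bi-parental (every best derivation needs both parents of a
pair), uni-or-bi (tie), or unreachable, and cohort summaries aggregate
minimal switch counts per parental-type class (A×A, A×C, C×C), reporting
per-pair minima and per-child minima — the published averages do not state
which was counted, so both are available.

## The simulator and the synthetic reference catalog

The simulator makes every module testable without external data. Simulated
fingers share a fixed C2H2-like scaffold (cysteines at residues 8/11,
histidines at 24/28, contact residues at 16/20/23), so units are homologous
like a real minisatellite; alleles are unit strings; reads are assembled as
outer barcode + inner barcode + 5' flank + array + 3' flank + reverse-
complemented barcodes, then subjected, in order, to whole-unit PCR slippage
(probability 0.10 per read; shifts ±1 with probability 0.35 each, ±2 with
0.15 each), per-base errors (substitution 0.01, insertion 0.005, deletion
0.005), truncation inside the array (0.02), and a random orientation flip.
The error rates are chosen to stress the 0.6/0.7 consensus floors without
overwhelming them at 150× coverage — roughly the regime in which merged
long-read data operates — and slippage is modelled as whole-unit gain/loss,
the artifact class the length rules are designed to absorb. The simulator
does not emulate base-quality structure, context-dependent error (e.g. the
CpG miscalls that motivated switching basecallers upstream of this tool),
chimeric reads, or partial-unit slippage; passing tests therefore
demonstrate correctness of the inference logic under a realistic error
budget, not robustness to every real-world artifact.

`synthetic_reference_catalog()` deterministically rebuilds a 71-allele
catalog with the documented *structure* of the human repertoire — A with 13
fingers, B one nucleotide from A (one amino acid, off the contact
residues), N = A minus one finger, C anchoring a C-type cluster at 15
fingers, L4 = C with four fingers duplicated non-adjacently, L14 with C's
intact contact profile, 50 A-lineage and 21 C-lineage alleles with length
medians 13 and 15 and disjoint contact-residue vocabularies apart from
shared terminal fingers. All sequences are synthetic; the catalog stands in
wherever the published allele tables would be read, and the planted lineage
is recorded so that classification and scan results can be checked against
construction.

## Numerical choices and problem sizes

Coordinates are 0-based half-open throughout. Alignment scores are
integral. Consensus ties break alphabetically; length-frequency ties break
toward the smaller unit count; greedy-match ties break leftmost — every
tie-break is deterministic, and rerunning any pipeline stage on the same
input reproduces its output byte-for-byte. The test suite and the
acceptance script exercise the full pipeline at 200 simulated individuals ×
150× coverage (the package's standard benchmark cohort), 10⁴ random
length-frequency tables, 10³ fuzzed switch-path instances, and 50 planted
recombinants; cross-platform concordance uses 40 individuals sequenced
twice and trio consistency 10 simulated trios.

## Known limitations

- Alleles shorter than one unit, or arrays whose true units deviate from
  84 bp, are outside the data model.
- The tiling gate (≥ 50% coverage at ≥ 75% identity per unit) assumes the
  catalog contains a homolog of every true finger; a wholly novel finger
  diverged beyond that gate would reject its reads rather than mint a code.
- The similarity threshold 0.5 for type labels was frozen against the
  synthetic catalog's planted structure; on real repertoires the
  config-exposed threshold and contact offsets may need revisiting.
- Quantities that depend on the content of the published allele tables or
  on the original sequencing cohort (e.g. exact population frequencies or
  switch-count averages of the real repertoire) are represented here only
  through their synthetic analogues.
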