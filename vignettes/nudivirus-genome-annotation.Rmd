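---
title: "Annotating and comparing circular nudivirus genomes with nudiannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and comparing circular nudivirus genomes with nudiannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nudiannot)
```

## The problem

Nudiviruses are non-occluded, rod-shaped dsDNA insect viruses, the sister
group of the baculoviruses. Their genomes are circular molecules of roughly
100–250 kb carrying on the order of a hundred protein-coding genes on both
strands. `nudiannot` implements the desk half of a genome project for such a
virus: calling ORFs on the circular molecule and filtering them down to a
credible gene set, finding tandem direct-repeat arrays (the *dr* elements
that stand in for the baculoviral *hr* repeats these viruses lack), scanning
proteins for the short degenerate motifs that support functional calls,
comparing the annotation against a close relative (gene parity, windowed
nucleotide identity, core-gene presence/absence, local gene-cluster layout),
and placing genes in distance-based phylogenies. A synthetic-genome
generator with known ground truth closes the loop: every stage of the
pipeline is validated against planted truth rather than against downloads.

The package ships the published annotation of the 231,621 bp HzNV-2 genome
(GenBank JN418988) as plain-text fixtures — the 113-row ORF table, the
six-row direct-repeat table and the 30-gene baculovirus core-gene catalog —
and its tests verify that the package's own statistics reproduce that
record: 66 forward / 47 reverse ORFs, one gene per 2.05 kb, 68% coding
density, a 1.4 kb mean ORF, and a 16-of-30 core-gene audit.

## ORF calling on a circular genome

`enumerate_orfs()` scans all six reading frames. Circularity is handled by
scanning a doubled copy of the sequence: every stop-bounded interval,
including the one through the origin, appears intact in the doubled copy,
and calls are deduplicated by requiring the start codon to lie in the first
copy. An ORF runs from an ATG to the codon before the next in-frame stop;
within each stop-bounded interval only the longest ORF (the first in-frame
ATG) is emitted. Two conventions matter and are used consistently:

* **Coordinates** are 1-based inclusive, and reverse-strand ORFs are
  recorded in coding orientation — `start` is the first base of the ATG on
  the coding strand, so `start > end` on the reverse strand. Conversion to
  `start <= end` happens only at the GFF3 boundary, where the coding start
  is preserved in an attribute.
* **Lengths** exclude the stop codon: a printed span of 3333 nt corresponds
  to 1111 aa. This is forced by every row of the packaged ORF table.

The default minimum length is 60 aa, the threshold used in the genome
record the package reproduces.

### Coding-potential filtering

Raw six-frame enumeration of a 230 kb genome yields several hundred
candidates; most short ones are noise. Candidates completely contained in a
longer ORF's footprint (either strand, circular-aware) are removed first.
The remaining candidates are scored with a hexamer log-odds model: the score
of a sequence is the mean of `log2 f_coding(h) / f_background(h)` over its
in-frame hexamers, in bits per hexamer. Coding frequencies are counted in
frame (offsets 0, 3, 6, …); background frequencies at every offset of both
strands of the genome; both are smoothed with an additive pseudocount
(default 1).

The model is self-trained by default: the seed coding set is all candidates
of at least 900 nt (long ORFs are almost never chance events), and one
re-estimation pass retrains on every candidate scoring above the threshold.
The default acceptance threshold is 0.0 bits/hexamer — "reads more like the
genome's genes than like the genome at large". A single interpretable score
with a configurable cutoff replaces the two-stage interpolated-Markov +
hexamer filtering used in the original genome project; scores from that
class of tools are version artifacts, whereas the hexamer statistic is
exactly defined and testable. For the same reason the intermediate
candidate counts of the original analysis are not reproduction targets,
though `annotate_genome()` logs its own stage counts in the same spirit
(enumerated → unnested → scored → final).

Finally, `resolve_overlaps()` enforces that no two surviving ORFs overlap
by more than 30% of the shorter member (the notion of "significant overlap"
is not standardized; the fraction is exposed as a parameter). While any
pair exceeds the threshold, the lower-scoring member of the worst pair is
removed, with deterministic tie-breaking (keep the longer, then the smaller
start).

`summarize_annotation()` computes the headline statistics. Coding density
deliberately does **not** merge overlapping spans — summing `length_nt`
over the packaged table and dividing by the genome length reproduces the
published 68% exactly, which indicates that convention. Gene clusters are
maximal same-strand runs with inter-ORF gaps of at most 2 kb; both knobs
are configurable because no formal cluster definition accompanies the
published count, and the packaged table yields a different cluster count
under this (or any simple) definition — the cluster statistic is reported,
not asserted.

## Tandem direct repeats

`find_tandem_repeats()` reconstructs consensus-scoring tandem-array
detection. For every unit size (default 10–100 bp) and phase, an array of
two units is grown by whole units while its score increases, where the
score compares every base against the per-column majority consensus:
`score = matches − mismatches`, ties resolved to the alphabetically first
base. Reports with score ≥ 100 (the conventional cutoff) are reduced to
local maxima: among overlapping reports only the highest-scoring survives,
ties preferring smaller units then smaller starts. Percent identity is
`100·matches/(unit·count)` and the consensus is reported in lower case, as
in the published repeat table.

The scan is exhaustive over unit sizes and phases, so the inner loop is
implemented in C++ (`src/tandem_scan.cpp`); an R-level exhaustive oracle
verifies it on short sequences in the test suite. The search is linear —
arrays wrapping the origin are not reported, and none occur in the packaged
table. The published score and %id values themselves are carried through
as-is, not recomputed: the exact denominator conventions of the original
tool are not recoverable, so only the span = unit × count arithmetic is
asserted.

## Motif scanning

One small grammar (`parse_pattern()`) normalizes the several notations in
which degenerate motifs are commonly written: literals, `x`/`X` wildcards,
repeat counts in both `x4` and `(3x)` styles, `Q/N` alternatives, `U` for
the bulky hydrophobics {F,I,L,M,V,W,Y}, IUPAC ambiguity codes in DNA mode,
and dashes/parentheses as separators. Single-residue patterns are accepted
(the packaged catalog contains catalytic single residues such as "E").
`scan_motif()` reports all, possibly overlapping, hits left to right and is
checked against an independently built regular-expression oracle.

`upstream_search()` scans the window (default 500 bp) 5' of an ORF's start
codon on its coding strand, circular-aware, for a DNA motif (default
`TAAG`, the baculovirus late-promoter core), returning genome coordinates.
`hydropathy_segments()` is a deliberately plain Kyte–Doolittle
sliding-window heuristic (window 19, threshold 1.6) for
transmembrane-like stretches — trained predictors are out of scope, and no
signal-peptide or topology calls are produced. `cysteine_profile()` reports
alignment columns whose non-gap residues are (by default all) cysteine, the
standard quick check for conserved disulfide scaffolds. The packaged
`motif_catalog()` records one reported motif span with an internally
inconsistent end coordinate (412–122); the catalog stores the evident
correction 412–422 and notes the typo rather than asserting the original.

## Two-genome comparison

* `parity()` reduces an ortholog mapping to its colinearity: the number of
  genes in the longest strictly increasing run of subject ordinals (a
  longest-increasing-subsequence statistic, computed by patience sorting
  and verified against a DP oracle), plus counts of descending steps and
  breakpoints.
* `window_identity()` tiles the ungapped base sequence into fixed windows
  (default 100 bp) over a supplied pairwise alignment and computes percent
  identity per window, counting gap columns as mismatches; windows at or
  above 95% are flagged. Both choices — tiling and gaps-as-mismatches —
  are the minimal reading of a windowed identity plot. Because windows are
  tiles of the genome that *has* a unique region, profiling an insert-bearing
  genome against its partner shows the insert as a contiguous run of
  near-zero windows.
* `global_align()` provides standard affine-gap global alignment
  (match +1, mismatch −1, gap open −5, extend −1; a k-base gap costs
  open + k·ext) via `Biostrings::pairwiseAlignment`, verified against a
  textbook three-state DP oracle. It is intended for ≤ ~100 kb; for
  genome-scale comparisons an externally produced alignment is supplied to
  `window_identity()` directly — the synthetic ortholog generator returns
  its implied alignment for exactly this purpose.
* `core_gene_audit()` marks each of the 30 catalog genes present iff an
  annotation row's predicted-function text matches its name or an alias at
  a word boundary, case-insensitively, grouped by the six functional
  categories. `alignment_identity()` reports identity both over alignment
  columns and over base positions, since either denominator is defensible
  for a genome-pair identity figure; both are labelled.
* `compare_gene_neighborhood()` compares a small set of shared genes
  between two layouts: relative order, strand relative to the anchor gene,
  and distances (both ways around for circular genomes).

## Phylogenetics

Distances are p-distances — mismatches over columns where both rows are
ungapped — the minimal-assumption choice when no substitution model is
asserted. `nj_tree()` implements Saitou–Nei neighbor joining with pinned
semantics: ties in the Q criterion go to the lowest-index pair, and
negative branch lengths are clamped to zero with the deficit transferred to
the sister branch. NJ is consistent on additive matrices, and the tests
exploit that: trees regenerated from their own cophenetic matrices must be
recovered exactly (topology and path lengths), and an independent NJ
implementation (`ape::nj`) must agree on topology. `bootstrap_support()`
resamples alignment columns, rebuilds NJ trees and reports bipartition
frequencies on the unrooted tree, deterministically for a given seed;
all-identical alignments are flagged as degenerate rather than decorated
with meaningless supports. `concat_alignments()` builds concatenated
multi-gene matrices (partition boundaries recorded), and
`root_with_outgroup()` re-roots at the midpoint of the outgroup's pendant
edge, leaving the bipartition set unchanged.

## The synthetic-data generator

`genome_spec()` defaults describe the study system: a circular 231,621 bp
genome at 41.9% G+C carrying 113 genes, with gene lengths drawn from a
clipped lognormal (median ~360 aa, range 63–1900 aa) chosen to give the
observed ~1.4 kb mean gene and ~2 kb/gene density. Genes receive a
deterministic biased codon usage (within each amino acid, codons get
geometrically decaying weights), which is what gives real genes their
hexamer signature; intergenic sequence is i.i.d. at the target G+C. Each
gene is planted with an in-frame TAA directly upstream of its ATG, so the
planted start is the first ATG of its stop-bounded interval and recovery
can be scored by exact coordinates. Repeat arrays are planted in intergenic
gaps and mutated at a stated per-base rate. `make_ortholog()` applies
point substitutions (each hit becomes one of the other three bases
uniformly, so divergence 0.065 means 93.5% expected identity) and one
novel inserted block at a recorded position, returning the full edit log
and the implied alignment. `make_protein_family()` evolves a uniform root
sequence down a given tree with per-site substitution probability
`1 − exp(−rate·branch length)`, uniform over the other 19 residues.

What the generator does **not** emulate: indels within genes, codon-usage
heterogeneity along the genome, transition/transversion bias, repeat
families with diverged units, and overlapping genes. Passing the recovery
tests therefore shows the pipeline is correct under its stated model, not
that its thresholds are optimal for any particular real genome.

## Numerical choices and test scale

All randomness sits behind explicit integer seeds; generators restore the
caller's RNG state. Scores and distances are plain doubles; the repeat
score and LIS statistics are exact integers. The test suite works at sizes
chosen to keep the full run in minutes while leaving the statistics sharp:
oracle equivalence for ORF calling on 5–15 kb genomes, exhaustive repeat
oracles on ≤ 2 kb sequences (with reduced unit ranges and cutoffs, since
oracle equivalence is parameter-free), 500 LIS permutations up to n = 200,
alignment oracles on ≤ 200 bp pairs, 20 gene-recovery replicates on 30 kb
genomes with 10 genes each, one full-scale 231,621 bp ortholog comparison,
50 + 20 additive-matrix NJ recoveries, 100 seeded 8-taxon topology
recoveries, and 200-replicate bootstraps. The published summary statistics
(row arithmetic, strand counts, densities, core-gene audit) are exact
checks against the packaged tables.

## Known limitations

* The ORF caller assumes a standard genetic code and ATG initiation; no
  ribosome-binding or promoter model is used.
* Cluster counts depend on an explicit gap/strand definition and are
  reported descriptively.
* The repeat finder reports maximal arrays under a strictly-increasing
  extension rule; arrays whose first two units are heavily diverged can be
  reported with a shifted phase (the local-maxima reduction keeps the
  best-scoring placement, which for a periodic array may begin a few bases
  before or after the planted origin).
* Window identity charges partner insertions to the window they interrupt;
  per-window identity near insertion breakpoints is therefore conservative.
* NJ with p-distances is a deliberately minimal pipeline; for saturated
  alignments a corrected distance should be substituted before joining.
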