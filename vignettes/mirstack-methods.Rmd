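---
title: "mirstack: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirstack: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstack)
```

mirstack re-implements, as plain auditable R, the analysis chain used to
profile known miRNAs and discover novel ones from small RNA sequencing of
three related cell types (early endothelial progenitor cells, late EPCs,
mature endothelial cells). This vignette explains what each stage computes,
why the defaults are what they are, and what the synthetic benchmark does
and does not demonstrate.

## Read filtration and collapsing

A library of small-RNA reads is dominated by ~18–24 nt mature miRNAs ligated
to a 3' adapter, contaminated by mRNA degradation fragments, poly-A
artifacts and adapter dimers. The filtration cascade evaluates, per read and
in a fixed order:

1. **adapter5** — the 5' adapter occurs (exact substring starting within the
   first `max_adapter_flank` bases); such reads are ligation artifacts.
2. **no_adapter3** — the read neither ends in a 6–18 nt prefix of the 3'
   adapter nor contains the complete adapter (read-through). The 6 nt
   minimum keeps the match specific (a 4^-6 chance match per position); the
   18 nt maximum reflects the longest flank a ~36 nt read of a ≥18 nt insert
   can carry.
3. **ambiguous** — more than `max_ambiguous` (default 0) non-ACGT bases in
   the trimmed insert.
4. **polyA** — a terminal A-run of ≥ 8 nt, or an insert that is ≥ 80 % A
   (covers pure-A inserts shorter than the run threshold). "Poly-A tract"
   is operationalized this way because oligo-dA artifacts present either as
   full A-reads or as A-tailed fragments.
5. **length** — trimmed insert outside 18–26 nt: mature miRNAs are 18–24 nt;
   2 nt of slack admits edge isomiRs without letting in tRNA/snoRNA halves.

Adapter matching is exact. A mismatch-tolerant flank match is deliberately
not implemented: it would complicate the brute-force oracle that the adapter
search is verified against, and at these flank lengths a single sequencing
error simply shifts the read into the (small) `no_adapter3` fraction.

The filter order affects only the per-rule accounting, never the kept set;
the report records the order used and satisfies
`input = kept + sum(discarded)` exactly. Base qualities are parsed and
carried along but not used — no quality filter is part of this design.

Kept inserts are collapsed to unique tags (count-descending, then
lexicographic, ids `t1, t2, …`), which makes all downstream work independent
of read order.

## Alignment and partitioning

Tags are placed full-length and ungapped with at most one substitution, on
both strands, using a k = 8 seed index with two non-overlapping seed windows
per query — by pigeonhole any placement with ≤ 1 mismatch is guaranteed to
be seeded for tags ≥ 16 nt. The aligner is verified in the test suite
against an independent full-scan (`Biostrings::matchPattern`) on the whole
toy genome.

Partitioning follows the discovery logic: tags matching known precursors are
"known" (miRNA precedence over mRNA), remaining tags matching the mRNA set
are discarded as degradation products, and the rest is aligned to the
genome; only genome-placed unannotated tags feed discovery. Coordinates are
1-based closed throughout, the GRanges/GFF3 convention of the Bioconductor
stack this package is built on.

## Known miRNA quantification and RPM

A tag placement is assigned to an annotated mature miRNA when it lies on the
same strand fully within the mature interval widened by 2 nt on the 5' side
and 5 nt on the 3' side — the asymmetric window reflects how isomiR
variability concentrates at the 3' end. A tag with M qualifying placements
contributes `count / M` to each, so the total assigned read mass is
conserved exactly (this identity is asserted by the pipeline manifest and
the test suite).

Expression is normalized as `RPM = C / (M N) × 1e9`, with N the reads of
genome-mapped non-mRNA tags. Because the 1/M split already happens at
counting time, the pipeline calls `rpm_normalize` with M = 1; passing the
per-tag M again would double-discount, which the API documents and the
tests guard. The 1e9 scale is kept exactly as the formula this package
follows prints it, and is a configuration knob (`rpm_scale`) for users who
prefer a literal per-million scale.

## Novel discovery

Unannotated placements are clustered into stacks by single-linkage with a
30 nt gap — comfortably larger than a terminal loop (3–20 nt), so both arms
of one precursor always land in one stack, and much smaller than the 200 nt
spacing between genuine loci. Around the dominant read (highest count,
leftmost on ties) two windows are excised: 15 nt upstream + 70 nt downstream
(dominant product = 5' arm) and the mirror (3' arm). 70 nt is enough for a
24 nt partner arm plus a 20 nt loop plus slack; only one of the two windows
can contain the full hairpin, and the other reliably fails the structural
rules, so both are simply scored.

### Folding

Windows are folded by maximum-weight non-crossing pairing (GC = 3, AU = 2,
GU = 1, minimum loop 3 nt) — base-pair maximization in the Nussinov style
rather than thermodynamic minimum free energy. The objective is chosen for
verifiability: the optimum is reproduced by exhaustive enumeration over all
valid structures for every test sequence up to 16 nt, an oracle a
thermodynamic model cannot offer without importing its parameter tables.
The traceback is deterministic (pairing preferred over leaving a base
unpaired on ties; among equal partners the innermost is taken). Reported
features: dot-bracket, weighted score, longest run of stacked pairs, and
the main hairpin loop — the terminal loop enclosed by the most pairs, which
makes the features robust to incidental flanking structure in a 107 nt
window.

### Evidence partitioning and the two predictors

The mature product is the dominant read; the star interval is the region
pairing with the mature across the stem shifted for the canonical 2 nt 3'
overhang; the loop lies between the arms. Every placement is assigned to
the category containing ≥ 80 % of its span, else counted inconsistent —
with ±1 nt isomiR jitter a 22 nt read still overlaps its category at 95 %.

Predictor A (additive score, default weights 2/4/10/3/6, threshold 5):

```
scoreA = 2·log2(1 + mature_count) + 4·consistent_fraction
       + 10·(fold_score / window_length) + 3·[star evidence]
       - 6·inconsistent_fraction
```

Predictor B (hard rules): mature length 18–26 nt; mature on one arm of the
main hairpin; longest stem ≥ 14 bp; loop 3–20 nt; fold density ≥ 0.25;
mature count ≥ 5; inconsistent fraction ≤ 0.2. The arm rule tolerates a
2 nt overhang past the loop-closing pair (`arm_slack`): when the +1-shifted
isomiR happens to be the most abundant tag its last base crosses the loop
boundary, and Dicer products genuinely do extend into the loop; without the
slack a strict reading rejects real hairpins on a read-sampling coin flip.

These are simplified, fully specified analogues of the two external
predictors whose intersection the original pipeline used; numeric outputs
are not expected to match any external tool — what is reproduced is the
consensus architecture: a call requires `passA AND passB`, overlapping
consensus loci (≥ 50 % reciprocal overlap) are merged keeping the higher
scoreA, and survivors are named `miR-N1, miR-N2, …` in genome order.
"Manual inspection" of the original workflow is replaced by the ranked
candidate report that accompanies every run.

## Expression patterns and exact tests

Expression is strict `RPM > 100`. Fold changes are computed on
pseudocounted RPM (default +1) so zeros are defined; classification is
homogeneous in scale (multiplying RPM, threshold and pseudocount by one
constant changes nothing). The eight classes are evaluated
specificity-first (expressed in exactly one cell type), then monotonic
up/down (≥ 1.5-fold at *both* steps), then the late/EC-high plateau
(late/EC within 1.5-fold of each other, both ≥ 1.5-fold over early), then
not-expressed, else expressed-unclassified — exactly one class per miRNA,
asserted over random matrices.

Mann–Whitney U and Wilcoxon signed-rank tests are exact for small samples
(≤ 10 combined, ≤ 12 pairs by default): the permutation distribution of the
midrank statistic is built by a generating-function convolution over doubled
midranks, and two-sided p-values take the deviation from the null mean.
Larger samples fall back to the normal approximation with tie and
continuity corrections (numerically identical to `wilcox.test`). Zero
differences are dropped; two-sided p-values throughout.

## The synthetic benchmark

`simulation_spec()` defaults define the reference study: a 50 kb genome
with 30 known precursors (annotated), 5 novel hairpins (truth only) and 50
decoy mRNA transcripts, all ≥ 200 nt apart; 50,000 reads per cell type —
85 % miRNA reads (8 % of them from novel loci), 6 % mRNA fragments, 1 %
poly-A artifacts; per-base error 0.001, 5' jitter ±1 nt, star products at
8 % of each locus (star evidence exists, mature dominance holds);
abundances log-normal (shared base sd 1.5 × cell effect sd 0.8). The depth
is a deliberate desk-scale stand-in for multi-million-read libraries; all
benchmark properties are defined at this scale.

Planted hairpins have one single-nucleotide bulge near the stem base, and
the generator rejects draws whose maximum-weight fold is not the intended
single-loop stem. The bulge is not cosmetic: with a perfect stem the two
arms are exact reverse complements, so mature tags map antisense onto the
star arm and create phantom opposite-strand loci; the bulge base is chosen
non-complementary to the mature bases it could line up against, and loop
termini are non-complementary for the same reason. Real precursors are
imperfect in just this way.

What passing the benchmark shows: the pipeline's bookkeeping is exact, rank
order of abundances survives preprocessing/alignment/normalization, and the
consensus caller separates planted hairpins from mRNA decoys at this noise
level. What it does not show: performance on real libraries with ligation
bias, quality-dependent errors, isomiR ends beyond ±1 nt, repeat-dense
genomes, or annotation ambiguity.

## Numerical and degenerate-input choices

* Fold scores are integer-valued sums stored as doubles; traceback equality
  tests are exact.
* `collapse_reads` breaks count ties lexicographically; stack dominance
  breaks ties leftmost; consensus merging orders by score then position —
  every output is invariant to input order, and reruns are byte-identical
  (no timestamps in result files; logs go to stderr).
* Empty inputs flow through: an empty FASTQ yields zero counts and a
  warning, zero unannotated tags yield an empty GFF3, both with success.
* All randomness derives from the single spec/config seed via fixed
  per-stage offsets (seed + 1000·cell-index, etc.), keeping derived seeds
  in 32-bit range.
* The test suite and the acceptance script use the default study sizes
  (3 × 50,000 reads, 50 kb genome) — chosen as the package's reference
  conditions; unit tests use smaller studies of the same shape.

## Known limitations

* Ungapped alignment, ≤ 1 substitution, no isomiR cataloguing, no SAM/BAM.
* Base-pair maximization is not a thermodynamic model; a hook for swapping
  in an external folder is the candidate `fold` slot, but cross-checking
  against such a folder is out of scope here.
* No conservation scoring of novel candidates and no multiple-testing
  correction across miRNAs — neither is part of the workflow this package
  reproduces.
* Single-process execution; per-sample parallelism would preserve
  byte-identical outputs only with per-sample seeding, so it is left out.
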