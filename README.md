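# mirstack

Small RNA-seq analysis for three-condition endothelial-lineage designs:
read filtration and collapsing, known-miRNA quantification with
multi-mapping-aware RPM normalization, consensus novel-miRNA discovery from
genomic read stacks with hairpin verification, and expression pattern
classification — plus a fully seeded synthetic-data generator so the whole
pipeline is testable at desk scale without external data.

## Who this is for

Groups profiling miRNAs by small RNA sequencing across a small number of
related cell types (here: early endothelial progenitor cells, late EPCs and
mature endothelial cells) who want a transparent, fully reproducible
re-implementation of the classic two-predictor discovery pipeline rather
than a black-box tool chain.

## The method

**Preprocessing.** Reads are kept when they carry no 5' adapter, end in a
6–18 nt prefix of the 3' adapter (or contain the full adapter,
read-through), and their trimmed insert has no ambiguous bases, no poly-A
tract, and length 18–26 nt. Kept inserts are collapsed to unique tags with
read multiplicities; a per-rule report guarantees
`input = kept + Σ discarded`.

**Quantification.** Tags are aligned full-length (0–1 substitutions, both
strands) with a k-mer seed index. Tags matching known miRNA precursors are
quantified; tags matching mRNA are discarded as degradation products; the
remainder goes to discovery. A tag placement counts toward an annotated
mature miRNA when it falls within the mature interval ±(2, 5) nt
(strand-aware); a tag with M qualifying placements contributes `count / M`
to each. Expression is normalized as

    RPM = C / (M · N) × 10^9

with C the read count assigned to the miRNA, M the multi-mapping factor
(already applied at counting time, so M = 1 there), and N the total reads
mapped to the genome.

**Novel discovery.** Unannotated genomic placements are clustered into read
stacks (gap ≤ 30 nt). Around each stack's dominant read two candidate
precursor windows are excised (dominant product on the 5' or 3' arm), folded
by weighted base-pair maximization (GC = 3, AU = 2, GU = 1, minimum loop
3 nt — a Nussinov-style dynamic program with an exactly enumerable
objective), and the stack is partitioned into mature / star / loop /
inconsistent evidence using the fold's pairing and the canonical 2 nt 3'
overhang. Two independent predictors vote: an additive scorer over read
support, consistency and fold density, and a hard rule filter over mature
length, stem length, loop size, fold density and read counts. Only
candidates passing **both** are called, merged at 50 % reciprocal overlap,
and named `miR-N1, miR-N2, …` in genome order with `-5p`/`-3p` products.

**Patterns.** Known miRNAs with RPM > 100 (strict) are "expressed"; each
miRNA is classified into exactly one of eight classes (cell-type-specific,
monotonic up/down at 1.5-fold per step, late/EC-high plateau, not expressed,
unclassified) on pseudocounted RPM, and the three-set Venn partition is
reported. Exact small-sample Mann–Whitney U and Wilcoxon signed-rank tests
(full enumeration with midrank ties) are included for group comparisons.

## Worked example

Simulate the reference study (50 kb genome, 30 known + 5 novel miRNA loci,
50 decoy mRNAs, 3 × 50,000 reads) and run the whole pipeline:

```r
library(mirstack)

spec <- simulation_spec(seed = 1)
sim  <- build_genome(spec)
write_simulation(sim, "study")

config <- validate_config(list(
  genome_fasta = "study/genome.fa",
  mrna_fasta   = "study/mrna.fa",
  mirna_fasta  = "study/mirna_precursors.fa",
  mirna_gff    = "study/annotations.gff3",
  samples      = list(early_EPC = "study/early_EPC.fastq",
                      late_EPC  = "study/late_EPC.fastq",
                      EC        = "study/EC.fastq"),
  cell_order   = c("early_EPC", "late_EPC", "EC"),
  output_dir   = "study/out",
  filter       = list(adapter3 = spec$adapter3)))

res <- run_all(config)
sum(res$novel$candidates$called)      # 5   (all planted novel loci)
dim(res$known$rpm_matrix)             # 30 miRNAs x 3 cell types
table(res$patterns$calls$class)       # pattern classes across the 30 miRNAs
```

On this run the three libraries keep ~97 % of reads (the rest are the
simulated poly-A artifacts, adapter failures and length outliers), all 30
known miRNAs are quantified with RPM rank order matching the planted
abundances (Spearman ≥ 0.99 per cell type), and the consensus caller
recovers all 5 planted novel hairpins with no false calls. `study/out/`
contains per-sample filter reports and collapsed FASTA, count and RPM
matrices, the candidate report with both predictor verdicts, consensus
calls as GFF3 with dot-bracket structures, pattern and Venn tables, and
JSON manifests with the full read-accounting chain. Reruns with the same
config are byte-identical.

A thin CLI wraps the same functions:

```sh
Rscript exec/mirstack simulate --seed 1 --out study
Rscript exec/mirstack run-all --config run.yaml
```

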