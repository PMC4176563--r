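# Shared study fixtures, built in code and cached for the session.

.study_cache <- new.env(parent = emptyenv())

# the reference desk-scale study: default simulation spec, seed 1
reference_study <- function() {
  if (!is.null(.study_cache$ref)) return(.study_cache$ref)
  spec <- simulation_spec(seed = 1L)
  sim <- build_genome(spec)
  dir <- file.path(tempdir(), "mirstack_ref_study")
  write_simulation(sim, dir)
  config <- validate_config(list(
    genome_fasta = file.path(dir, "genome.fa"),
    mrna_fasta = file.path(dir, "mrna.fa"),
    mirna_fasta = file.path(dir, "mirna_precursors.fa"),
    mirna_gff = file.path(dir, "annotations.gff3"),
    samples = list(early_EPC = file.path(dir, "early_EPC.fastq"),
                   late_EPC = file.path(dir, "late_EPC.fastq"),
                   EC = file.path(dir, "EC.fastq")),
    cell_order = c("early_EPC", "late_EPC", "EC"),
    output_dir = file.path(dir, "out"),
    log_level = "quiet",
    filter = list(adapter3 = spec$adapter3)))
  res <- run_all(config)
  .study_cache$ref <- list(spec = spec, sim = sim, dir = dir,
                           config = config, result = res)
  .study_cache$ref
}

# a small fast study for pipeline mechanics tests
small_study <- function(seed = 11L, dir = file.path(tempdir(),
                                                    paste0("mirstack_small_", seed))) {
  spec <- simulation_spec(seed = seed, genome_length = 20000L, n_known = 8L,
                          n_novel = 2L, n_mrna_decoys = 10L,
                          reads_per_sample = 2000L)
  sim <- build_genome(spec)
  write_simulation(sim, dir)
  config <- validate_config(list(
    genome_fasta = file.path(dir, "genome.fa"),
    mrna_fasta = file.path(dir, "mrna.fa"),
    mirna_fasta = file.path(dir, "mirna_precursors.fa"),
    mirna_gff = file.path(dir, "annotations.gff3"),
    samples = list(early_EPC = file.path(dir, "early_EPC.fastq"),
                   late_EPC = file.path(dir, "late_EPC.fastq"),
                   EC = file.path(dir, "EC.fastq")),
    cell_order = c("early_EPC", "late_EPC", "EC"),
    output_dir = file.path(dir, "out"),
    log_level = "quiet",
    filter = list(adapter3 = spec$adapter3)))
  list(spec = spec, sim = sim, dir = dir, config = config)
}

toy_rules <- function() {
  filter_rules(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
               adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
}

toy_fixture_path <- function() {
  p <- system.file("extdata", "toy12.fastq", package = "mirstack")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata", "toy12.fastq")
}

# recall/false-call bookkeeping against the planted truth
novel_call_stats <- function(called, truth_novel) {
  recovered <- vapply(seq_len(nrow(truth_novel)), function(i) {
    any(called$start <= truth_novel$start[i] &
          called$end >= truth_novel$end[i] &
          called$strand == truth_novel$strand[i] &
          called$chrom == truth_novel$chrom[i])
  }, logical(1))
  decoy <- vapply(seq_len(nrow(called)), function(j) {
    !any(truth_novel$start >= called$start[j] &
           truth_novel$end <= called$end[j] &
           truth_novel$strand == called$strand[j] &
           truth_novel$chrom == called$chrom[j])
  }, logical(1))
  list(n_recovered = sum(recovered), n_truth = nrow(truth_novel),
       n_decoy_calls = sum(decoy), n_called = nrow(called))
}
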