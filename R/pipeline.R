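# Pipeline orchestration.
#
# A YAML run configuration drives the stages: preprocess each sample,
# partition tags against mRNA/miRNA/genome references, quantify and
# RPM-normalize known miRNAs, discover novel miRNAs from the pooled
# unannotated stacks, and classify expression patterns.  All result files
# are written atomically and carry no timestamps, so a rerun with the same
# configuration is byte-identical; a JSON manifest records settings and the
# per-stage read accounting.

.CONFIG_SCHEMA <- list(
  top = c("genome_fasta", "mrna_fasta", "mirna_fasta", "mirna_gff",
          "samples", "cell_order", "output_dir", "seed", "log_level",
          "rpm_scale", "filter", "alignment", "discovery", "patterns"),
  filter = c("adapter3", "adapter5", "min_adapter_flank",
             "max_adapter_flank", "polya_min_run", "max_ambiguous",
             "min_len", "max_len"),
  alignment = c("k", "max_mismatch"),
  discovery = c("max_gap", "score_threshold", "min_mature_count",
                "min_stem", "min_loop", "max_loop", "min_density",
                "max_inconsistent_frac", "min_stack_count"),
  patterns = c("expr_threshold", "fc", "pseudocount")
)

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes an equivalent named list), checks every key
#' against the schema (unknown keys are errors, never silently ignored),
#' verifies referenced paths, fills defaults and validates bounds.
#'
#' @param config path to a YAML file or a named list.
#' @return a fully-defaulted list of class \code{run_config}; errors list
#'   every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  errors <- character(0)
  unknown <- setdiff(names(config), .CONFIG_SCHEMA$top)
  if (length(unknown))
    errors <- c(errors, paste0("unknown key: ", unknown))
  for (sec in c("filter", "alignment", "discovery", "patterns")) {
    bad <- setdiff(names(config[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(bad))
      errors <- c(errors, paste0("unknown key: ", sec, ".", bad))
  }
  required <- c("genome_fasta", "mrna_fasta", "mirna_fasta", "mirna_gff",
                "samples", "output_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    errors <- c(errors, paste0("missing required key: ", missing))
  if (!("adapter3" %in% names(config$filter)))
    errors <- c(errors, "missing required key: filter.adapter3")
  for (key in c("genome_fasta", "mrna_fasta", "mirna_fasta", "mirna_gff")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      errors <- c(errors, paste0("path does not exist: ", key, " = ", p))
  }
  if (!is.null(config$samples)) {
    if (anyDuplicated(names(config$samples)))
      errors <- c(errors, "duplicate sample labels")
    for (s in names(config$samples)) {
      if (!file.exists(config$samples[[s]]))
        errors <- c(errors, paste0("path does not exist: samples.", s,
                                   " = ", config$samples[[s]]))
    }
    if (!is.null(config$cell_order) &&
        !all(unlist(config$cell_order) %in% names(config$samples)))
      errors <- c(errors, "cell_order contains labels not in samples")
  }
  if (length(errors)) stop("invalid configuration:\n  ",
                           paste(errors, collapse = "\n  "))

  defaults <- list(seed = 1L, log_level = "info", rpm_scale = 1e9,
                   cell_order = names(config$samples))
  config <- utils::modifyList(defaults, config)
  fr <- do.call(filter_rules, config$filter)   # validates bounds
  al <- utils::modifyList(list(k = 8L, max_mismatch = 0L),
                          as.list(config$alignment))
  dv <- utils::modifyList(list(max_gap = 30L, score_threshold = 5,
                               min_mature_count = 5, min_stem = 14L,
                               min_loop = 3L, max_loop = 20L,
                               min_density = 0.25,
                               max_inconsistent_frac = 0.2,
                               min_stack_count = 3),
                          as.list(config$discovery))
  pt <- do.call(pattern_config,
                utils::modifyList(list(cell_order = unlist(config$cell_order)),
                                  as.list(config$patterns)))
  config$filter <- fr
  config$alignment <- al
  config$discovery <- dv
  config$patterns <- pt
  config$cell_order <- unlist(config$cell_order)
  structure(config, class = "run_config")
}

.log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[mirstack] ", ...)
}

.atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the known-miRNA quantification pipeline
#'
#' For every sample: read and filter the FASTQ, collapse to tags, partition
#' tags against the miRNA precursor, mRNA and genome references, count known
#' miRNAs with 1/M-weighted assignment and normalize to RPM (N = reads of
#' genome-mapped non-mRNA tags).  Writes per-sample filter reports and
#' collapsed FASTA, the count and RPM matrices, per-sample unannotated
#' genomic hits (the novel-discovery input) and a JSON manifest with the
#' full read-accounting chain.
#'
#' @param config a validated \code{\link{validate_config}} object.
#' @return invisible list with matrices, partitions, hits and the manifest.
#' @export
run_known_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- as.character(Biostrings::readDNAStringSet(config$genome_fasta))
  names(genome) <- sub("\\s.*$", "", names(genome))
  mrna <- as.character(Biostrings::readDNAStringSet(config$mrna_fasta))
  names(mrna) <- sub("\\s.*$", "", names(mrna))
  mirna <- as.character(Biostrings::readDNAStringSet(config$mirna_fasta))
  names(mirna) <- sub("\\s.*$", "", names(mirna))
  ann <- read_mirna_annotations(config$mirna_gff)

  k <- config$alignment$k
  mm <- config$alignment$max_mismatch
  .log(config, "building indices (k = ", k, ")")
  gidx <- build_index(genome, k = k, name = "genome")
  midx <- build_index(mirna, k = k, name = "mirna")
  xidx <- build_index(mrna, k = k, name = "mrna")

  records <- list(); manifest_samples <- list()
  unann_hits <- list(); partitions <- list()
  for (s in names(config$samples)) {
    .log(config, "sample ", s, ": preprocessing")
    reads <- read_fastq(config$samples[[s]])
    pp <- preprocess_sample(reads, config$filter)
    if (!nrow(pp$tags)) warning("sample ", s, ": no reads kept")
    part <- partition_tags(pp$tags, xidx, midx, gidx, max_mismatch = mm)
    known_tags <- pp$tags[pp$tags$tag_id %in% part$known_mirna_tags, ,
                          drop = FALSE]
    khits <- if (nrow(known_tags))
      align_tags(known_tags, gidx, max_mismatch = mm) else .empty_hits()
    N <- sum(pp$tags$count[pp$tags$tag_id %in%
                             c(unique(khits$tag_id),
                               part$unannotated_tags)])
    counts <- count_known_mirnas(khits, ann, seqlens = nchar(genome))
    rpm <- if (N > 0)
      rpm_normalize(counts$raw_count, M = 1, N = N,
                    scale = config$rpm_scale) else counts$raw_count * 0
    records[[s]] <- data.frame(mirna_name = counts$mirna_name, sample = s,
                               count = counts$raw_count, rpm = rpm,
                               stringsAsFactors = FALSE)
    .atomic_write(function(p) write_filter_report(pp$report, p),
                  file.path(config$output_dir,
                            paste0(s, ".filter_report.tsv")))
    .atomic_write(function(p) write_collapsed_fasta(pp$tags, p),
                  file.path(config$output_dir, paste0(s, ".collapsed.fa")))
    uh <- part$genome_hits
    .atomic_write(function(p) utils::write.table(uh, p, sep = "\t",
                                                 quote = FALSE,
                                                 row.names = FALSE),
                  file.path(config$output_dir,
                            paste0(s, ".unannotated_hits.tsv")))
    unann_hits[[s]] <- uh
    partitions[[s]] <- part
    rep0 <- pp$report
    manifest_samples[[s]] <- list(
      fastq = config$samples[[s]],
      input_reads = rep0$reads[rep0$rule == "input"],
      discarded = as.list(stats::setNames(
        rep0$reads[!rep0$rule %in% c("input", "kept")],
        rep0$rule[!rep0$rule %in% c("input", "kept")])),
      kept_reads = rep0$reads[rep0$rule == "kept"],
      unique_tags = nrow(pp$tags),
      tag_partition = list(
        known_mirna = length(part$known_mirna_tags),
        mrna = length(part$mrna_tags),
        unannotated = length(part$unannotated_tags),
        unaligned = length(part$unaligned_tags)),
      genome_mapped_reads = N,
      mirna_assigned_read_mass = attr(counts, "assigned_tag_mass"),
      mirna_count_sum = sum(counts$raw_count))
  }
  all_rec <- do.call(rbind, records)
  count_mat <- build_expression_matrix(
    data.frame(mirna_name = all_rec$mirna_name, sample = all_rec$sample,
               value = all_rec$count, stringsAsFactors = FALSE))
  rpm_mat <- build_expression_matrix(
    data.frame(mirna_name = all_rec$mirna_name, sample = all_rec$sample,
               value = all_rec$rpm, stringsAsFactors = FALSE))
  .atomic_write(function(p) write_matrix_tsv(count_mat, p),
                file.path(config$output_dir, "known_counts.tsv"))
  .atomic_write(function(p) write_matrix_tsv(rpm_mat, p),
                file.path(config$output_dir, "known_rpm.tsv"))
  manifest <- list(
    stage = "known_quantification",
    settings = list(seed = config$seed, k = k, max_mismatch = mm,
                    rpm_scale = config$rpm_scale,
                    filter = unclass(config$filter)),
    samples = manifest_samples)
  .atomic_write(function(p) jsonlite::write_json(manifest, p,
                                                 auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE),
                file.path(config$output_dir, "manifest_known.json"))
  invisible(list(count_matrix = count_mat, rpm_matrix = rpm_mat,
                 records = all_rec, partitions = partitions,
                 unannotated_hits = unann_hits, annotations = ann,
                 genome = genome, manifest = manifest))
}

#' Run the novel-miRNA discovery pipeline
#'
#' Pools the unannotated genomic hits of all samples, drops placements on
#' known precursor loci, and runs consensus discovery.  Writes the full
#' candidate report (both predictor verdicts per candidate), consensus calls
#' as GFF3, hairpin structures as dot-bracket text, and a manifest with the
#' per-step candidate accounting.
#'
#' @param config a validated \code{\link{validate_config}} object.
#' @param known optional result of \code{\link{run_known_pipeline}} (rerun
#'   otherwise).
#' @return invisible list with the candidate table and discovery result.
#' @export
run_novel_pipeline <- function(config, known = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(known)) known <- run_known_pipeline(config)
  pooled <- do.call(rbind, lapply(names(known$unannotated_hits), function(s) {
    h <- known$unannotated_hits[[s]]
    if (nrow(h)) h$tag_id <- paste0(s, "|", h$tag_id)   # ids are per-sample
    h
  }))
  if (is.null(pooled)) pooled <- .empty_hits()
  rownames(pooled) <- NULL
  dv <- config$discovery
  res <- discover_novel_mirnas(
    known$genome, pooled, known_precursors = known$annotations$precursors,
    max_gap = dv$max_gap, score_threshold = dv$score_threshold,
    rule_args = list(min_mature_count = dv$min_mature_count,
                     min_stem = dv$min_stem, min_loop = dv$min_loop,
                     max_loop = dv$max_loop, min_density = dv$min_density,
                     max_inconsistent_frac = dv$max_inconsistent_frac),
    min_stack_count = dv$min_stack_count)
  cand <- res$candidates
  .atomic_write(function(p) utils::write.table(
    cand[setdiff(names(cand), "structure")], p, sep = "\t", quote = FALSE,
    row.names = FALSE),
    file.path(config$output_dir, "novel_candidates.tsv"))
  .atomic_write(function(p) export_novel_gff(cand, p),
                file.path(config$output_dir, "novel_calls.gff3"))
  db <- unlist(lapply(which(cand$called %in% TRUE), function(i) {
    d <- res$details[[i]]
    c(paste0(">", cand$name[i]), d$fold$sequence, d$fold$structure)
  }))
  .atomic_write(function(p) writeLines(if (is.null(db)) character(0) else db,
                                       p),
                file.path(config$output_dir, "novel_structures.txt"))
  manifest <- list(
    stage = "novel_discovery",
    settings = dv,
    accounting = list(
      pooled_unannotated_placements = nrow(pooled),
      read_stacks = res$n_stacks,
      folded_candidates = nrow(cand),
      passA = sum(cand$passA), passB = sum(cand$passB),
      consensus = sum(cand$consensus),
      called_after_merge = sum(cand$called)))
  .atomic_write(function(p) jsonlite::write_json(manifest, p,
                                                 auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE),
                file.path(config$output_dir, "manifest_novel.json"))
  invisible(list(candidates = cand, discovery = res, manifest = manifest,
                 known = known))
}

#' Classify expression patterns and write the pattern outputs
#'
#' @param config a validated \code{\link{validate_config}} object.
#' @param rpm_matrix RPM matrix (from \code{\link{run_known_pipeline}}).
#' @return invisible list with the classification table and Venn partition.
#' @export
run_classify <- function(config, rpm_matrix) {
  pc <- config$patterns
  calls <- classify_patterns(rpm_matrix, pc)
  expressed <- call_expressed(rpm_matrix[, pc$cell_order, drop = FALSE], pc)
  venn <- venn_partition(expressed)
  .atomic_write(function(p) utils::write.table(calls, p, sep = "\t",
                                               quote = FALSE,
                                               row.names = FALSE),
                file.path(config$output_dir, "pattern_calls.tsv"))
  venn_df <- data.frame(region = names(venn$counts),
                        n = as.integer(venn$counts),
                        members = vapply(venn$members, paste,
                                         character(1), collapse = ","),
                        stringsAsFactors = FALSE)
  .atomic_write(function(p) utils::write.table(venn_df, p, sep = "\t",
                                               quote = FALSE,
                                               row.names = FALSE),
                file.path(config$output_dir, "venn_regions.tsv"))
  invisible(list(calls = calls, venn = venn))
}

#' Run the complete pipeline
#'
#' \code{\link{run_known_pipeline}}, then \code{\link{run_novel_pipeline}},
#' then \code{\link{run_classify}}.
#'
#' @param config a config path, list, or validated \code{run_config}.
#' @return invisible list with all stage results.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  known <- run_known_pipeline(config)
  novel <- run_novel_pipeline(config, known)
  patt <- run_classify(config, known$rpm_matrix)
  invisible(list(known = known, novel = novel, patterns = patt,
                 config = config))
}
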