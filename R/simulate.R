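# Synthetic small-RNA study generator.
#
# Builds a toy genome with planted known miRNA precursors (annotated),
# planted novel hairpins (ground truth only), and decoy mRNA transcripts,
# then draws per-cell-type read libraries with Drosha/Dicer-consistent
# stacking: mature-dominant reads with small 5' jitter, a minor star
# fraction, substitution errors, 3'-adapter read-through and poly-A
# artifacts.  Everything is deterministic under the single spec seed.

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation specification
#'
#' Defaults define the reference desk-scale study: a 50 kb genome, 30 known
#' and 5 novel miRNA loci, 50 decoy mRNAs, and 5e4 reads per cell type
#' across three cell types, with 0.1 percent substitution errors, 1 nt 5'
#' jitter, 8 percent star fraction, 6 percent mRNA-degradation reads and 1
#' percent poly-A artifacts.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param genome_length,n_known,n_novel,n_mrna_decoys,reads_per_sample see
#'   defaults.
#' @param cell_types character(3) sample labels.
#' @param error_rate per-base substitution probability.
#' @param jitter max 5' end offset in nt.
#' @param adapter3 3' adapter appended to every insert.
#' @param polya_artifact_frac,decoy_read_frac,novel_read_frac read-fraction
#'   mixture (the remainder is known-miRNA reads).
#' @param star_frac probability that a miRNA read is the star product.
#' @param read_length raw read length after adapter read-through clipping.
#' @param bulges asymmetric bulges per planted hairpin (default 1; keeps the
#'   star arm from being a perfect reverse complement of the mature arm).
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(seed = 1L, genome_length = 50000L,
                            n_known = 30L, n_novel = 5L,
                            n_mrna_decoys = 50L, reads_per_sample = 50000L,
                            cell_types = c("early_EPC", "late_EPC", "EC"),
                            error_rate = 0.001, jitter = 1L,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            polya_artifact_frac = 0.01,
                            decoy_read_frac = 0.06,
                            novel_read_frac = 0.08,
                            star_frac = 0.08, read_length = 36L,
                            bulges = 1L) {
  stopifnot(length(cell_types) == 3L,
            polya_artifact_frac >= 0, polya_artifact_frac <= 1,
            decoy_read_frac >= 0, decoy_read_frac <= 1,
            novel_read_frac >= 0, novel_read_frac <= 1,
            star_frac >= 0, star_frac <= 1,
            genome_length > 0, reads_per_sample > 0, jitter >= 0)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Construct a synthetic pre-miRNA hairpin
#'
#' The precursor is mature arm + loop + an imperfect reverse complement of
#' the mature arm (the star arm), with \code{bulges} extra unpaired
#' nucleotides inserted near the base of the star arm so the stem is
#' imperfect the way real precursors are.  Uses the current RNG state.
#'
#' @param mature_len mature product length, 20-24 nt.
#' @param loop_len terminal loop length, 4-12 nt.
#' @param bulges number of single-nucleotide bulges (default 0).
#' @return list with \code{precursor} (DNA), \code{mature}, \code{star}
#'   sequences and their 1-based intervals \code{mature_rel},
#'   \code{star_rel} within the precursor.
#' @export
make_hairpin <- function(mature_len = 22L, loop_len = 6L, bulges = 0L) {
  stopifnot(mature_len >= 20L, mature_len <= 24L,
            loop_len >= 4L, loop_len <= 12L, bulges >= 0L)
  for (try in 1:100) {
    hp <- .draw_hairpin(mature_len, loop_len, bulges)
    f <- fold_hairpin(hp$precursor)
    # accept only designs whose maximum-weight fold is the intended
    # single-loop stem (loop self-pairing or loop/arm interactions can
    # otherwise bifurcate or erode the designed helix)
    if (f$is_hairpin && f$longest_stem >= mature_len - bulges - 2L &&
        !is.na(f$loop_size) && f$loop_size >= 3L && f$loop_size <= loop_len)
      return(hp)
  }
  stop("failed to draw a clean hairpin in 100 attempts")
}

.draw_hairpin <- function(mature_len, loop_len, bulges) {
  repeat {
    mature <- .rand_dna(mature_len)
    # avoid accidental poly-A tracts in the product
    if (!grepl("AAAAAA", mature)) break
  }
  repeat {
    loop <- .rand_dna(loop_len)
    # non-complementary loop termini: a terminal loop whose ends pair would
    # extend the stem, and it lets jittered arm reads (read shifted one base
    # into the loop) align antisense to the opposite arm past the bulge
    if (substr(loop, loop_len, loop_len) !=
        chartr("ACGT", "TGCA", substr(loop, 1L, 1L))) break
  }
  # star arm = reverse complement of the mature arm, then bulged
  star_b <- rev(strsplit(chartr("ACGT", "TGCA", mature), "")[[1]])
  if (bulges > 0L) {
    # Insert extra bases near the 3' end of the star arm (stem base).  The
    # inserted base must not complement the mature bases it could line up
    # against, otherwise the bulge closes into a shifted perfect duplex and
    # the arms become exact antisense copies of each other.
    mature_b <- strsplit(mature, "")[[1]]
    comp <- chartr("ACGT", "TGCA", mature_b)
    for (b in seq_len(bulges)) {
      banned <- comp[seq_len(min(bulges + 2L, length(comp)))]
      pool <- setdiff(c("A", "C", "G", "T"), banned)
      if (!length(pool)) pool <- setdiff(c("A", "C", "G", "T"), comp[b])
      at <- length(star_b) - b          # stays within the last few positions
      star_b <- append(star_b, sample(pool, 1L), after = at)
    }
  }
  star <- paste(star_b, collapse = "")
  precursor <- paste0(mature, loop, star)
  list(precursor = precursor, mature = mature, star = star,
       mature_rel = c(1L, mature_len),
       star_rel = c(mature_len + loop_len + 1L, nchar(precursor)))
}

#' Build the synthetic genome, annotations and truth table
#'
#' Plants known precursors (annotated in GFF3-style tables and present in
#' the precursor reference), novel hairpins (truth table only) and decoy
#' mRNA transcripts (separate FASTA, also embedded in the genome), all
#' separated by at least 200 nt of random background.  Precursor loci carry
#' a 10 nt flank on each side inside the annotated interval.  Per-cell
#' abundance weights are drawn log-normally (shared base abundance times a
#' cell-type effect).
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{genome} (named character), \code{mrna} (named
#'   character, transcript sequences), \code{precursor_fasta} (named
#'   character, transcript-oriented known precursor sequences),
#'   \code{annotations} (precursors/matures data.frames as in
#'   \code{\link{read_mirna_annotations}}), \code{truth} (per-locus truth
#'   table), \code{profiles} (locus x cell weight matrix), \code{spec}.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  flank <- 10L
  chrom <- "chr1"

  n_loci <- spec$n_known + spec$n_novel
  hp <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    hp[[i]] <- make_hairpin(mature_len = sample(20:24, 1L),
                            loop_len = sample(4:12, 1L),
                            bulges = spec$bulges)
  }
  decoy_len <- sample(200:500, spec$n_mrna_decoys, replace = TRUE)
  decoys <- vapply(decoy_len, .rand_dna, character(1))

  # interleave elements and place them with >= 200 nt spacing
  elements <- c(
    lapply(seq_len(spec$n_known), function(i)
      list(type = "known", name = sprintf("miR-S%d", i), idx = i)),
    lapply(seq_len(spec$n_novel), function(i)
      list(type = "novel", name = sprintf("novel-%d", i),
           idx = spec$n_known + i)),
    lapply(seq_len(spec$n_mrna_decoys), function(i)
      list(type = "decoy", name = sprintf("decoy_tx%d", i), idx = i))
  )
  elements <- elements[sample(length(elements))]

  seqs <- vapply(elements, function(el) {
    if (el$type == "decoy") decoys[el$idx] else
      paste0(.rand_dna(flank), hp[[el$idx]]$precursor, .rand_dna(flank))
  }, character(1))
  lens <- nchar(seqs)
  gaps <- 200L + sample(0:100, length(elements), replace = TRUE)
  starts <- 100L + cumsum(c(0L, (lens + gaps)[-length(lens)]))
  total <- starts[length(starts)] + lens[length(lens)] + 200L
  if (total > spec$genome_length)
    stop("planted elements exceed genome capacity (need ", total,
         " nt, have ", spec$genome_length, ")")
  genome <- .rand_dna(spec$genome_length)
  strands <- ifelse(vapply(elements, `[[`, character(1), "type") == "decoy",
                    "+", sample(c("+", "-"), length(elements), replace = TRUE))
  for (i in seq_along(elements)) {
    s <- seqs[i]
    if (strands[i] == "-") s <- .revcomp(s)
    substr(genome, starts[i], starts[i] + lens[i] - 1L) <- s
  }

  rows <- list()
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    gs <- starts[i]; ge <- starts[i] + lens[i] - 1L
    if (el$type == "decoy") {
      rows[[i]] <- data.frame(
        name = el$name, type = "decoy", chrom = chrom,
        start = gs, end = ge, strand = strands[i],
        mature_start = NA_integer_, mature_end = NA_integer_,
        star_start = NA_integer_, star_end = NA_integer_,
        mature_seq = NA_character_, star_seq = NA_character_,
        precursor_seq = decoys[el$idx], stringsAsFactors = FALSE)
    } else {
      h <- hp[[el$idx]]
      # transcript-relative intervals (flank offset), converted to genomic
      rel_m <- h$mature_rel + flank
      rel_s <- h$star_rel + flank
      conv <- function(rel) {
        if (strands[i] == "+") c(gs + rel[1L] - 1L, gs + rel[2L] - 1L)
        else c(ge - rel[2L] + 1L, ge - rel[1L] + 1L)
      }
      gm <- conv(rel_m); gst <- conv(rel_s)
      rows[[i]] <- data.frame(
        name = el$name, type = el$type, chrom = chrom,
        start = gs, end = ge, strand = strands[i],
        mature_start = gm[1L], mature_end = gm[2L],
        star_start = gst[1L], star_end = gst[2L],
        mature_seq = h$mature, star_seq = h$star,
        precursor_seq = paste0(substr(seqs[i], 1L, flank), h$precursor,
                               substr(seqs[i], lens[i] - flank + 1L, lens[i])),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(match(truth$type, c("known", "novel", "decoy")),
                       truth$start), ]
  rownames(truth) <- NULL

  known <- truth[truth$type == "known", ]
  precursors <- data.frame(name = known$name, chrom = known$chrom,
                           start = known$start, end = known$end,
                           strand = known$strand, stringsAsFactors = FALSE)
  # the planted mature product is always the 5' arm of its hairpin
  matures <- data.frame(name = paste0(known$name, "-5p"),
                        precursor_name = known$name, chrom = known$chrom,
                        start = known$mature_start, end = known$mature_end,
                        strand = known$strand, stringsAsFactors = FALSE)
  precursor_fasta <- known$precursor_seq
  names(precursor_fasta) <- known$name
  names(decoys) <- sprintf("decoy_tx%d", seq_along(decoys))

  loci <- truth$name[truth$type != "decoy"]
  base <- stats::rlnorm(length(loci), meanlog = 0, sdlog = 1.5)
  eff <- matrix(stats::rlnorm(length(loci) * 3L, 0, 0.8), ncol = 3L)
  profiles <- base * eff
  dimnames(profiles) <- list(loci, spec$cell_types)

  g <- genome
  names(g) <- chrom
  list(genome = g, mrna = decoys, precursor_fasta = precursor_fasta,
       annotations = list(precursors = precursors, matures = matures),
       truth = truth, profiles = profiles, spec = spec)
}

#' Simulate per-cell-type read libraries
#'
#' For each cell type, reads are drawn multinomially from the planted locus
#' weights (known loci share \code{1 - novel_read_frac - decoy_read_frac -
#' polya_artifact_frac} of the library, novel loci \code{novel_read_frac});
#' each miRNA read is the mature (or, with probability \code{star_frac},
#' the star) product with uniform 5' jitter up to \code{spec$jitter} nt,
#' substitution errors at \code{error_rate}, the 3' adapter appended and
#' the read clipped to \code{read_length}.  Decoy reads are random 18-30 nt
#' mRNA fragments; poly-A artifacts are pure A-runs.  Read order is
#' shuffled.
#'
#' @param sim output of \code{\link{build_genome}}.
#' @return list per cell type, each with \code{reads} (data.frame read_id,
#'   sequence, quality) and \code{locus_counts} (data.frame locus,
#'   mature_reads, star_reads).
#' @export
simulate_reads <- function(sim) {
  spec <- sim$spec
  out <- vector("list", length(spec$cell_types))
  names(out) <- spec$cell_types
  truth <- sim$truth
  mir <- truth[truth$type != "decoy", ]
  n_decoy_tx <- sum(truth$type == "decoy")

  for (ci in seq_along(spec$cell_types)) {
    ct <- spec$cell_types[ci]
    set.seed(spec$seed + 1000L * ci)
    n <- spec$reads_per_sample
    n_polya <- round(spec$polya_artifact_frac * n)
    n_decoy <- round(spec$decoy_read_frac * n)
    n_mir <- n - n_polya - n_decoy

    w <- sim$profiles[, ct]
    is_novel <- truth$type[match(names(w), truth$name)] == "novel"
    w[is_novel] <- w[is_novel] / sum(w[is_novel]) * spec$novel_read_frac
    w[!is_novel] <- w[!is_novel] / sum(w[!is_novel]) * (1 - spec$novel_read_frac)
    pick <- sample(names(w), n_mir, replace = TRUE, prob = w)
    star <- stats::runif(n_mir) < spec$star_frac
    offs <- if (spec$jitter > 0)
      sample(seq(-spec$jitter, spec$jitter), n_mir, replace = TRUE)
    else rep(0L, n_mir)

    ti <- match(pick, mir$name)
    # transcript-oriented precursor sequence with flank; product intervals
    flank <- 10L
    pre <- mir$precursor_seq[ti]
    m_rel <- cbind(flank + 1L,
                   flank + nchar(mir$mature_seq[ti]))
    loop_len <- nchar(pre) - 2L * flank - nchar(mir$mature_seq[ti]) -
      nchar(mir$star_seq[ti])
    s_rel <- cbind(flank + nchar(mir$mature_seq[ti]) + loop_len + 1L,
                   nchar(pre) - flank)
    rs <- ifelse(star, s_rel[, 1L], m_rel[, 1L]) + offs
    re <- ifelse(star, s_rel[, 2L], m_rel[, 2L]) + offs
    inserts_mir <- substr(pre, rs, re)

    # substitution errors
    nerr <- stats::rbinom(n_mir, nchar(inserts_mir), spec$error_rate)
    for (i in which(nerr > 0L)) {
      b <- strsplit(inserts_mir[i], "")[[1]]
      pos <- sample(length(b), min(nerr[i], length(b)))
      for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
      inserts_mir[i] <- paste(b, collapse = "")
    }

    inserts_decoy <- character(n_decoy)
    if (n_decoy > 0L) {
      dtx <- sample(n_decoy_tx, n_decoy, replace = TRUE)
      dlen <- sample(18:30, n_decoy, replace = TRUE)
      txseq <- sim$mrna[dtx]
      dstart <- 1L + floor(stats::runif(n_decoy) * (nchar(txseq) - dlen))
      inserts_decoy <- substr(txseq, dstart, dstart + dlen - 1L)
    }
    inserts_polya <- if (n_polya > 0L)
      strrep("A", sample(18:30, n_polya, replace = TRUE)) else character(0)

    inserts <- c(inserts_mir, inserts_decoy, inserts_polya)
    reads <- substr(paste0(inserts, spec$adapter3, spec$adapter3),
                    1L, spec$read_length)
    perm <- sample(length(reads))
    reads <- reads[perm]
    df <- data.frame(read_id = sprintf("%s_r%06d", ct, seq_along(reads)),
                     sequence = reads,
                     quality = strrep("I", nchar(reads)),
                     stringsAsFactors = FALSE)
    lc <- data.frame(locus = mir$name,
                     mature_reads = vapply(mir$name, function(nm)
                       sum(pick == nm & !star), numeric(1)),
                     star_reads = vapply(mir$name, function(nm)
                       sum(pick == nm & star), numeric(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
    out[[ci]] <- list(reads = df, locus_counts = lc)
  }
  out
}

#' Write FASTQ from a read table
#' @param reads data.frame with read_id, sequence, quality.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Write a complete simulated study to a directory
#'
#' Produces genome.fa, mrna.fa, mirna_precursors.fa, annotations.gff3,
#' truth.tsv and one FASTQ per cell type.
#'
#' @param sim output of \code{\link{build_genome}}.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  fa <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
    path
  }
  p$genome <- fa(sim$genome, file.path(dir, "genome.fa"))
  p$mrna <- fa(sim$mrna, file.path(dir, "mrna.fa"))
  p$mirna <- fa(sim$precursor_fasta, file.path(dir, "mirna_precursors.fa"))
  p$gff <- file.path(dir, "annotations.gff3")
  .write_annotation_gff(sim$annotations, p$gff)
  p$truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reads <- simulate_reads(sim)
  p$fastq <- character(0)
  for (ct in names(reads)) {
    fp <- file.path(dir, paste0(ct, ".fastq"))
    write_fastq(reads[[ct]]$reads, fp)
    lp <- file.path(dir, paste0(ct, ".locus_counts.tsv"))
    utils::write.table(reads[[ct]]$locus_counts, lp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p$fastq[ct] <- fp
  }
  invisible(p)
}

.write_annotation_gff <- function(annotations, path) {
  pre <- annotations$precursors
  mat <- annotations$matures
  gr_pre <- GenomicRanges::GRanges(
    pre$chrom, IRanges::IRanges(pre$start, pre$end), strand = pre$strand,
    type = "miRNA_primary_transcript", ID = pre$name, Name = pre$name)
  gr_mat <- GenomicRanges::GRanges(
    mat$chrom, IRanges::IRanges(mat$start, mat$end), strand = mat$strand,
    type = "miRNA", ID = mat$name, Name = mat$name,
    Derives_from = mat$precursor_name)
  rtracklayer::export(suppressWarnings(c(gr_pre, gr_mat)), path,
                      format = "gff3")
  invisible(path)
}
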