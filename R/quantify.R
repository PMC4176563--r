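# Known miRNA quantification.
#
# Genomic tag placements are assigned to annotated mature miRNAs with a small
# strand-aware tolerance window (2 nt on the 5' side, 5 nt on the 3' side,
# typical isomiR wobble).  A tag mapping to M mature windows contributes its
# read count split 1/M across them; per-miRNA raw counts are normalized as
# RPM = C / (M * N) * 1e9 with M = 1 after fractional allocation.

#' Read miRNA annotations from a miRBase-dialect GFF3
#'
#' Expects \code{miRNA_primary_transcript} features for precursors and
#' \code{miRNA} features for mature products, linked by \code{Derives_from}.
#'
#' @param path GFF3 file.
#' @return list with data.frames \code{precursors} (name, chrom, start, end,
#'   strand; 1-based inclusive) and \code{matures} (name, precursor_name,
#'   chrom, start, end, strand).
#' @export
read_mirna_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_pre <- md$type == "miRNA_primary_transcript"
  is_mat <- md$type == "miRNA"
  pre <- data.frame(
    name = as.character(md$Name[is_pre]),
    id = as.character(md$ID[is_pre]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_pre]),
    start = GenomicRanges::start(gr)[is_pre],
    end = GenomicRanges::end(gr)[is_pre],
    strand = as.character(GenomicRanges::strand(gr)[is_pre]),
    stringsAsFactors = FALSE)
  derives <- as.character(md$Derives_from[is_mat])
  mat <- data.frame(
    name = as.character(md$Name[is_mat]),
    precursor_name = pre$name[match(derives, pre$id)],
    chrom = as.character(GenomicRanges::seqnames(gr)[is_mat]),
    start = GenomicRanges::start(gr)[is_mat],
    end = GenomicRanges::end(gr)[is_mat],
    strand = as.character(GenomicRanges::strand(gr)[is_mat]),
    stringsAsFactors = FALSE)
  if (any(is.na(mat$precursor_name)))
    stop("mature miRNA without resolvable Derives_from precursor: ",
         paste(mat$name[is.na(mat$precursor_name)], collapse = ", "))
  ok <- mapply(function(p, s, e, st) {
    i <- match(p, pre$name)
    s >= pre$start[i] && e <= pre$end[i] && st == pre$strand[i]
  }, mat$precursor_name, mat$start, mat$end, mat$strand)
  if (!all(ok))
    stop("mature interval outside its precursor: ",
         paste(mat$name[!ok], collapse = ", "))
  list(precursors = pre[setdiff(names(pre), "id")], matures = mat)
}

#' Count known miRNAs from genomic tag placements
#'
#' A placement qualifies for a mature miRNA when it lies, on the same strand,
#' fully within the mature interval extended by \code{flank5} nt on the 5'
#' side and \code{flank3} nt on the 3' side (strand-aware).  Each tag's read
#' count is split 1/M over its M qualifying placements, so total assigned
#' read mass is conserved exactly.
#'
#' @param hits genomic hit table from \code{\link{align_tags}} (must carry
#'   \code{count}).
#' @param annotations from \code{\link{read_mirna_annotations}}.
#' @param flank5,flank3 tolerance window (defaults 2 and 5 nt).
#' @param seqlens optional named vector of chromosome lengths; annotation
#'   intervals beyond them raise an error naming the interval.
#' @return data.frame with columns \code{mirna_name}, \code{raw_count}; one
#'   row per annotated mature miRNA (zeros included), ordered by name.
#' @export
count_known_mirnas <- function(hits, annotations, flank5 = 2L, flank3 = 5L,
                               seqlens = NULL) {
  mat <- annotations$matures
  if (!is.null(seqlens)) {
    over <- mat$end > seqlens[mat$chrom] | mat$start < 1L
    if (any(over, na.rm = TRUE)) {
      i <- which(over)[1L]
      stop("annotation interval off the reference: ", mat$name[i], " ",
           mat$chrom[i], ":", mat$start[i], "-", mat$end[i])
    }
  }
  plus <- mat$strand == "+"
  win_start <- ifelse(plus, mat$start - flank5, mat$start - flank3)
  win_end <- ifelse(plus, mat$end + flank3, mat$end + flank5)
  out <- data.frame(mirna_name = mat$name, raw_count = 0,
                    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hit_gr <- GenomicRanges::GRanges(hits$refname,
                                     IRanges::IRanges(hits$start, hits$end),
                                     strand = hits$strand)
    win_gr <- GenomicRanges::GRanges(mat$chrom,
                                     IRanges::IRanges(win_start, win_end),
                                     strand = mat$strand)
    ov <- GenomicRanges::findOverlaps(hit_gr, win_gr, type = "within")
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      m_per_tag <- table(hits$tag_id[qh])
      w <- hits$count[qh] / as.integer(m_per_tag[hits$tag_id[qh]])
      csum <- tapply(w, sh, sum)
      out$raw_count[as.integer(names(csum))] <-
        out$raw_count[as.integer(names(csum))] + as.numeric(csum)
      first <- !duplicated(hits$tag_id) & hits$tag_id %in% hits$tag_id[qh]
      assigned_tag_mass <- sum(hits$count[first])
    } else {
      assigned_tag_mass <- 0
    }
  } else {
    assigned_tag_mass <- 0
  }
  out <- out[order(out$mirna_name, method = "radix"), ]
  rownames(out) <- NULL
  # total read mass of tags with >= 1 qualifying placement; by construction
  # of the 1/M split it equals sum(out$raw_count) exactly (mass balance)
  attr(out, "assigned_tag_mass") <- assigned_tag_mass
  out
}

#' RPM normalization
#'
#' Computes \code{C / (M * N) * scale}.  When counts were already
#' 1/M-weighted at assignment time (the package default), callers must pass
#' \code{M = 1}; the explicit M form is for single-tag use.
#'
#' @param C raw count(s), non-negative.
#' @param M multi-mapping placement count(s), >= 1 (default 1).
#' @param N total reads mapped to the genome, > 0.
#' @param scale normalization scale (default 1e9, as printed in the RPM
#'   definition this package follows).
#' @return numeric RPM value(s); 0 exactly when C is 0.
#' @export
rpm_normalize <- function(C, M = 1, N, scale = 1e9) {
  if (any(N <= 0)) stop("N must be > 0")
  if (any(M < 1)) stop("M must be >= 1")
  if (any(C < 0)) stop("C must be non-negative")
  C / (M * N) * scale
}

#' Assemble an RPM (or count) matrix across samples
#'
#' @param records data.frame with columns \code{mirna_name}, \code{sample},
#'   \code{value} (e.g. RPM).  Duplicate (miRNA, sample) records are an
#'   error.
#' @return numeric matrix, rows = miRNAs, columns = samples, both sorted
#'   lexicographically; missing entries are 0.
#' @export
build_expression_matrix <- function(records) {
  stopifnot(all(c("mirna_name", "sample", "value") %in% names(records)))
  key <- paste(records$mirna_name, records$sample, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate record for (", d$mirna_name, ", ", d$sample, ")")
  }
  rows <- sort(unique(records$mirna_name), method = "radix")
  cols <- sort(unique(records$sample), method = "radix")
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(records$mirna_name, rows), match(records$sample, cols))] <-
    records$value
  m
}

#' Write a matrix as a TSV with a leading id column
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_col name of the leading column (default "mirna").
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "mirna") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
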