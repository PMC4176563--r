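# Consensus novel miRNA discovery from genomic read stacks.
#
# Unannotated genomic placements are clustered into read stacks; around each
# stack's dominant read two candidate precursor windows are excised (the
# mature product can sit on either arm), folded, and the stack partitioned
# into mature / star / loop / inconsistent evidence using the fold's pairing.
# Two independent predictors (a weighted additive scorer and a hard rule
# filter) vote; a candidate is called only on consensus, mirroring the
# two-algorithm intersection design of miRDeep2/MIREAP-style pipelines.

#' Cluster genomic placements into read stacks
#'
#' Same-chromosome, same-strand placements whose intervals are within
#' \code{max_gap} nt of each other (single linkage) are merged into one
#' stack.
#'
#' @param hits genomic hit table (\code{tag_id, refname, start, end, strand,
#'   count}).
#' @param max_gap integer, maximum gap in nt (default 30).
#' @return list of stacks ordered by (chrom, start, strand); each stack is a
#'   list with \code{chrom}, \code{strand}, \code{start}, \code{end},
#'   \code{placements} (data.frame) and \code{total_count}.
#' @export
cluster_stacks <- function(hits, max_gap = 30L) {
  if (!nrow(hits)) return(list())
  hits <- hits[order(hits$refname, hits$strand, hits$start, hits$end,
                     method = "radix"), ]
  key <- paste(hits$refname, hits$strand, sep = "\r")
  stacks <- list()
  for (k in unique(key)) {
    h <- hits[key == k, , drop = FALSE]
    upper <- cummax(h$end)
    new_grp <- c(TRUE, h$start[-1L] > upper[-nrow(h)] + max_gap)
    grp <- cumsum(new_grp)
    for (g in unique(grp)) {
      p <- h[grp == g, , drop = FALSE]
      rownames(p) <- NULL
      stacks[[length(stacks) + 1L]] <- list(
        chrom = p$refname[1L], strand = p$strand[1L],
        start = min(p$start), end = max(p$end),
        placements = p, total_count = sum(p$count))
    }
  }
  o <- order(vapply(stacks, `[[`, character(1), "chrom"),
             vapply(stacks, `[[`, integer(1), "start"),
             vapply(stacks, `[[`, character(1), "strand"),
             method = "radix")
  stacks[o]
}

.dominant_placement <- function(stack) {
  p <- stack$placements
  p[order(-p$count, p$start, p$end, p$tag_id, method = "radix")[1L], ]
}

#' Excise candidate precursor windows around a stack's dominant read
#'
#' Window A extends the dominant read 15 nt upstream and 70 nt downstream
#' (dominant product on the 5' arm); window B extends 70 nt upstream and
#' 15 nt downstream (3' arm).  Windows are clipped at chromosome ends and
#' skipped when shorter than \code{min_window}.
#'
#' @param genome named character vector of chromosome sequences.
#' @param stack a stack from \code{\link{cluster_stacks}}.
#' @param up,down extension lengths in nt (defaults 15 and 70).
#' @param min_window minimum emitted window length (default 40 nt).
#' @return list of up to two windows, each a list with \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{arm_hint} ("5p"/"3p"),
#'   \code{seq} (genome-forward orientation); an attribute \code{skipped}
#'   reports windows dropped for being too short.
#' @export
excise_windows <- function(genome, stack, up = 15L, down = 70L,
                           min_window = 40L) {
  dom <- .dominant_placement(stack)
  slen <- nchar(genome[[stack$chrom]])
  spans <- list(`5p` = c(dom$start - up, dom$end + down),
                `3p` = c(dom$start - down, dom$end + up))
  out <- list()
  skipped <- character(0)
  for (arm in names(spans)) {
    s <- max(1L, spans[[arm]][1L]); e <- min(slen, spans[[arm]][2L])
    if (e - s + 1L < min_window) {
      skipped <- c(skipped, sprintf("%s:%d-%d window < %d nt after clipping",
                                    stack$chrom, s, e, min_window))
      next
    }
    out[[length(out) + 1L]] <- list(
      chrom = stack$chrom, start = s, end = e, strand = stack$strand,
      arm_hint = arm, seq = substr(genome[[stack$chrom]], s, e))
  }
  attr(out, "skipped") <- skipped
  out
}

# genomic -> window-local oriented (5'->3') coordinates
.to_local <- function(gstart, gend, window) {
  if (window$strand == "+") {
    cbind(start = gstart - window$start + 1L, end = gend - window$start + 1L)
  } else {
    cbind(start = window$end - gend + 1L, end = window$end - gstart + 1L)
  }
}

.to_genomic <- function(lstart, lend, window) {
  if (window$strand == "+") {
    c(window$start + lstart - 1L, window$start + lend - 1L)
  } else {
    c(window$end - lend + 1L, window$end - lstart + 1L)
  }
}

#' Partition a read stack over a folded precursor window
#'
#' The mature product is the dominant read; the star interval is the region
#' pairing with the mature across the stem, shifted to leave the canonical
#' 2 nt 3' overhang; the loop lies between the two arms.  Every placement is
#' assigned to the category containing at least \code{min_frac} of its span,
#' otherwise it is counted as inconsistent.  Placements outside the window
#' are ignored.
#'
#' @param fold a \code{\link{fold_hairpin}} of the window sequence (oriented
#'   5' to 3', i.e. reverse-complemented for minus-strand windows).
#' @param stack the read stack.
#' @param window a window from \code{\link{excise_windows}}.
#' @param min_frac span fraction required for a category call (default 0.8).
#' @return list with local and genomic mature/star/loop intervals,
#'   \code{mature_arm}, the four evidence counts and \code{total_count}
#'   (reads considered within the window).
#' @export
partition_stack <- function(fold, stack, window, min_frac = 0.8) {
  L <- nchar(fold$sequence)
  loc <- .to_local(stack$placements$start, stack$placements$end, window)
  inside <- loc[, "start"] <= L & loc[, "end"] >= 1L
  pl <- stack$placements[inside, , drop = FALSE]
  loc <- loc[inside, , drop = FALSE]
  loc[, "start"] <- pmax(loc[, "start"], 1L)
  loc[, "end"] <- pmin(loc[, "end"], L)

  dom <- .dominant_placement(stack)
  dl <- .to_local(dom$start, dom$end, window)
  a <- max(1L, dl[1L, "start"]); b <- min(L, dl[1L, "end"])
  mature <- c(a, b)

  pt <- fold$pairs
  # nearest paired positions inward from the mature ends
  k1 <- NA_integer_
  for (x in seq(max(a, b - 2L), a)) if (pt[x] > 0L) { k1 <- x; break }
  star <- NULL
  if (!is.na(k1)) {
    k0 <- NA_integer_
    for (x in seq(a, b)) if (pt[x] > 0L) { k0 <- x; break }
    ends <- sort(c(pt[k1], pt[k0] + 2L))
    star <- c(max(1L, ends[1L]), min(L, ends[2L]))
    if (star[2L] < star[1L]) star <- NULL
  }

  if (!is.null(star)) {
    left <- if (mature[1L] <= star[1L]) mature else star
    right <- if (mature[1L] <= star[1L]) star else mature
    loop <- c(left[2L] + 1L, right[1L] - 1L)
    if (loop[2L] < loop[1L]) loop <- NULL
  } else if (!is.na(fold$main_loop[1L])) {
    loop <- c(fold$main_loop[1L] + 1L, fold$main_loop[2L] - 1L)
  } else {
    loop <- NULL
  }

  cat_frac <- function(iv) {
    if (is.null(iv)) return(rep(0, nrow(pl)))
    ov <- pmin(loc[, "end"], iv[2L]) - pmax(loc[, "start"], iv[1L]) + 1L
    pmax(ov, 0L) / (loc[, "end"] - loc[, "start"] + 1L)
  }
  fr <- cbind(mature = cat_frac(mature), star = cat_frac(star),
              loop = cat_frac(loop))
  best <- max.col(fr, ties.method = "first")
  ok <- fr[cbind(seq_len(nrow(fr)), best)] >= min_frac
  categ <- ifelse(ok, colnames(fr)[best], "inconsistent")
  counts <- vapply(c("mature", "star", "loop", "inconsistent"),
                   function(cc) sum(pl$count[categ == cc]), numeric(1))

  arm <- if (!is.na(fold$main_loop[1L])) {
    if (mean(mature) <= mean(fold$main_loop)) "5p" else "3p"
  } else {
    window$arm_hint
  }

  list(mature_local = mature, star_local = star, loop_local = loop,
       mature_genomic = .to_genomic(mature[1L], mature[2L], window),
       star_genomic = if (is.null(star)) NULL else
         .to_genomic(star[1L], star[2L], window),
       mature_arm = arm,
       mature_count = counts[["mature"]], star_count = counts[["star"]],
       loop_count = counts[["loop"]],
       inconsistent_count = counts[["inconsistent"]],
       total_count = sum(pl$count))
}

#' Score a precursor candidate (probabilistic predictor arm)
#'
#' scoreA = w1*log2(1 + mature_count) + w2*consistent_fraction +
#' w3*(fold score / window length) + w4*[star evidence] -
#' w5*inconsistent_fraction.
#'
#' @param cand a candidate list (as assembled by
#'   \code{\link{discover_novel_mirnas}}) carrying \code{fold} and the
#'   partition counts.
#' @param weights numeric(5), default c(2, 4, 10, 3, 6).
#' @param threshold pass threshold on scoreA (default 5).
#' @return list(scoreA, passA).
#' @export
score_candidate_a <- function(cand, weights = c(2, 4, 10, 3, 6),
                              threshold = 5) {
  tot <- cand$total_count
  cons <- if (tot > 0) (cand$mature_count + cand$star_count + cand$loop_count) / tot else 0
  dens <- cand$fold$score / nchar(cand$fold$sequence)
  s <- weights[1L] * log2(1 + cand$mature_count) +
    weights[2L] * cons +
    weights[3L] * dens +
    weights[4L] * (cand$star_count > 0) -
    weights[5L] * (1 - cons)
  list(scoreA = s, passA = s >= threshold)
}

#' Hard rule filter (rule-based predictor arm)
#'
#' Passes only when all hold: mature length 18-26 nt; mature on one arm of
#' the main hairpin (a 2 nt overhang past the loop-closing pair is
#' tolerated, as Dicer products routinely extend a base into the loop);
#' longest stem >= 14 bp; terminal loop 3-20 nt; fold score density >= 0.25;
#' mature read count >= 5; inconsistent read fraction <= 0.2.
#'
#' @param cand a candidate list.
#' @param min_mature_len,max_mature_len,min_stem,min_loop,max_loop,
#'   min_density,min_mature_count,max_inconsistent_frac rule thresholds.
#' @param arm_slack nt of mature overhang past the loop-closing pair still
#'   counted as "on one arm" (default 2).
#' @return logical passB.
#' @export
rule_filter_b <- function(cand, min_mature_len = 18L, max_mature_len = 26L,
                          min_stem = 14L, min_loop = 3L, max_loop = 20L,
                          min_density = 0.25, min_mature_count = 5,
                          max_inconsistent_frac = 0.2, arm_slack = 2L) {
  f <- cand$fold
  ml <- cand$mature_local[2L] - cand$mature_local[1L] + 1L
  if (ml < min_mature_len || ml > max_mature_len) return(FALSE)
  if (is.na(f$main_loop[1L])) return(FALSE)
  on_arm <- cand$mature_local[2L] <= f$main_loop[1L] + arm_slack ||
    cand$mature_local[1L] >= f$main_loop[2L] - arm_slack
  if (!on_arm) return(FALSE)
  if (f$longest_stem < min_stem) return(FALSE)
  if (is.na(f$loop_size) || f$loop_size < min_loop || f$loop_size > max_loop)
    return(FALSE)
  if (f$score / nchar(f$sequence) < min_density) return(FALSE)
  if (cand$mature_count < min_mature_count) return(FALSE)
  tot <- cand$total_count
  incf <- if (tot > 0) cand$inconsistent_count / tot else 1
  if (incf > max_inconsistent_frac) return(FALSE)
  TRUE
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0L) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

#' Consensus calling and provisional naming
#'
#' consensus = passA AND passB.  Overlapping consensus candidates (>= 50
#' percent reciprocal overlap, same chromosome and strand) are merged keeping
#' the higher scoreA; survivors are named miR-N1, miR-N2, ... in genome
#' order, with -5p/-3p product names.
#'
#' @param candidates data.frame of candidates (one row per excised window)
#'   with columns \code{chrom, start, end, strand, mature_arm, scoreA,
#'   passA, passB}.
#' @param min_reciprocal reciprocal overlap for merging (default 0.5).
#' @return the data.frame with added columns \code{consensus},
#'   \code{called}, \code{name}, \code{mature_product},
#'   \code{star_product}; called rows carry unique miR-N names.
#' @export
consensus_and_name <- function(candidates, min_reciprocal = 0.5) {
  candidates$consensus <- candidates$passA & candidates$passB
  candidates$called <- FALSE
  candidates$name <- NA_character_
  candidates$mature_product <- NA_character_
  candidates$star_product <- NA_character_
  idx <- which(candidates$consensus)
  if (length(idx)) {
    ord <- idx[order(-candidates$scoreA[idx], candidates$chrom[idx],
                     candidates$start[idx], method = "radix")]
    kept <- integer(0)
    for (i in ord) {
      clash <- FALSE
      for (j in kept) {
        if (candidates$chrom[i] == candidates$chrom[j] &&
            candidates$strand[i] == candidates$strand[j] &&
            .reciprocal_overlap(candidates$start[i], candidates$end[i],
                                candidates$start[j], candidates$end[j]) >=
              min_reciprocal) { clash <- TRUE; break }
      }
      if (!clash) kept <- c(kept, i)
    }
    kept <- kept[order(candidates$chrom[kept], candidates$start[kept],
                       candidates$strand[kept], method = "radix")]
    candidates$called[kept] <- TRUE
    candidates$name[kept] <- paste0("miR-N", seq_along(kept))
    arm <- candidates$mature_arm[kept]
    other <- ifelse(arm == "5p", "3p", "5p")
    candidates$mature_product[kept] <- paste0(candidates$name[kept], "-", arm)
    candidates$star_product[kept] <- paste0(candidates$name[kept], "-", other)
  }
  candidates
}

#' Discover novel miRNAs from unannotated genomic hits
#'
#' Orchestrates stack clustering, window excision, folding, stack
#' partitioning, both predictors and consensus naming.  Hits overlapping
#' known precursor loci can be excluded first (reads not mapped to any known
#' miRNA locus are the discovery input).
#'
#' @param genome named character vector of chromosome sequences.
#' @param hits unannotated genomic hit table.
#' @param known_precursors optional data.frame (chrom, start, end, strand);
#'   hits overlapping these are dropped.
#' @param max_gap stack clustering gap (default 30).
#' @param score_weights,score_threshold predictor A settings.
#' @param rule_args named list of \code{\link{rule_filter_b}} overrides.
#' @param min_stack_count minimum stack read count to fold a window
#'   (default 3; thinner stacks cannot satisfy either predictor).
#' @return list with \code{candidates} (data.frame, one row per folded
#'   window, predictor verdicts, consensus and names), \code{details} (list
#'   of per-candidate fold/partition objects), and \code{n_stacks}.
#' @export
discover_novel_mirnas <- function(genome, hits, known_precursors = NULL,
                                  max_gap = 30L,
                                  score_weights = c(2, 4, 10, 3, 6),
                                  score_threshold = 5,
                                  rule_args = list(),
                                  min_stack_count = 3) {
  if (!is.null(known_precursors) && nrow(hits) && nrow(known_precursors)) {
    hit_gr <- GenomicRanges::GRanges(hits$refname,
                                     IRanges::IRanges(hits$start, hits$end))
    pre_gr <- GenomicRanges::GRanges(known_precursors$chrom,
                                     IRanges::IRanges(known_precursors$start,
                                                      known_precursors$end))
    drop <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(hit_gr, pre_gr, ignore.strand = TRUE))
    if (length(drop)) hits <- hits[-unique(drop), , drop = FALSE]
  }
  stacks <- cluster_stacks(hits, max_gap = max_gap)
  rows <- list(); details <- list()
  for (st in stacks) {
    if (st$total_count < min_stack_count) next
    windows <- excise_windows(genome, st)
    for (w in windows) {
      wseq <- if (w$strand == "-") .revcomp(w$seq) else w$seq
      fold <- fold_hairpin(wseq)
      part <- partition_stack(fold, st, w)
      cand <- c(part, list(fold = fold, window = w))
      sa <- score_candidate_a(cand, weights = score_weights,
                              threshold = score_threshold)
      pb <- do.call(rule_filter_b, c(list(cand = cand), rule_args))
      mg <- part$mature_genomic
      sg <- part$star_genomic
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = w$chrom, start = w$start, end = w$end, strand = w$strand,
        arm_hint = w$arm_hint, mature_arm = part$mature_arm,
        mature_start = mg[1L], mature_end = mg[2L],
        star_start = if (is.null(sg)) NA_integer_ else sg[1L],
        star_end = if (is.null(sg)) NA_integer_ else sg[2L],
        mature_count = part$mature_count, star_count = part$star_count,
        loop_count = part$loop_count,
        inconsistent_count = part$inconsistent_count,
        total_count = part$total_count,
        fold_score = fold$score, longest_stem = fold$longest_stem,
        loop_size = fold$loop_size, structure = fold$structure,
        scoreA = sa$scoreA, passA = sa$passA, passB = pb,
        stringsAsFactors = FALSE)
      details[[length(details) + 1L]] <- cand
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), arm_hint = character(),
               mature_arm = character(), mature_start = integer(),
               mature_end = integer(), star_start = integer(),
               star_end = integer(), mature_count = numeric(),
               star_count = numeric(), loop_count = numeric(),
               inconsistent_count = numeric(), total_count = numeric(),
               fold_score = numeric(), longest_stem = integer(),
               loop_size = integer(), structure = character(),
               scoreA = numeric(), passA = logical(), passB = logical(),
               stringsAsFactors = FALSE)
  candidates <- consensus_and_name(candidates)
  rownames(candidates) <- NULL
  list(candidates = candidates, details = details, n_stacks = length(stacks))
}

#' Export consensus novel calls as GFF3
#'
#' Writes precursor (\code{miRNA_primary_transcript}) and mature/star
#' (\code{miRNA}) features for called candidates, with scoreA in the score
#' column.
#'
#' @param candidates candidate table from
#'   \code{\link{discover_novel_mirnas}}.
#' @param path output GFF3 file.
#' @return the path, invisibly.
#' @export
export_novel_gff <- function(candidates, path) {
  called <- candidates[candidates$called %in% TRUE, , drop = FALSE]
  grs <- list()
  for (i in seq_len(nrow(called))) {
    r <- called[i, ]
    pre_id <- r$name
    grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(r$start, r$end), strand = r$strand,
      type = "miRNA_primary_transcript", ID = pre_id, Name = pre_id,
      score = r$scoreA)
    grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(r$mature_start, r$mature_end),
      strand = r$strand, type = "miRNA", ID = r$mature_product,
      Name = r$mature_product, score = r$scoreA, Derives_from = pre_id)
    if (!is.na(r$star_start)) {
      grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
        r$chrom, IRanges::IRanges(r$star_start, r$star_end),
        strand = r$strand, type = "miRNA", ID = r$star_product,
        Name = r$star_product, score = r$scoreA, Derives_from = pre_id)
    }
  }
  gr <- if (length(grs)) suppressWarnings(do.call(c, grs)) else
    GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
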