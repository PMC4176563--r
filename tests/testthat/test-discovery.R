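mk_hits <- function(starts, ends, counts = NULL, strand = "+",
                    chrom = "chr1") {
  n <- length(starts)
  data.frame(tag_id = paste0("t", seq_len(n)), refname = chrom,
             start = as.integer(starts), end = as.integer(ends),
             strand = strand, mismatches = 0L,
             count = if (is.null(counts)) rep(1L, n) else as.integer(counts),
             multiplicity = 1L, stringsAsFactors = FALSE)
}

test_that("stack clustering merges by gap and matches the naive oracle", {
  one <- cluster_stacks(mk_hits(c(100, 132), c(121, 153)))
  expect_length(one, 1L)
  expect_equal(one[[1]]$total_count, 2)
  two <- cluster_stacks(mk_hits(c(100, 222), c(121, 243)))
  expect_length(two, 2L)
  # opposite strands never merge
  mixed <- mk_hits(c(100, 105), c(121, 126), strand = c("+", "-"))
  expect_length(cluster_stacks(mixed), 2L)

  set.seed(8)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    df <- mk_hits(starts <- sample(2000, n),
                  starts + sample(18:26, n, replace = TRUE),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  chrom = sample(c("c1", "c2"), n, replace = TRUE))
    got <- cluster_stacks(df, max_gap = 30)
    comp <- naive_cluster(df, max_gap = 30)
    expect_equal(length(got), length(unique(comp)))
    # same membership: every oracle component appears as one stack
    key <- paste(df$refname, df$strand, comp)
    sizes_oracle <- sort(as.integer(table(key)))
    sizes_got <- sort(vapply(got, function(s) nrow(s$placements), integer(1)))
    expect_equal(sizes_got, sizes_oracle)
  }
})

test_that("window excision follows the 15/70 extension rule and clips", {
  genome <- c(chr1 = strrep("ACGT", 1000))
  st <- cluster_stacks(mk_hits(1001, 1022, counts = 5))[[1]]
  w <- excise_windows(genome, st)
  expect_length(w, 2L)
  expect_equal(c(w[[1]]$start, w[[1]]$end), c(986L, 1092L))   # 5p window
  expect_equal(c(w[[2]]$start, w[[2]]$end), c(931L, 1037L))   # 3p window
  # near the contig start the 3p window clips but is still emitted
  st2 <- cluster_stacks(mk_hits(11, 32, counts = 5))[[1]]
  w2 <- excise_windows(genome, st2)
  expect_length(w2, 2L)
  expect_equal(w2[[2]]$start, 1L)
  # a stack on a tiny contig is skipped with a reason
  tiny <- c(chr1 = strrep("ACGT", 8))
  st3 <- cluster_stacks(mk_hits(3, 24, counts = 2))[[1]]
  w3 <- excise_windows(tiny, st3)
  expect_length(w3, 0L)
  expect_length(attr(w3, "skipped"), 2L)
})

# build a planted hairpin window plus a Dicer-consistent stack
planted_candidate <- function(seed = 9, n_mature = 40, n_star = 6,
                              n_loop = 0, strand = "+") {
  set.seed(seed)
  hp <- make_hairpin(mature_len = 22, loop_len = 8, bulges = 1)
  lead <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  tail <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  tx <- paste0(lead, hp$precursor, tail)
  genome <- c(chr1 = if (strand == "+") tx else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx))))
  # transcript-relative product intervals
  m_rel <- 300L + hp$mature_rel
  s_rel <- 300L + hp$star_rel
  to_g <- function(rel) {
    if (strand == "+") rel else c(nchar(tx) - rel[2] + 1L,
                                  nchar(tx) - rel[1] + 1L)
  }
  gm <- to_g(m_rel); gs <- to_g(s_rel)
  # collapsed placements: one tag per product carrying the read multiplicity
  hits <- rbind(
    mk_hits(gm[1], gm[2], counts = n_mature, strand = strand),
    if (n_star > 0) mk_hits(gs[1], gs[2], counts = n_star, strand = strand),
    if (n_loop > 0) mk_hits(gm[2] - 10, gm[2] + 11, counts = n_loop,
                            strand = strand))
  hits$tag_id <- paste0("t", seq_len(nrow(hits)))
  list(genome = genome, hits = hits, gm = gm, gs = gs, hp = hp)
}

test_that("stack partitioning assigns mature, star, loop and inconsistent reads", {
  pc <- planted_candidate(n_mature = 30, n_star = 5, n_loop = 2)
  res <- discover_novel_mirnas(pc$genome, pc$hits)
  cand <- res$candidates
  best <- cand[which.max(cand$scoreA), ]
  expect_equal(best$mature_count, 30)
  expect_equal(best$star_count, 5)
  # the read spanning the loop center is inconsistent
  expect_equal(best$inconsistent_count, 2)
  expect_equal(best$mature_start, pc$gm[1])
  expect_equal(best$mature_end, pc$gm[2])
  # star interval sits on the opposite arm near the truth
  expect_lte(abs(best$star_start - pc$gs[1]), 3)
  expect_lte(abs(best$star_end - pc$gs[2]), 3)

  # all reads on one arm: no star evidence, nothing inconsistent
  pc2 <- planted_candidate(seed = 10, n_mature = 25, n_star = 0)
  res2 <- discover_novel_mirnas(pc2$genome, pc2$hits)
  best2 <- res2$candidates[which.max(res2$candidates$scoreA), ]
  expect_equal(best2$star_count, 0)
  expect_equal(best2$inconsistent_count, 0)
})

test_that("minus-strand candidates are recovered with oriented folding", {
  pc <- planted_candidate(seed = 12, n_mature = 30, n_star = 5,
                          strand = "-")
  res <- discover_novel_mirnas(pc$genome, pc$hits)
  called <- res$candidates[res$candidates$called, ]
  expect_equal(nrow(called), 1L)
  expect_equal(called$strand, "-")
  expect_equal(called$mature_start, pc$gm[1])
  expect_equal(called$mature_end, pc$gm[2])
})

test_that("predictor A scores as specified and is monotone in mature reads", {
  pc <- planted_candidate(n_mature = 50, n_star = 5)
  res <- discover_novel_mirnas(pc$genome, pc$hits)
  i <- which.max(res$candidates$scoreA)
  cand <- res$details[[i]]
  sa <- score_candidate_a(cand)
  cons <- (cand$mature_count + cand$star_count + cand$loop_count) /
    cand$total_count
  dens <- cand$fold$score / nchar(cand$fold$sequence)
  expect_equal(sa$scoreA,
               2 * log2(1 + cand$mature_count) + 4 * cons + 10 * dens +
                 3 * (cand$star_count > 0) - 6 * (1 - cons))
  expect_true(sa$passA)
  # degenerate config: all-zero weights
  expect_equal(score_candidate_a(cand, weights = rep(0, 5))$scoreA, 0)
  # monotonicity: adding consistent mature reads never decreases the score
  prev <- -Inf
  for (extra in c(0, 10, 50, 200)) {
    c2 <- cand
    c2$mature_count <- cand$mature_count + extra
    c2$total_count <- cand$total_count + extra
    s <- score_candidate_a(c2)$scoreA
    expect_gte(s, prev)
    prev <- s
  }
  # a candidate with zero consistent reads is bounded by the fold density
  c0 <- cand
  c0$mature_count <- 0; c0$star_count <- 0; c0$loop_count <- 0
  c0$inconsistent_count <- c0$total_count
  s0 <- score_candidate_a(c0)
  expect_lte(s0$scoreA, 10 * dens)
  expect_false(s0$passA)
})

test_that("the rule filter enforces each bound, inclusively at the boundary", {
  pc <- planted_candidate(n_mature = 50, n_star = 5)
  res <- discover_novel_mirnas(pc$genome, pc$hits)
  cand <- res$details[[which.max(res$candidates$scoreA)]]
  expect_true(rule_filter_b(cand))
  # mature length out of bounds
  c2 <- cand; c2$mature_local <- c(cand$mature_local[1],
                                   cand$mature_local[1] + 29L)
  expect_false(rule_filter_b(c2))
  # thresholds met exactly still pass (boundary inclusive)
  expect_true(rule_filter_b(cand,
                            min_stem = cand$fold$longest_stem,
                            min_mature_count = cand$mature_count,
                            min_density = cand$fold$score /
                              nchar(cand$fold$sequence)))
  # one notch beyond fails
  expect_false(rule_filter_b(cand, min_stem = cand$fold$longest_stem + 1L))
  expect_false(rule_filter_b(cand,
                             min_mature_count = cand$mature_count + 1))
})

test_that("unstructured mRNA-fragment stacks fail the structural rules", {
  set.seed(13)
  frag <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                collapse = "")
  genome <- c(chr1 = frag)
  hits <- mk_hits(rep(301, 30), rep(322, 30))
  res <- discover_novel_mirnas(genome, hits)
  expect_true(all(!res$candidates$passB))
  expect_equal(sum(res$candidates$called), 0L)
})

test_that("consensus requires both predictors and merges duplicate loci", {
  base <- data.frame(chrom = "chr1", start = c(100L, 110L, 400L),
                     end = c(210L, 220L, 510L), strand = "+",
                     mature_arm = c("5p", "5p", "3p"),
                     scoreA = c(20, 15, 9),
                     passA = c(TRUE, TRUE, TRUE),
                     passB = c(TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  out <- consensus_and_name(base)
  expect_equal(out$consensus, c(TRUE, TRUE, FALSE))
  # rows 1 and 2 overlap ~91%: the higher scoreA survives
  expect_equal(out$called, c(TRUE, FALSE, FALSE))
  expect_equal(out$name[1], "miR-N1")
  expect_equal(out$mature_product[1], "miR-N1-5p")
  expect_equal(out$star_product[1], "miR-N1-3p")
  # naming follows genome order and is invariant to input order
  base2 <- base[c(3, 1, 2), ]
  out2 <- consensus_and_name(base2)
  expect_equal(sort(out2$name[out2$called]), sort(out$name[out$called]))
  expect_equal(out2[out2$called, c("chrom", "start", "end", "name")],
               out[out$called, c("chrom", "start", "end", "name")],
               ignore_attr = TRUE)
})

test_that("impossible thresholds yield zero consensus calls", {
  pc <- planted_candidate(n_mature = 50, n_star = 5)
  res <- discover_novel_mirnas(pc$genome, pc$hits,
                               rule_args = list(min_mature_count = 1e9))
  expect_equal(sum(res$candidates$called), 0L)
  expect_true(all(!res$candidates$consensus))
})

test_that("novel call GFF3 export round-trips through rtracklayer", {
  pc <- planted_candidate(n_mature = 40, n_star = 6)
  res <- discover_novel_mirnas(pc$genome, pc$hits)
  tmp <- withr::local_tempfile(fileext = ".gff3")
  export_novel_gff(res$candidates, tmp)
  back <- rtracklayer::import(tmp, format = "gff3")
  called <- res$candidates[res$candidates$called, ]
  expect_equal(sum(S4Vectors::mcols(back)$type == "miRNA_primary_transcript"),
               nrow(called))
  expect_true(all(called$name %in% S4Vectors::mcols(back)$ID))
})
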