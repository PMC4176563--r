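mk_ann <- function(mat_df, pre_df = NULL) {
  if (is.null(pre_df)) {
    pre_df <- data.frame(name = paste0("pre-", mat_df$name),
                         chrom = mat_df$chrom,
                         start = mat_df$start - 10L, end = mat_df$end + 30L,
                         strand = mat_df$strand, stringsAsFactors = FALSE)
    mat_df$precursor_name <- pre_df$name
  }
  list(precursors = pre_df, matures = mat_df)
}

test_that("unique placements count fully; multi-mapped mass splits 1/M", {
  ann <- mk_ann(data.frame(name = c("mirA", "mirB"), chrom = "chr1",
                           start = c(100L, 500L), end = c(121L, 521L),
                           strand = "+", stringsAsFactors = FALSE))
  hits1 <- data.frame(tag_id = "t1", refname = "chr1", start = 100L,
                      end = 121L, strand = "+", mismatches = 0L,
                      count = 10L, multiplicity = 1L,
                      stringsAsFactors = FALSE)
  c1 <- count_known_mirnas(hits1, ann)
  expect_equal(c1$raw_count[c1$mirna_name == "mirA"], 10)
  # same tag placed in two miRNA windows: M = 2, count 10 -> 5 at each
  hits2 <- rbind(hits1, transform(hits1, start = 500L, end = 521L))
  c2 <- count_known_mirnas(hits2, ann)
  expect_equal(c2$raw_count, c(5, 5))
  expect_equal(attr(c2, "assigned_tag_mass"), 10)
  expect_equal(sum(c2$raw_count), attr(c2, "assigned_tag_mass"))
})

test_that("the assignment window is [-2,+5] around the mature, strand-aware", {
  ann <- mk_ann(data.frame(name = "mirP", chrom = "chr1", start = 100L,
                           end = 121L, strand = "+",
                           stringsAsFactors = FALSE))
  mk_hit <- function(s, e, strand = "+")
    data.frame(tag_id = "t1", refname = "chr1", start = s, end = e,
               strand = strand, mismatches = 0L, count = 1L,
               multiplicity = 1L, stringsAsFactors = FALSE)
  # plus strand: 2 nt slack on the 5' (left) side, 5 nt on the 3' (right)
  expect_equal(sum(count_known_mirnas(mk_hit(98L, 126L), ann)$raw_count), 1)
  expect_equal(sum(count_known_mirnas(mk_hit(97L, 121L), ann)$raw_count), 0)
  expect_equal(sum(count_known_mirnas(mk_hit(100L, 127L), ann)$raw_count), 0)
  # wrong strand never counts
  expect_equal(sum(count_known_mirnas(mk_hit(100L, 121L, "-"), ann)$raw_count), 0)
  # minus strand: the slack flips in genomic coordinates
  annm <- mk_ann(data.frame(name = "mirM", chrom = "chr1", start = 100L,
                            end = 121L, strand = "-",
                            stringsAsFactors = FALSE))
  expect_equal(sum(count_known_mirnas(mk_hit(95L, 123L, "-"), annm)$raw_count), 1)
  expect_equal(sum(count_known_mirnas(mk_hit(94L, 121L, "-"), annm)$raw_count), 0)
})

test_that("annotation intervals off the reference raise a named error", {
  ann <- mk_ann(data.frame(name = "mirX", chrom = "chr1", start = 990L,
                           end = 1011L, strand = "+",
                           stringsAsFactors = FALSE))
  hits <- data.frame(tag_id = "t1", refname = "chr1", start = 990L,
                     end = 1011L, strand = "+", mismatches = 0L,
                     count = 1L, multiplicity = 1L, stringsAsFactors = FALSE)
  expect_error(count_known_mirnas(hits, ann, seqlens = c(chr1 = 1000L)),
               "mirX")
})

test_that("strand safety: mirroring the genome leaves all counts unchanged", {
  set.seed(5)
  L <- 3000L
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = ""))
  mat <- data.frame(name = paste0("m", 1:5), chrom = "chr1",
                    start = seq(200L, 2200L, by = 500L),
                    end = seq(200L, 2200L, by = 500L) + 21L,
                    strand = sample(c("+", "-"), 5, replace = TRUE),
                    stringsAsFactors = FALSE)
  ann <- mk_ann(mat)
  tags <- data.frame(tag_id = paste0("t", 1:5),
                     sequence = vapply(1:5, function(i) {
                       s <- substr(genome[["chr1"]], mat$start[i], mat$end[i])
                       if (mat$strand[i] == "-")
                         s <- as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(s)))
                       s
                     }, character(1)),
                     count = c(3L, 7L, 2L, 9L, 4L), stringsAsFactors = FALSE)
  idx <- build_index(genome, k = 8)
  counts <- count_known_mirnas(align_tags(tags, idx), ann)

  rc_genome <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome[["chr1"]]))))
  mat_rc <- mat
  mat_rc$start <- L - mat$end + 1L
  mat_rc$end <- L - mat$start + 1L
  mat_rc$strand <- ifelse(mat$strand == "+", "-", "+")
  counts_rc <- count_known_mirnas(align_tags(tags, build_index(rc_genome, k = 8)),
                                  mk_ann(mat_rc))
  expect_equal(counts$raw_count, counts_rc$raw_count)
})

test_that("rpm_normalize implements C/(M N) * scale with its edge cases", {
  expect_equal(rpm_normalize(0, 1, 123), 0)
  expect_equal(rpm_normalize(100, 1, 1e6), 1e5)
  expect_equal(rpm_normalize(100, 4, 1e6), 25000)
  expect_error(rpm_normalize(1, 1, 0), "N")
  expect_error(rpm_normalize(1, 0.5, 10), "M")
  expect_error(rpm_normalize(-1, 1, 10), "non-negative")
  # linearity in C
  set.seed(6)
  C <- runif(50, 0, 1e4); a <- 3.7
  expect_equal(rpm_normalize(a * C, 2, 1e5), a * rpm_normalize(C, 2, 1e5))
})

test_that("expression matrix assembly is deterministic with zero fill", {
  rec <- data.frame(mirna_name = c("mA", "mA", "mB", "mB", "mA"),
                    sample = c("s1", "s2", "s1", "s3", "s3"),
                    value = c(1, 2, 3, 4, 5), stringsAsFactors = FALSE)
  m <- build_expression_matrix(rec)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["mB", "s2"], 0)
  expect_equal(m["mA", "s3"], 5)
  set.seed(7)
  m2 <- build_expression_matrix(rec[sample(nrow(rec)), ])
  expect_identical(m, m2)
  expect_error(build_expression_matrix(rbind(rec, rec[1, ])), "duplicate")
})

test_that("miRBase-style GFF3 annotations round-trip through rtracklayer", {
  ann <- list(
    precursors = data.frame(name = c("pre1", "pre2"), chrom = "chr1",
                            start = c(100L, 400L), end = c(170L, 470L),
                            strand = c("+", "-"), stringsAsFactors = FALSE),
    matures = data.frame(name = c("pre1-5p", "pre2-5p"),
                         precursor_name = c("pre1", "pre2"), chrom = "chr1",
                         start = c(110L, 440L), end = c(131L, 461L),
                         strand = c("+", "-"), stringsAsFactors = FALSE))
  tmp <- withr::local_tempfile(fileext = ".gff3")
  mirstack:::.write_annotation_gff(ann, tmp)
  back <- read_mirna_annotations(tmp)
  expect_equal(back$precursors, ann$precursors)
  expect_equal(back$matures, ann$matures)
})
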