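test_that("read_fastq parses records in order and validates structure", {
  fx <- read_fastq(toy_fixture_path())
  expect_equal(nrow(fx), 12L)
  expect_equal(fx$read_id[1], "r01_kept_22nt")
  expect_equal(fx$read_id[12], "r12_too_short_10nt")
  expect_equal(nchar(fx$sequence), nchar(fx$quality))

  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), tmp)
  one <- read_fastq(tmp)
  expect_equal(one$read_id, "r1")
  expect_equal(one$sequence, "ACGT")

  writeLines(character(0), tmp)
  expect_equal(nrow(read_fastq(tmp)), 0L)

  writeLines(c("@r1", "ACGT", "+", "III"), tmp)
  expect_error(read_fastq(tmp), "length mismatch at line 2")
  writeLines(c("r1", "ACGT", "+", "IIII"), tmp)
  expect_error(read_fastq(tmp), "'@' at line 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACXT", "+", "IIII"), tmp)
  expect_error(read_fastq(tmp), "non-IUPAC character in sequence at line 6")
  expect_error(read_fastq(file.path(tempdir(), "nope.fastq")), "no such file")
})

test_that("read_fastq falls back to FASTA input", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 desc", "ACGTACGT", ">s2", "TTTT"), tmp)
  fa <- read_fastq(tmp)
  expect_equal(fa$read_id, c("s1", "s2"))
  expect_equal(fa$sequence, c("ACGTACGT", "TTTT"))
  expect_true(all(is.na(fa$quality)))
})

test_that("find_adapter3 honors the 6-18 nt flank rule", {
  rules <- toy_rules()
  a3 <- rules$adapter3
  # constructed: 8 nt insert + 8 nt adapter prefix
  expect_equal(find_adapter3(paste0("ACGTACGT", substr(a3, 1, 8)), rules), 8L)
  # only 5 nt of adapter at the end: below the minimum flank
  expect_true(is.na(find_adapter3(paste0("ACGTACGTACGTACGTACGTA",
                                         substr(a3, 1, 5)), rules)))
  # full read-through matches anywhere
  expect_equal(find_adapter3(paste0("ACCGTTACCGTTACCGTTAC", a3, "GTT"),
                             rules), 20L)
})

test_that("find_adapter3 agrees with the brute-force (position, flank) scan", {
  rules <- toy_rules()
  a3 <- rules$adapter3
  set.seed(42)
  seqs <- vapply(1:1000, function(i) {
    ins <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    fl <- sample(0:18, 1)
    paste0(ins, substr(a3, 1, fl))
  }, character(1))
  got <- find_adapter3(seqs, rules)
  want <- vapply(seqs, brute_find_adapter3, integer(1), rules = rules,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("filtration cascade reproduces the hand-verified fixture truth", {
  res <- apply_filters(read_fastq(toy_fixture_path()), toy_rules())
  rep <- filter_report(res$status)
  counts <- stats::setNames(rep$reads, rep$rule)
  expect_identical(counts[["input"]], 12L)
  expect_identical(counts[["adapter5"]], 2L)
  expect_identical(counts[["no_adapter3"]], 2L)
  expect_identical(counts[["ambiguous"]], 1L)
  expect_identical(counts[["polyA"]], 2L)
  expect_identical(counts[["length"]], 1L)
  expect_identical(counts[["kept"]], 4L)
  # conservation: input = kept + sum(discarded)
  expect_identical(counts[["input"]],
                   counts[["kept"]] + sum(counts[c("adapter5", "no_adapter3",
                                                   "ambiguous", "polyA",
                                                   "length")]))
  # kept reads are trimmed to their inserts
  kept <- res[res$status == "kept", ]
  expect_equal(kept$insert[1], "ACGTACGTACGTACGTACGTAC")
  expect_equal(nchar(kept$insert), c(22L, 18L, 20L, 26L))
})

test_that("individual discard rules trigger as specified", {
  rules <- toy_rules()
  a3 <- rules$adapter3
  flank <- substr(a3, 1, 14)
  # poly-A insert
  expect_equal(apply_filters(paste0(strrep("A", 22), flank), rules)$status,
               "polyA")
  # ambiguous nucleotide in the insert
  expect_equal(apply_filters(paste0("ACGNACGTACGTACGTACG", flank),
                             rules)$status, "ambiguous")
  # clean 22 nt insert with 10 nt flank is kept and trimmed
  ins <- "GCATGCATGCATGCATGCATGC"
  r <- apply_filters(paste0(ins, substr(a3, 1, 10)), rules)
  expect_equal(r$status, "kept")
  expect_equal(r$insert, ins)
  # terminal A-run shorter than the threshold is kept
  ins2 <- paste0("GCATGCATGCATGCG", strrep("A", 7))
  r2 <- apply_filters(paste0(ins2, flank), rules)
  expect_equal(r2$status, "kept")
})

test_that("re-trimming a kept insert with the adapter re-appended is stable", {
  rules <- toy_rules()
  res <- apply_filters(read_fastq(toy_fixture_path()), rules)
  kept <- res$insert[res$status == "kept"]
  again <- apply_filters(paste0(kept, rules$adapter3), rules)
  expect_true(all(again$status == "kept"))
  expect_equal(again$insert, kept)
})

test_that("collapse_reads is order independent, deterministic and conserving", {
  tags <- collapse_reads(c("ACGT", "ACGT", "GGGC"))
  expect_equal(tags$sequence, c("ACGT", "GGGC"))
  expect_equal(tags$count, c(2L, 1L))
  expect_equal(tags$tag_id, c("t1", "t2"))
  expect_equal(nrow(collapse_reads(character(0))), 0L)

  set.seed(7)
  pool <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = ""),
    character(1))
  reads <- sample(pool, 1e4, replace = TRUE,
                  prob = stats::rlnorm(30))
  t1 <- collapse_reads(reads)
  t2 <- collapse_reads(sample(reads))
  expect_identical(t1, t2)
  expect_equal(sum(t1$count), 1e4)
})

test_that("filter_rules validates its bounds", {
  expect_error(filter_rules(adapter3 = "ACGTACGT", min_len = 30, max_len = 20),
               "min_len")
  expect_error(filter_rules(adapter3 = "ACGTACGT", min_adapter_flank = 19),
               "min_adapter_flank")
  expect_error(filter_rules(adapter3 = "ACGU"), "DNA")
})
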