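# Read filtration and collapsing.
#
# Reproduces the filtration cascade of small-RNA libraries: reads must be
# free of a 5' adapter, carry a 6-18 nt flank of the 3' adapter (or the full
# adapter, read-through), contain no ambiguous bases or poly-A tracts in the
# trimmed insert, and fall in the mature miRNA length window.  Surviving
# inserts are collapsed to unique tags with multiplicities.

#' Filtration rule set
#'
#' Validated container of the filtration parameters.  A read is kept when it
#' carries no 5' adapter, ends in a \code{min_adapter_flank}..
#' \code{max_adapter_flank} nt prefix of the 3' adapter (or contains the full
#' adapter, i.e. read-through), and its trimmed insert has at most
#' \code{max_ambiguous} non-ACGT bases, no poly-A tract (terminal A-run of
#' \code{polya_min_run} nt or more, or 80 percent A overall), and length in
#' \code{[min_len, max_len]}.
#'
#' @param adapter3 character(1), 3' adapter sequence (required).
#' @param adapter5 character(1) or NULL, optional 5' adapter.
#' @param min_adapter_flank,max_adapter_flank integer, allowed partial 3'
#'   adapter match lengths at the read end (defaults 6 and 18 nt).
#' @param polya_min_run integer, terminal A-run length that marks a poly-A
#'   artifact (default 8 nt).
#' @param max_ambiguous integer, maximum non-ACGT bases in the insert
#'   (default 0).
#' @param min_len,max_len integer, insert length window (defaults 18 and 26).
#' @param max_mismatch integer, mismatches tolerated in the adapter flank
#'   match (default 0, exact matching).
#' @return A list of class \code{filter_rules}.
#' @export
filter_rules <- function(adapter3, adapter5 = NULL,
                         min_adapter_flank = 6L, max_adapter_flank = 18L,
                         polya_min_run = 8L, max_ambiguous = 0L,
                         min_len = 18L, max_len = 26L, max_mismatch = 0L) {
  stopifnot(is.character(adapter3), length(adapter3) == 1L, nchar(adapter3) >= 1L)
  adapter3 <- toupper(adapter3)
  if (!grepl("^[ACGT]+$", adapter3)) stop("adapter3 must be a DNA string over ACGT")
  if (!is.null(adapter5)) {
    adapter5 <- toupper(adapter5)
    if (!grepl("^[ACGT]+$", adapter5)) stop("adapter5 must be a DNA string over ACGT")
  }
  min_adapter_flank <- as.integer(min_adapter_flank)
  max_adapter_flank <- as.integer(max_adapter_flank)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_adapter_flank > max_adapter_flank)
    stop("min_adapter_flank must be <= max_adapter_flank")
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (min_adapter_flank < 1L || min_len < 1L || polya_min_run < 1L)
    stop("all lengths must be positive")
  if (max_mismatch != 0L)
    stop("only exact adapter matching (max_mismatch = 0) is implemented")
  structure(list(adapter3 = adapter3, adapter5 = adapter5,
                 min_adapter_flank = min_adapter_flank,
                 max_adapter_flank = max_adapter_flank,
                 polya_min_run = as.integer(polya_min_run),
                 max_ambiguous = as.integer(max_ambiguous),
                 min_len = min_len, max_len = max_len,
                 max_mismatch = 0L),
            class = "filter_rules")
}

#' Read a FASTQ (or FASTA) file into a read table
#'
#' Parses 4-line FASTQ records (phred+33 qualities are carried along but not
#' used for filtering); a file starting with \code{>} is read as FASTA and
#' the quality column is \code{NA}.  Malformed FASTQ records raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @return data.frame with columns \code{read_id}, \code{sequence},
#'   \code{quality}; zero rows for an empty file.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > suppressWarnings(max(which(nzchar(lines)), 0)))]
  if (!length(lines))
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (startsWith(lines[1L], ">")) {
    dna <- Biostrings::readDNAStringSet(path)
    return(data.frame(read_id = sub("\\s.*$", "", names(dna)),
                      sequence = as.character(dna),
                      quality = NA_character_, stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record starting at line ",
         4L * (length(lines) %/% 4L) + 1L)
  hd <- lines[seq(1L, length(lines), by = 4L)]
  sq <- toupper(lines[seq(2L, length(lines), by = 4L)])
  pl <- lines[seq(3L, length(lines), by = 4L)]
  qu <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("FASTQ record header missing '@' at line ", (bad[1L] - 1L) * 4L + 1L)
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("FASTQ separator missing '+' at line ", (bad[1L] - 1L) * 4L + 3L)
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop("sequence/quality length mismatch at line ", (bad[1L] - 1L) * 4L + 2L)
  bad <- which(grepl("[^ACGTN]", sq))
  if (length(bad))
    stop("non-IUPAC character in sequence at line ", (bad[1L] - 1L) * 4L + 2L)
  bad <- which(nchar(sq) < 1L)
  if (length(bad))
    stop("empty sequence at line ", (bad[1L] - 1L) * 4L + 2L)
  data.frame(read_id = sub("\\s.*$", "", sub("^@", "", hd)),
             sequence = sq, quality = qu, stringsAsFactors = FALSE)
}

#' Locate the 3' adapter in read sequences
#'
#' Returns, for each sequence, the leftmost trim position p (the length of the
#' kept insert) such that the remainder of the read either (a) is exactly a
#' prefix of the 3' adapter of length between \code{min_adapter_flank} and
#' \code{max_adapter_flank}, or (b) begins with the complete adapter
#' (read-through), or \code{NA} when no such position exists.
#'
#' @param sequences character vector of read sequences.
#' @param rules a \code{\link{filter_rules}} object.
#' @return integer vector of insert lengths (possibly 0), NA when the adapter
#'   flank is absent.
#' @export
find_adapter3 <- function(sequences, rules) {
  stopifnot(inherits(rules, "filter_rules"))
  a3 <- rules$adapter3
  la <- nchar(a3)
  hi <- min(rules$max_adapter_flank, la)
  alts <- character(0)
  if (hi >= rules$min_adapter_flank) {
    flanks <- hi:rules$min_adapter_flank
    alts <- paste0(vapply(flanks, function(l) substr(a3, 1L, l), character(1)), "$")
  }
  pattern <- paste(c(a3, alts), collapse = "|")
  pos <- regexpr(pattern, sequences, perl = TRUE)
  out <- as.integer(pos) - 1L
  out[pos == -1L] <- NA_integer_
  out
}

#' Apply the filtration cascade to reads
#'
#' Discard reasons are evaluated in a fixed order per read:
#' \code{adapter5} (5' adapter present within the first
#' \code{max_adapter_flank} bases), \code{no_adapter3} (no 3' adapter flank),
#' \code{ambiguous} (insert has more than \code{max_ambiguous} non-ACGT
#' bases), \code{polyA} (terminal A-run of \code{polya_min_run}+ nt, or the
#' insert is at least 80 percent A), \code{length} (insert outside
#' \code{[min_len, max_len]}).  Kept reads report the trimmed insert.
#'
#' @param sequences character vector of read sequences (or a data.frame from
#'   \code{\link{read_fastq}}).
#' @param rules a \code{\link{filter_rules}} object.
#' @return data.frame with columns \code{sequence}, \code{insert} (NA unless
#'   a 3' adapter was found), \code{status} ("kept" or the discard reason).
#' @export
apply_filters <- function(sequences, rules) {
  stopifnot(inherits(rules, "filter_rules"))
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  n <- length(sequences)
  if (!n)
    return(data.frame(sequence = character(), insert = character(),
                      status = character(), stringsAsFactors = FALSE))
  sequences <- toupper(sequences)
  status <- rep(NA_character_, n)

  if (!is.null(rules$adapter5)) {
    p5 <- regexpr(rules$adapter5, sequences, fixed = TRUE)
    status[p5 != -1L & p5 <= rules$max_adapter_flank] <- "adapter5"
  }
  p3 <- find_adapter3(sequences, rules)
  status[is.na(status) & is.na(p3)] <- "no_adapter3"

  insert <- rep(NA_character_, n)
  live <- is.na(status)
  insert[live] <- substr(sequences[live], 1L, p3[live])

  len <- nchar(insert)
  n_amb <- len - nchar(gsub("[^ACGT]", "", insert))
  status[live & n_amb > rules$max_ambiguous] <- "ambiguous"
  live <- is.na(status)

  arun <- regexpr("A+$", insert)
  arun_len <- ifelse(arun == -1L, 0L, attr(arun, "match.length"))
  n_a <- len - nchar(gsub("A", "", insert, fixed = TRUE))
  frac_a <- ifelse(len > 0L, n_a / len, 0)
  status[live & (arun_len >= rules$polya_min_run | (len > 0L & frac_a >= 0.8))] <- "polyA"
  live <- is.na(status)

  status[live & (len < rules$min_len | len > rules$max_len)] <- "length"
  status[is.na(status)] <- "kept"
  data.frame(sequence = sequences, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

.FILTER_RULE_ORDER <- c("adapter5", "no_adapter3", "ambiguous", "polyA", "length")

#' Summarize a filtration run
#'
#' @param status character vector of per-read statuses from
#'   \code{\link{apply_filters}}.
#' @return data.frame with one row per rule (in evaluation order) plus
#'   \code{input} and \code{kept}; satisfies
#'   input = kept + sum(discarded).
#' @export
filter_report <- function(status) {
  counts <- vapply(.FILTER_RULE_ORDER, function(r) sum(status == r), integer(1))
  data.frame(rule = c("input", .FILTER_RULE_ORDER, "kept"),
             reads = c(length(status), counts, sum(status == "kept")),
             stringsAsFactors = FALSE)
}

#' Collapse kept inserts to unique tags
#'
#' Identical sequences are collapsed to one tag carrying the read
#' multiplicity.  Tags are ordered by count (descending) then sequence
#' (lexicographic) and named \code{t1}, \code{t2}, ...; the order is
#' independent of the input read order.
#'
#' @param inserts character vector of kept (trimmed) insert sequences.
#' @return data.frame with columns \code{tag_id}, \code{sequence},
#'   \code{count}.
#' @export
collapse_reads <- function(inserts) {
  if (!length(inserts))
    return(data.frame(tag_id = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  tab <- table(inserts)
  sq <- names(tab)
  ct <- as.integer(tab)
  o <- order(-ct, sq, method = "radix")
  data.frame(tag_id = paste0("t", seq_along(o)),
             sequence = sq[o], count = ct[o], stringsAsFactors = FALSE)
}

#' Preprocess one sample end to end
#'
#' Runs \code{\link{apply_filters}}, \code{\link{filter_report}} and
#' \code{\link{collapse_reads}} on a read table.
#'
#' @param reads data.frame from \code{\link{read_fastq}} or a character
#'   vector of sequences.
#' @param rules a \code{\link{filter_rules}} object.
#' @return list with \code{tags} (collapsed tag table), \code{report}
#'   (filter report), and \code{filtered} (per-read status table).
#' @export
preprocess_sample <- function(reads, rules) {
  filt <- apply_filters(reads, rules)
  tags <- collapse_reads(filt$insert[filt$status == "kept"])
  list(tags = tags, report = filter_report(filt$status), filtered = filt)
}

#' Write collapsed tags as FASTA
#'
#' Headers use the collapsed-read dialect \code{>tagid_xCOUNT} common to
#' small-RNA pipelines.
#'
#' @param tags tag table from \code{\link{collapse_reads}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  if (!nrow(tags)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(2L * nrow(tags))
  out[c(TRUE, FALSE)] <- paste0(">", tags$tag_id, "_x", tags$count)
  out[c(FALSE, TRUE)] <- tags$sequence
  writeLines(out, path)
  invisible(path)
}

#' Write a filter report as TSV
#' @param report data.frame from \code{\link{filter_report}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
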