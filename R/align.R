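# k-mer seed alignment of collapsed tags.
#
# Full-length, ungapped placement of short tags on a reference with at most
# one substitution.  Two non-overlapping k-mer seed windows per query
# guarantee that any placement with <= 1 mismatch is found (pigeonhole), and
# every candidate diagonal is verified base by base.

#' Build a k-mer seed index over reference sequences
#'
#' @param sequences named character vector, or a
#'   \code{Biostrings::DNAStringSet}, of reference sequences over A,C,G,T,N.
#'   k-mers containing N are never indexed as seeds.
#' @param k integer seed length, at least 8 and no longer than the shortest
#'   reference sequence.
#' @param name label for the index (used in messages).
#' @return A list of class \code{kmer_index}.
#' @export
build_index <- function(sequences, k = 8L, name = "reference") {
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  k <- as.integer(k)
  if (!length(sequences)) stop("empty reference: no sequences to index")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("reference sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence ids in reference")
  if (k < 8L) stop("seed length k must be >= 8")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (k > min(lens))
    stop("k (", k, ") exceeds the shortest reference sequence (", min(lens), ")")

  sid <- integer(0); pos <- integer(0); kmer <- character(0)
  for (s in seq_along(sequences)) {
    n <- lens[s]
    starts <- seq_len(n - k + 1L)
    km <- substring(sequences[[s]], starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    sid <- c(sid, rep.int(s, sum(ok)))
    pos <- c(pos, starts[ok])
    kmer <- c(kmer, km[ok])
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  idx <- split(seq_along(kmer), kmer)
  packed <- lapply(idx, function(i) cbind(sid = sid[i], pos = pos[i]))
  list2env(packed, envir = env)
  structure(list(name = name, k = k, env = env,
                 sequences = sequences, seqnames = names(sequences),
                 seqlens = lens),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index '%s': %d sequence(s), %s nt total, k = %d\n",
              x$name, length(x$sequences),
              format(sum(x$seqlens), big.mark = ","), x$k))
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.count_mismatches <- function(a, b) {
  if (a == b) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# candidate start positions for one oriented query against the index
.seed_candidates <- function(q, index) {
  k <- index$k
  L <- nchar(q)
  if (L < k) return(NULL)
  offs <- if (L >= 2L * k) c(1L, k + 1L) else unique(c(1L, L - k + 1L))
  cand <- NULL
  for (o in offs) {
    hits <- get0(substr(q, o, o + k - 1L), envir = index$env)
    if (!is.null(hits)) {
      cand <- rbind(cand, cbind(sid = hits[, 1L], start = hits[, 2L] - o + 1L))
    }
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[cand[, 2L] >= 1L &
                 cand[, 2L] + L - 1L <= index$seqlens[cand[, 1L]], , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  unique(cand)
}

#' Align tags against an indexed reference
#'
#' Reports every full-length ungapped placement of each tag, on both strands,
#' with at most \code{max_mismatch} substitutions (N in the reference counts
#' as a mismatch).  Hits are ordered by (reference, start, strand); tags
#' without hits are absent from the output.  Tags shorter than
#' \code{2 * k} are only guaranteed complete at \code{max_mismatch = 0}.
#'
#' @param tags data.frame with columns \code{tag_id}, \code{sequence} and
#'   optionally \code{count} (defaults to 1).
#' @param index a \code{\link{build_index}} object.
#' @param max_mismatch 0 or 1 substitutions (default 0).
#' @return data.frame with columns \code{tag_id}, \code{refname},
#'   \code{start}, \code{end} (1-based, inclusive), \code{strand},
#'   \code{mismatches}, \code{count}, \code{multiplicity} (number of
#'   placements of that tag in this reference).
#' @export
align_tags <- function(tags, index, max_mismatch = 0L) {
  stopifnot(inherits(index, "kmer_index"))
  max_mismatch <- as.integer(max_mismatch)
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  if (!nrow(tags)) return(.empty_hits())
  counts <- if ("count" %in% names(tags)) tags$count else rep(1L, nrow(tags))
  fwd <- toupper(tags$sequence)
  rev <- .revcomp(fwd)

  res <- vector("list", nrow(tags))
  for (t in seq_len(nrow(tags))) {
    L <- nchar(fwd[t])
    rows <- NULL
    for (strand in 1:2) {
      q <- if (strand == 1L) fwd[t] else rev[t]
      cand <- .seed_candidates(q, index)
      if (is.null(cand)) next
      refs <- substr(index$sequences[cand[, 1L]], cand[, 2L], cand[, 2L] + L - 1L)
      mm <- vapply(seq_along(refs),
                   function(i) .count_mismatches(refs[i], q), integer(1))
      keep <- mm <= max_mismatch
      if (any(keep)) {
        rows <- rbind(rows, cbind(tag = t, sid = cand[keep, 1L],
                                  start = cand[keep, 2L], strand = strand,
                                  mm = mm[keep]))
      }
    }
    res[[t]] <- rows
  }
  m <- do.call(rbind, res)
  if (is.null(m) || !nrow(m)) return(.empty_hits())
  L <- nchar(fwd)[m[, "tag"]]
  hits <- data.frame(tag_id = tags$tag_id[m[, "tag"]],
                     refname = index$seqnames[m[, "sid"]],
                     start = as.integer(m[, "start"]),
                     end = as.integer(m[, "start"] + L - 1L),
                     strand = c("+", "-")[m[, "strand"]],
                     mismatches = as.integer(m[, "mm"]),
                     count = counts[m[, "tag"]],
                     stringsAsFactors = FALSE)
  hits <- hits[!duplicated(hits[c("tag_id", "refname", "start", "strand")]), ]
  hits <- hits[order(hits$refname, hits$start, hits$strand, hits$tag_id,
                     method = "radix"), ]
  mult <- table(hits$tag_id)
  hits$multiplicity <- as.integer(mult[hits$tag_id])
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(tag_id = character(), refname = character(), start = integer(),
             end = integer(), strand = character(), mismatches = integer(),
             count = integer(), multiplicity = integer(),
             stringsAsFactors = FALSE)
}

#' Partition tags into known-miRNA, mRNA and unannotated sets
#'
#' Tags matching the known miRNA reference are called known; of the rest,
#' tags matching the mRNA reference are discarded as mRNA contamination; the
#' remainder is aligned to the genome, and genome-placed tags form the
#' novel-discovery input.  miRNA matches take precedence over mRNA matches.
#'
#' @param tags collapsed tag table.
#' @param mrna_index,mirna_index,genome_index \code{\link{build_index}}
#'   objects built with compatible settings.
#' @param max_mismatch passed to \code{\link{align_tags}}.
#' @return list with character vectors \code{known_mirna_tags},
#'   \code{mrna_tags}, \code{unannotated_tags}, \code{unaligned_tags}, plus
#'   \code{genome_hits} (placements of unannotated tags on the genome).
#' @export
partition_tags <- function(tags, mrna_index, mirna_index, genome_index,
                           max_mismatch = 0L) {
  if (!nrow(tags))
    return(list(known_mirna_tags = character(), mrna_tags = character(),
                unannotated_tags = character(), unaligned_tags = character(),
                genome_hits = .empty_hits()))
  mir_hits <- align_tags(tags, mirna_index, max_mismatch)
  known <- unique(mir_hits$tag_id)
  rest <- tags[!tags$tag_id %in% known, , drop = FALSE]
  mrna_hits <- if (nrow(rest)) align_tags(rest, mrna_index, max_mismatch) else .empty_hits()
  mrna <- unique(mrna_hits$tag_id)
  rest2 <- rest[!rest$tag_id %in% mrna, , drop = FALSE]
  gen_hits <- if (nrow(rest2)) align_tags(rest2, genome_index, max_mismatch) else .empty_hits()
  unann <- unique(gen_hits$tag_id)
  unaligned <- setdiff(rest2$tag_id, unann)
  list(known_mirna_tags = known, mrna_tags = mrna,
       unannotated_tags = unann, unaligned_tags = unaligned,
       genome_hits = gen_hits)
}
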