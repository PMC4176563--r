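# Independent oracles used across the suite.  Each deliberately uses a
# different algorithm than the implementation it checks.

# --- adapter search: literal scan over every (position, flank-length) pair
brute_find_adapter3 <- function(seq, rules) {
  n <- nchar(seq)
  a3 <- rules$adapter3
  la <- nchar(a3)
  for (p in 0:(n - 1)) {
    rem <- substr(seq, p + 1, n)
    L <- n - p
    if (L >= rules$min_adapter_flank && L <= rules$max_adapter_flank &&
        L <= la && rem == substr(a3, 1, L)) return(p)
    if (L >= la && substr(rem, 1, la) == a3) return(p)
  }
  NA_integer_
}

# --- folding: exhaustive first-position recursion over ALL valid structures
# (no memoization; explores every non-crossing pairing with min loop 3)
enum_fold_score <- function(seq, min_loop = 3L) {
  s <- chartr("Tt", "Uu", toupper(seq))
  b <- strsplit(s, "")[[1]]
  wt <- list(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
  w <- function(i, j) {
    v <- wt[[paste0(b[i], b[j])]]
    if (is.null(v)) 0 else v
  }
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- rec(i + 1, j)             # i unpaired
    for (q in (i + 1):j) {
      if (q - i > min_loop && w(i, q) > 0) {
        best <- max(best, w(i, q) + rec(i + 1, q - 1) + rec(q + 1, j))
      }
    }
    best
  }
  rec(1, length(b))
}

# --- Mann-Whitney: full enumeration of labelings, U by pairwise comparison
enum_mann_whitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  u_of <- function(xi, yi) {
    sum(outer(z[xi], z[yi], ">")) + 0.5 * sum(outer(z[xi], z[yi], "=="))
  }
  mu <- n1 * n2 / 2
  obs <- abs(u_of(seq_len(n1), n1 + seq_len(n2)) - mu)
  labelings <- utils::combn(n1 + n2, n1)
  devs <- apply(labelings, 2, function(xi) {
    abs(u_of(xi, setdiff(seq_len(n1 + n2), xi)) - mu)
  })
  mean(devs >= obs - 1e-9)
}

# --- Wilcoxon signed-rank: enumeration of all 2^n sign vectors
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  obs <- abs(sum(r[d > 0]) - mu)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mean(abs(ws - mu) >= obs - 1e-9)
}

# --- alignment: full-scan oracle via Biostrings matchPattern
scan_align <- function(tag_seq, genome, max_mismatch = 0L) {
  out <- NULL
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag_seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag_seq)))
      m <- Biostrings::matchPattern(q, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m)) {
        out <- rbind(out, data.frame(refname = chrom,
                                     start = Biostrings::start(m),
                                     end = Biostrings::end(m),
                                     strand = strand,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# --- Venn regions by direct set arithmetic
brute_venn_counts <- function(expressed) {
  sets <- lapply(1:3, function(j) which(expressed[, j]))
  a <- sets[[1]]; b <- sets[[2]]; c3 <- sets[[3]]
  c(length(setdiff(a, union(b, c3))),
    length(setdiff(b, union(a, c3))),
    length(setdiff(c3, union(a, b))),
    length(setdiff(intersect(a, b), c3)),
    length(setdiff(intersect(a, c3), b)),
    length(setdiff(intersect(b, c3), a)),
    length(intersect(a, intersect(b, c3))))
}

# --- single-linkage interval clustering, naive O(n^2)
naive_cluster <- function(df, max_gap) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- df$refname[i] == df$refname[j] &&
      df$strand[i] == df$strand[j] &&
      df$start[j] <= df$end[i] + max_gap &&
      df$start[i] <= df$end[j] + max_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}
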