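# RNA secondary structure by weighted base-pair maximization.
#
# A Nussinov-style interval dynamic program maximizes the summed pair weight
# (GC = 3, AU = 2, GU = 1) over all non-crossing structures with a minimum
# terminal-loop separation.  This trades thermodynamic realism for an exact,
# enumerable objective: for short sequences the optimum can be verified by
# exhaustive enumeration of every valid structure.

.PAIR_ALPHABET <- c("A", "C", "G", "U", "N")

# 5x5 weight lookup over A,C,G,U,N (N unpairable).
.pair_weight_table <- function() {
  w <- matrix(0, 5, 5, dimnames = list(.PAIR_ALPHABET, .PAIR_ALPHABET))
  w["G", "C"] <- w["C", "G"] <- 3
  w["A", "U"] <- w["U", "A"] <- 2
  w["G", "U"] <- w["U", "G"] <- 1
  w
}

.encode_rna <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(b, .PAIR_ALPHABET)
  if (anyNA(code)) {
    bad <- unique(b[is.na(code)])
    stop("sequence contains characters outside {A,C,G,U,T,N}: ",
         paste(bad, collapse = ", "))
  }
  list(seq = paste(b, collapse = ""), code = code)
}

#' Fold a sequence into its maximum-weight hairpin structure
#'
#' Computes the maximum-weight non-crossing secondary structure of an RNA (or
#' DNA, T is read as U) sequence by dynamic programming.  Allowed pairs are
#' Watson-Crick and G-U wobble with weights GC = 3, AU = 2, GU = 1; at least
#' \code{min_loop} unpaired bases must separate the two partners of a pair.
#' The traceback is deterministic: on ties a pairing is preferred over leaving
#' the 3' base unpaired, and among equal-scoring partners the one closest to
#' the 3' base is chosen.
#'
#' Besides the dot-bracket string the fold reports hairpin-oriented features:
#' the number of paired bases, the total weighted score, the longest run of
#' consecutively stacked pairs (\code{longest_stem}), the number of terminal
#' loops, and the size and closing pair of the main hairpin loop (the terminal
#' loop enclosed by the largest number of pairs).
#'
#' @param seq character(1), sequence over A,C,G,U,T,N; N is unpairable.
#' @param min_loop integer, minimum number of unpaired bases in a terminal
#'   loop (default 3).
#' @return An object of class \code{hairpin_fold}: a list with elements
#'   \code{sequence}, \code{structure} (dot-bracket), \code{pairs} (integer
#'   vector, partner position or 0), \code{paired_bases}, \code{score},
#'   \code{longest_stem}, \code{loop_size}, \code{n_loops},
#'   \code{is_hairpin} (exactly one terminal loop), and \code{main_loop}
#'   (closing pair of the main hairpin loop, or \code{NA}).
#' @examples
#' f <- fold_hairpin("GGGAAAACCC")
#' f$structure   # "(((....)))"
#' f$score       # 9
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  min_loop <- as.integer(min_loop)
  enc <- .encode_rna(seq)
  code <- enc$code
  n <- length(code)
  wtab <- .pair_weight_table()
  wlin <- as.numeric(wtab)                     # 25-long, column-major

  S <- matrix(0, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- S[i, j - 1L]
        ks <- i:(j - min_loop - 1L)
        wv <- wlin[code[ks] + 5L * (code[j] - 1L)]
        ok <- wv > 0
        if (any(ok)) {
          kk <- ks[ok]
          left <- numeric(length(kk))
          gt <- kk > i
          if (any(gt)) left[gt] <- S[i + n * (kk[gt] - 2L)]   # S[i, k-1]
          inner <- S[(kk + 1L) + n * (j - 2L)]                # S[k+1, j-1]
          tot <- left + inner + wv[ok]
          m <- max(tot)
          if (m > best) best <- m
        }
        S[i, j] <- best
      }
    }
  }

  # Deterministic traceback (scores are integer-valued, equality is exact).
  pairs <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i <= min_loop) next
    target <- S[i, j]
    if (target == 0) next
    ks <- i:(j - min_loop - 1L)
    wv <- wlin[code[ks] + 5L * (code[j] - 1L)]
    ok <- wv > 0
    paired <- FALSE
    if (any(ok)) {
      kk <- ks[ok]
      left <- numeric(length(kk))
      gt <- kk > i
      if (any(gt)) left[gt] <- S[i + n * (kk[gt] - 2L)]
      inner <- S[(kk + 1L) + n * (j - 2L)]
      tot <- left + inner + wv[ok]
      hit <- which(tot == target)
      if (length(hit)) {
        k <- kk[max(hit)]                     # partner closest to j
        pairs[k] <- j; pairs[j] <- k
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        paired <- TRUE
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }

  .fold_features(enc$seq, pairs, wtab, n)
}

.fold_features <- function(seq, pairs, wtab, n) {
  dots <- rep(".", n)
  open_i <- which(pairs > seq_len(n))
  dots[open_i] <- "("
  dots[pairs[open_i]] <- ")"
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  score <- if (length(open_i)) sum(wtab[cbind(b[open_i], b[pairs[open_i]])]) else 0

  # terminal loops: pairs with no paired base strictly inside
  is_loop <- vapply(open_i, function(i) {
    j <- pairs[i]
    all(pairs[(i + 1L):(j - 1L)] == 0L)
  }, logical(1))
  loop_i <- open_i[is_loop]
  n_loops <- length(loop_i)

  main_loop <- c(NA_integer_, NA_integer_)
  loop_size <- NA_integer_
  if (n_loops > 0L) {
    # main hairpin = terminal loop enclosed by the most pairs
    enclosing <- vapply(loop_i, function(li) {
      lj <- pairs[li]
      sum(open_i <= li & pairs[open_i] >= lj)
    }, integer(1))
    pick <- loop_i[which.max(enclosing)]
    main_loop <- c(pick, pairs[pick])
    loop_size <- pairs[pick] - pick - 1L
  }

  # longest run of consecutively stacked pairs
  longest_stem <- 0L
  if (length(open_i)) {
    oi <- sort(open_i)
    run <- 1L
    longest_stem <- 1L
    if (length(oi) > 1L) {
      for (t in 2L:length(oi)) {
        if (oi[t] == oi[t - 1L] + 1L && pairs[oi[t]] == pairs[oi[t - 1L]] - 1L) {
          run <- run + 1L
        } else {
          run <- 1L
        }
        if (run > longest_stem) longest_stem <- run
      }
    }
  }

  structure(list(
    sequence = seq,
    structure = paste(dots, collapse = ""),
    pairs = pairs,
    paired_bases = length(open_i),
    score = as.numeric(score),
    longest_stem = longest_stem,
    loop_size = loop_size,
    n_loops = n_loops,
    is_hairpin = n_loops == 1L,
    main_loop = main_loop
  ), class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("score %.0f | %d pairs | stem %d | loop %s | %d terminal loop(s)\n",
              x$score, x$paired_bases, x$longest_stem,
              ifelse(is.na(x$loop_size), "NA", x$loop_size), x$n_loops))
  invisible(x)
}
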