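# Expression pattern classification across three cell types.
#
# Given an RPM matrix over (early EPC, late EPC, EC), miRNAs are called
# expressed at a strict RPM threshold, partitioned into the seven regions of
# the 3-set Venn, and classified into monotonic / plateau / cell-type-
# specific fold-change classes.  Fold changes are computed on pseudocounted
# RPM so that zeros are defined.

#' The eight mutually exclusive expression pattern classes
#' @format character vector of class labels.
#' @export
PATTERN_CLASSES <- c("specific_early", "specific_late", "specific_EC",
                     "monotonic_up_to_EC", "monotonic_down_to_EC",
                     "late_and_EC_high", "not_expressed",
                     "expressed_unclassified")

#' Pattern classification configuration
#'
#' @param expr_threshold RPM above which a miRNA is called expressed
#'   (strict \code{>}; default 100).
#' @param fc fold-change threshold (default 1.5, must be > 1).
#' @param cell_order character(3): sample labels in developmental order
#'   (early progenitor, late progenitor, mature endothelial cell).
#' @param pseudocount RPM added before ratio computation (default 1).
#' @return list of class \code{pattern_config}.
#' @export
pattern_config <- function(expr_threshold = 100, fc = 1.5,
                           cell_order = c("early_EPC", "late_EPC", "EC"),
                           pseudocount = 1) {
  stopifnot(fc > 1, expr_threshold >= 0, length(cell_order) == 3L,
            !anyDuplicated(cell_order), pseudocount >= 0)
  structure(list(expr_threshold = expr_threshold, fc = fc,
                 cell_order = as.character(cell_order),
                 pseudocount = pseudocount),
            class = "pattern_config")
}

#' Call expressed miRNAs
#'
#' @param mat RPM matrix (miRNA x sample), non-negative.
#' @param config a \code{\link{pattern_config}}.
#' @return logical matrix of the same shape; TRUE iff RPM strictly exceeds
#'   the threshold.
#' @export
call_expressed <- function(mat, config = pattern_config()) {
  stopifnot(all(mat >= 0))
  mat > config$expr_threshold
}

#' Classify expression patterns
#'
#' Each miRNA receives exactly one class, evaluated in this order on its
#' (early, late, EC) triple: expressed in exactly one cell type ->
#' the matching \code{specific_*} class; else monotonic up
#' (EC >= fc*late and late >= fc*early on pseudocounted RPM) or monotonic
#' down (the mirror); else \code{late_and_EC_high} (late and EC within fc of
#' each other, both >= fc * early); else \code{not_expressed} when no cell
#' type passes the expression threshold; else
#' \code{expressed_unclassified}.
#'
#' @param mat RPM matrix whose columns include \code{config$cell_order}.
#' @param config a \code{\link{pattern_config}}.
#' @return data.frame with \code{mirna_name}, \code{class}, the RPM triple
#'   and the two step fold changes (late/early and EC/late, pseudocounted).
#' @export
classify_patterns <- function(mat, config = pattern_config()) {
  stopifnot(all(config$cell_order %in% colnames(mat)))
  m <- mat[, config$cell_order, drop = FALSE]
  e <- m[, 1L]; l <- m[, 2L]; c3 <- m[, 3L]
  ps <- config$pseudocount
  fc <- config$fc
  ep <- e + ps; lp <- l + ps; cp <- c3 + ps
  expr <- m > config$expr_threshold
  nexp <- rowSums(expr)

  cls <- rep("expressed_unclassified", nrow(m))
  up <- cp >= fc * lp & lp >= fc * ep
  dn <- ep >= fc * lp & lp >= fc * cp
  plateau <- pmax(lp, cp) / pmin(lp, cp) < fc & pmin(lp, cp) >= fc * ep
  cls[plateau] <- "late_and_EC_high"
  cls[dn] <- "monotonic_down_to_EC"
  cls[up] <- "monotonic_up_to_EC"
  cls[!up & !dn & !plateau & nexp == 0L] <- "not_expressed"
  cls[nexp == 1L & expr[, 1L]] <- "specific_early"
  cls[nexp == 1L & expr[, 2L]] <- "specific_late"
  cls[nexp == 1L & expr[, 3L]] <- "specific_EC"

  data.frame(mirna_name = rownames(m), class = cls,
             early = e, late = l, ec = c3,
             fc_late_early = lp / ep, fc_ec_late = cp / lp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Seven-region Venn partition of an expression call matrix
#'
#' @param expressed logical matrix with exactly three columns (cell types).
#' @return list with \code{counts} (named integer vector over the 7 regions,
#'   names like "early_EPC", "early_EPC&late_EPC", ...) and \code{members}
#'   (list of row-name vectors per region).  Region counts sum to the number
#'   of rows expressed in at least one cell type.
#' @export
venn_partition <- function(expressed) {
  stopifnot(ncol(expressed) == 3L)
  cn <- colnames(expressed)
  if (is.null(cn)) cn <- paste0("set", 1:3)
  combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  region_name <- vapply(combos, function(i) paste(cn[i], collapse = "&"),
                        character(1))
  rn <- rownames(expressed)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(expressed)))
  members <- lapply(combos, function(i) {
    inside <- rowSums(expressed[, i, drop = FALSE]) == length(i) &
      rowSums(expressed[, -i, drop = FALSE]) == 0L
    rn[inside]
  })
  names(members) <- region_name
  counts <- vapply(members, length, integer(1))
  list(counts = counts, members = members)
}
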