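# Median-of-ratios size factors and log2 fold-change summaries.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference rows i of
#' `k_ij / geomean_i`, where `geomean_i` is the geometric mean of row i
#' across samples.  Rows containing any zero are excluded from estimation
#' (their log-space geometric mean is undefined), the standard
#' median-of-ratios practice.
#'
#' @param counts junction-count matrix (circRNA x sample), at least one row
#'   with all-positive counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_fmt(paste("no row with all-positive counts: size factors undefined;",
                   "apply the expression filter or supply deeper data"))
  ref <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, stats::median)
  if (any(!is.finite(sf) | sf <= 0))
    stop_fmt("degenerate size factor(s): %s",
             paste(colnames(counts)[!is.finite(sf) | sf <= 0], collapse = ", "))
  sf
}

#' Normalize counts by size factors
#'
#' Divides every column by its size factor.  `normalize_counts(x, sf) * sf`
#' (column-wise) recovers `x` exactly.
#'
#' @param counts junction-count matrix.
#' @param sf named size-factor vector covering every column (see
#'   [size_factors()]).
#' @return real-valued normalized matrix.
#' @export
normalize_counts <- function(counts, sf) {
  validate_count_matrix(counts)
  miss <- setdiff(colnames(counts), names(sf))
  if (length(miss))
    stop_fmt("missing size factor(s) for sample(s): %s", paste(miss, collapse = ", "))
  sf <- sf[colnames(counts)]
  if (any(!is.finite(sf) | sf <= 0)) stop_fmt("size factors must be positive and finite")
  out <- sweep(counts, 2, sf, "/")
  attr(out, "row_meta") <- attr(counts, "row_meta")
  out
}

#' log2 transform used by the downstream screens
#'
#' @param norm normalized matrix.
#' @param pseudocount added before taking log2 (default 1).
#' @return `log2(norm + pseudocount)`.
#' @export
log2_norm <- function(norm, pseudocount = 1) {
  out <- log2(norm + pseudocount)
  attr(out, "row_meta") <- attr(norm, "row_meta")
  out
}

.factor_groups <- function(samples, factor = c("age", "sex")) {
  factor <- match.arg(factor)
  samples <- as_sample_table(samples)
  if (factor == "age") {
    levels <- c("10", "20")
    values <- as.character(samples$age_years)
  } else {
    levels <- c("F", "M")
    values <- samples$sex
  }
  g1 <- samples$sample_id[values == levels[1L]]
  g2 <- samples$sample_id[values == levels[2L]]
  if (!length(g1) || !length(g2))
    stop_fmt("factor '%s' needs both levels present (found only %s)", factor,
             paste(unique(values), collapse = ", "))
  list(levels = levels, group1 = g1, group2 = g2)
}

#' Per-circRNA log2 fold change between two design groups
#'
#' Fold change is `log2((mean_group2 + pseudocount) / (mean_group1 +
#' pseudocount))` on normalized counts, with group2 = 20 y (age) or M (sex),
#' so positive values mean higher expression in the older / male samples.
#' The t statistic and p-value come from a Welch test on
#' `log2(norm + pseudocount)`.
#'
#' @param norm normalized count matrix.
#' @param samples sample table.
#' @param factor `"age"` (10 y vs 20 y) or `"sex"` (F vs M).
#' @param pseudocount stabilizing offset (default 1).
#' @return data.frame `circ_id`, `log2fc`, `t_stat`, `p_value`, `direction`
#'   (factor levels group1/group2/none), with a `direction_counts` attribute
#'   (named vector over all rows: volcano-style counts per direction).
#' @export
log2_fold_change <- function(norm, samples, factor = c("age", "sex"),
                             pseudocount = 1) {
  factor <- match.arg(factor)
  grp <- .factor_groups(samples, factor)
  miss <- setdiff(colnames(norm), as_sample_table(samples)$sample_id)
  if (length(miss))
    stop_fmt("samples missing from table: %s", paste(miss, collapse = ", "))
  i1 <- colnames(norm) %in% grp$group1
  i2 <- colnames(norm) %in% grp$group2
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  lg <- log2_norm(norm, pseudocount)
  tw <- row_welch(lg, which(i1), which(i2))
  direction <- ifelse(lfc > 0, grp$levels[2L], ifelse(lfc < 0, grp$levels[1L], "none"))
  out <- data.frame(circ_id = rownames(norm), log2fc = lfc, t_stat = tw$t,
                    p_value = tw$p,
                    direction = factor(direction, levels = c(grp$levels, "none")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "direction_counts") <- table(out$direction)
  out
}
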