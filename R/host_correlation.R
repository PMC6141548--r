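# Pearson correlation between circRNA and host-mRNA expression, and the
# positive/negative/uncorrelated classification.

#' Correlate circRNAs with their host mRNA expression
#'
#' For every (circRNA, host gene) pair of `host_map` present in both
#' matrices, computes the Pearson correlation coefficient across the shared
#' ordered samples plus the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Pairs with a zero-variance profile get `pcc = NA` (excluded from
#' classification); map entries whose circRNA or gene is absent are skipped
#' with a logged count.
#'
#' @param circ_mat circRNA expression matrix (e.g. `log2(norm + 1)`),
#'   circRNA x sample.
#' @param mrna_mat host-mRNA expression matrix, gene x sample; must carry
#'   the same ordered sample columns (correlation is unit-free, so any
#'   expression units work).
#' @param host_map data.frame with columns `circ_id`, `gene_id`; one pair
#'   per row (circRNA isoforms of one gene give several pairs).
#' @return data.frame `circ_id`, `host_gene`, `pcc`, `p_value`, `n`.
#' @export
pair_correlations <- function(circ_mat, mrna_mat, host_map) {
  if (!identical(colnames(circ_mat), colnames(mrna_mat)))
    stop_fmt("circRNA and mRNA matrices must share the same ordered samples")
  need <- c("circ_id", "gene_id")
  if (!all(need %in% names(host_map)))
    stop_fmt("host_map needs columns circ_id, gene_id")
  n <- ncol(circ_mat)
  if (n < 3L) stop_fmt("need >= 3 samples for correlation")
  present <- host_map$circ_id %in% rownames(circ_mat) &
    host_map$gene_id %in% rownames(mrna_mat)
  skipped <- sum(!present)
  if (skipped) .msg("pair_correlations: skipped %d pair(s) without both profiles", skipped)
  hm <- host_map[present, , drop = FALSE]
  x <- circ_mat[hm$circ_id, , drop = FALSE]
  y <- mrna_mat[hm$gene_id, , drop = FALSE]
  vx <- row_vars(x); vy <- row_vars(y)
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / ((n - 1) * sqrt(vx * vy))
  r[vx == 0 | vy == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  out <- data.frame(circ_id = hm$circ_id, host_gene = hm$gene_id,
                    pcc = unname(r), p_value = unname(p), n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify circRNA/host-mRNA correlation pairs
#'
#' A pair is `positive` when `pcc >= min_abs_pcc` and `p <= max_p`,
#' `negative` when `pcc <= -min_abs_pcc` and `p <= max_p`, else
#' `uncorrelated`.  Both thresholds are inclusive ("no less than 0.3",
#' "no more than 0.1").  Pairs with undefined correlation are left `NA` and
#' excluded from the summary fractions.
#'
#' @param pairs data.frame from [pair_correlations()].
#' @param min_abs_pcc absolute-correlation threshold in (0, 1) (default 0.3).
#' @param max_p p-value threshold (default 0.1).
#' @return the input with a `class` factor column
#'   (positive/negative/uncorrelated) and a `summary` attribute: `n_total`,
#'   `n_classifiable`, `n_positive`, `n_negative`, `n_uncorrelated`,
#'   `fraction_correlated` (over classifiable pairs), `n_host_genes` and
#'   `fraction_correlated_genes` (correlated pairs over distinct host
#'   genes — the alternative denominator).
#' @export
classify_pairs <- function(pairs, min_abs_pcc = 0.3, max_p = 0.1) {
  if (!is.numeric(min_abs_pcc) || min_abs_pcc <= 0 || min_abs_pcc >= 1)
    stop_fmt("min_abs_pcc must lie in (0, 1)")
  if (!is.numeric(max_p) || max_p < 0 || max_p > 1)
    stop_fmt("max_p must lie in [0, 1]")
  cls <- rep(NA_character_, nrow(pairs))
  ok <- !is.na(pairs$pcc)
  cls[ok] <- "uncorrelated"
  sig <- ok & pairs$p_value <= max_p
  cls[sig & pairs$pcc >= min_abs_pcc] <- "positive"
  cls[sig & pairs$pcc <= -min_abs_pcc] <- "negative"
  out <- pairs
  out$class <- factor(cls, levels = c("positive", "negative", "uncorrelated"))
  n_pos <- sum(cls == "positive", na.rm = TRUE)
  n_neg <- sum(cls == "negative", na.rm = TRUE)
  n_cls <- sum(ok)
  attr(out, "summary") <- list(
    n_total = nrow(pairs), n_classifiable = n_cls,
    n_positive = n_pos, n_negative = n_neg,
    n_uncorrelated = n_cls - n_pos - n_neg,
    fraction_correlated = if (n_cls) (n_pos + n_neg) / n_cls else NA_real_,
    n_host_genes = length(unique(pairs$host_gene)),
    fraction_correlated_genes = if (length(unique(pairs$host_gene)))
      (n_pos + n_neg) / length(unique(pairs$host_gene)) else NA_real_)
  out
}
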