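# Spatial one-vs-rest, sex-biased and age-biased circRNA calling by Welch
# t-tests and a label-permutation null.

# Vectorized Welch test over matrix rows.  Degenerate rule: when both group
# variances are zero, equal means give (t = 0, p = 1) and unequal means give
# (t = +/-Inf, p = 0) — deterministic limits of the statistic.
row_welch <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop_fmt("each group needs n >= 2 (got %d and %d)", n1, n2)
  x1 <- mat[, idx1, drop = FALSE]; x2 <- mat[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0
  }
  list(t = t, p = p, mean1 = m1, mean2 = m2)
}

#' Two-group t-test with deterministic degenerate handling
#'
#' Welch's unequal-variance two-sided test for unpaired groups, or the
#' paired t-test on matched differences.  When all variance vanishes the
#' result is the deterministic limit: equal means give `(t = 0, p = 1)`,
#' unequal constant groups give `(t = +/-Inf, p = 0)`.
#'
#' @param x,y numeric vectors (each `n >= 2`; equal matched lengths when
#'   `paired`).
#' @param paired pair observations by position.
#' @return list with elements `t` and `p`.
#' @export
two_group_t_test <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop_fmt("each group needs n >= 2 (got %d and %d)", length(x), length(y))
  if (paired) {
    if (length(x) != length(y))
      stop_fmt("paired test needs equal-length matched vectors")
    d <- x - y
    n <- length(d)
    v <- stats::var(d)
    if (v == 0) {
      if (mean(d) == 0) return(list(t = 0, p = 1))
      return(list(t = sign(mean(d)) * Inf, p = 0))
    }
    t <- mean(d) / sqrt(v / n)
    return(list(t = t, p = 2 * stats::pt(-abs(t), n - 1)))
  }
  r <- row_welch(rbind(c(x, y)), seq_along(x), length(x) + seq_along(y))
  list(t = unname(r$t), p = unname(r$p))
}

#' Spatially specific circRNAs by one-vs-rest screening
#'
#' Per region and circRNA, a Welch test compares the region's samples with
#' all remaining samples on `log2(norm + 1)`.  A circRNA is called for a
#' region when `p < alpha` and the region mean is strictly greater than the
#' rest mean; mode `"vs_each"` additionally requires the region mean to
#' exceed each other region's mean ("consistently higher").  A circRNA is
#' called for at most one region — the smallest p, ties broken
#' lexicographically by region name.
#'
#' @param norm normalized count matrix.
#' @param samples sample table; every region present must have >= 2 samples.
#' @param alpha raw p-value threshold (default 0.01).
#' @param mode `"one_vs_rest"` or `"vs_each"`.
#' @param log2_transform test on `log2(norm + 1)` (default) or on the given
#'   scale.
#' @return data.frame with one row per (circRNA, region): `circ_id`,
#'   `contrast` (e.g. `"CB-vs-rest"`), `region`, `t_stat`, `p_t`, `q_value`
#'   (Benjamini-Hochberg within region, informational), `mean_region`,
#'   `mean_rest`, `enriched_group`, `called`.
#' @export
spatial_specific <- function(norm, samples, alpha = 0.01,
                             mode = c("one_vs_rest", "vs_each"),
                             log2_transform = TRUE) {
  mode <- match.arg(mode)
  samples <- as_sample_table(samples)
  region <- samples$region[match(colnames(norm), samples$sample_id)]
  if (anyNA(region)) stop_fmt("matrix samples missing from sample table")
  tab <- table(region)
  if (any(tab < 2L))
    stop_fmt("every region needs >= 2 samples; offending: %s",
             paste(names(tab)[tab < 2L], collapse = ", "))
  if (length(tab) < 2L) stop_fmt("need at least 2 regions")
  mat <- if (log2_transform) log2_norm(norm) else norm
  regions <- sort_c(unique(region))
  region_means <- vapply(regions, function(r)
    rowMeans(mat[, region == r, drop = FALSE]), numeric(nrow(mat)))
  if (nrow(mat) == 1L) region_means <- matrix(region_means, nrow = 1L,
                                              dimnames = list(rownames(mat), regions))
  res <- lapply(regions, function(r) {
    idx1 <- which(region == r); idx2 <- which(region != r)
    w <- row_welch(mat, idx1, idx2)
    higher <- w$mean1 > w$mean2
    if (mode == "vs_each") {
      others <- region_means[, colnames(region_means) != r, drop = FALSE]
      higher <- higher & (region_means[, r] > apply(others, 1, max))
    }
    data.frame(circ_id = rownames(mat),
               contrast = paste0(r, "-vs-rest"), region = r,
               t_stat = w$t, p_t = w$p,
               q_value = stats::p.adjust(w$p, "BH"),
               mean_region = w$mean1, mean_rest = w$mean2,
               called = w$p < alpha & higher,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # at most one region per circRNA: smallest p among called, ties lexicographic
  called <- out[out$called, , drop = FALSE]
  if (nrow(called)) {
    ord <- order(called$circ_id, called$p_t, called$region, method = "radix")
    winner <- called[ord, ][!duplicated(called$circ_id[ord]), ]
    win_key <- paste(winner$circ_id, winner$region)
    out$called <- out$called & paste(out$circ_id, out$region) %in% win_key
  }
  out$enriched_group <- ifelse(out$called, out$region, NA_character_)
  rownames(out) <- NULL
  out
}

#' Sex- or age-biased circRNAs
#'
#' Per-circRNA Welch test between the two levels of the factor (F vs M, or
#' 10 y vs 20 y) on `log2(norm + 1)`; called when `p < alpha`, with the
#' enriched group being the higher-mean level.
#'
#' @inheritParams spatial_specific
#' @param factor `"sex"` or `"age"`.
#' @param alpha raw p-value threshold (default 0.05).
#' @return data.frame `circ_id`, `contrast`, `t_stat`, `p_t`, `q_value`
#'   (BH, informational), group means, `enriched_group`, `called`.
#' @export
group_biased <- function(norm, samples, factor = c("sex", "age"), alpha = 0.05,
                         log2_transform = TRUE) {
  factor <- match.arg(factor)
  grp <- .factor_groups(samples, factor)
  mat <- if (log2_transform) log2_norm(norm) else norm
  idx1 <- which(colnames(mat) %in% grp$group1)
  idx2 <- which(colnames(mat) %in% grp$group2)
  w <- row_welch(mat, idx1, idx2)
  enriched <- ifelse(w$mean1 > w$mean2, grp$levels[1L],
                     ifelse(w$mean2 > w$mean1, grp$levels[2L], NA_character_))
  out <- data.frame(circ_id = rownames(mat),
                    contrast = paste0(grp$levels[2L], "-vs-", grp$levels[1L]),
                    t_stat = w$t, p_t = w$p,
                    q_value = stats::p.adjust(w$p, "BH"),
                    mean_group1 = w$mean1, mean_group2 = w$mean2,
                    enriched_group = enriched,
                    called = w$p < alpha,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_group1"] <- paste0("mean_", grp$levels[1L])
  names(out)[names(out) == "mean_group2"] <- paste0("mean_", grp$levels[2L])
  rownames(out) <- NULL
  out
}

#' Label-permutation test for group-biased expression
#'
#' The statistic is the per-circRNA difference of group means (level2 minus
#' level1) on `log2(norm + 1)`.  Group labels are permuted jointly across
#' all circRNAs; the two-sided p-value uses the add-one estimator
#' `p = (1 + #\{|stat_perm| >= |stat_obs|\}) / (1 + n_perm)`, so
#' `1/(1 + n_perm) <= p <= 1`.  With `exhaustive = TRUE` all distinct label
#' assignments are enumerated and the exact permutation p-value
#' `#\{|stat| >= |stat_obs|\} / n_assignments` (identity included) is
#' returned instead.
#'
#' @inheritParams group_biased
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @param exhaustive enumerate all distinct assignments of the level sizes
#'   (exact test; feasible for small designs).
#' @return data.frame `circ_id`, `mean_diff`, `p_perm`.
#' @export
permutation_test <- function(norm, samples, factor = c("sex", "age"),
                             n_perm = 10000L, seed = NULL, exhaustive = FALSE,
                             log2_transform = TRUE) {
  factor <- match.arg(factor)
  if (!exhaustive && n_perm < 1L) stop_fmt("n_perm must be >= 1")
  grp <- .factor_groups(samples, factor)
  mat <- if (log2_transform) log2_norm(norm) else norm
  is2 <- colnames(mat) %in% grp$group2
  is1 <- colnames(mat) %in% grp$group1
  if (!all(is1 | is2)) stop_fmt("matrix contains samples outside the two groups")
  n <- ncol(mat); n2 <- sum(is2); n1 <- sum(is1)
  weight <- function(memb2) ifelse(memb2, 1 / n2, -1 / n1)
  obs <- as.numeric(mat %*% weight(is2))
  # tie guard: mirrored label splits give exactly -obs mathematically, but a
  # different summation order numerically; count them as >=
  eps <- 1e-12 * (1 + abs(obs))
  count_ge <- numeric(nrow(mat))
  if (exhaustive) {
    combos <- utils::combn(n, n2)
    n_assign <- ncol(combos)
    W <- matrix(-1 / n1, nrow = n, ncol = n_assign)
    W[cbind(as.vector(combos), rep(seq_len(n_assign), each = n2))] <- 1 / n2
    perm <- mat %*% W
    count_ge <- rowSums(abs(perm) >= abs(obs) - eps)
    p <- count_ge / n_assign
  } else {
    count_ge <- with_seed(seed, {
      cnt <- numeric(nrow(mat))
      chunk <- 500L
      done <- 0L
      while (done < n_perm) {
        k <- min(chunk, n_perm - done)
        W <- vapply(seq_len(k), function(i) {
          memb2 <- logical(n); memb2[sample.int(n, n2)] <- TRUE
          weight(memb2)
        }, numeric(n))
        cnt <- cnt + rowSums(abs(mat %*% W) >= abs(obs) - eps)
        done <- done + k
      }
      cnt
    })
    p <- (1 + count_ge) / (1 + n_perm)
  }
  data.frame(circ_id = rownames(mat), mean_diff = obs, p_perm = p,
             stringsAsFactors = FALSE)
}

#' Compare two called sets
#'
#' Overlap summary in the convention "intersection / size of b", as used to
#' report the agreement between t-test and permutation calls.
#'
#' @param a,b character vectors of ids (duplicates ignored).
#' @return list `size_a`, `size_b`, `intersection`, `overlap_ratio`
#'   (`intersection / size_b`; `NA` when `b` is empty).
#' @export
compare_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  list(size_a = length(a), size_b = length(b), intersection = i,
       overlap_ratio = if (length(b)) i / length(b) else NA_real_)
}
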