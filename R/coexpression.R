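# Simplified weighted co-expression network: soft-threshold adjacency,
# topological overlap, average-linkage modules, module eigengenes.

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted network: `a_ij = |cor(row_i, row_j)|^beta` with Pearson
#' correlation across samples.  The cubic soft threshold (`beta = 3`) is the
#' default.  The diagonal is set to zero so that connectivity sums exclude
#' self-edges; `signed = TRUE` uses `((1 + cor)/2)^beta` instead.
#'
#' @param mat expression matrix (features x samples), >= 3 samples, no
#'   zero-variance rows.
#' @param beta positive integer soft-threshold power (default 3).
#' @param signed signed network variant (default unsigned).
#' @return symmetric matrix in \[0, 1\] with zero diagonal and attribute
#'   `soft_power`.
#' @export
adjacency <- function(mat, beta = 3L, signed = FALSE) {
  if (ncol(mat) < 3L) stop_fmt("adjacency needs >= 3 samples")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1)
    stop_fmt("beta must be a positive integer")
  v <- row_vars(mat)
  if (any(v == 0))
    stop_fmt("zero-variance row(s): %s; exclude before building the network",
             paste(utils::head(rownames(mat)[v == 0], 5), collapse = ", "))
  r <- stats::cor(t(mat))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  a <- pmin(a, 1)
  diag(a) <- 0
  attr(a, "soft_power") <- beta
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and connectivity
#' `k_i = sum_u a_iu`; `TOM_ii = 1`.  `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adj adjacency matrix from [adjacency()] (symmetric, zero
#'   diagonal).
#' @return symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop_fmt("adjacency must be square")
  if (max(abs(adj - t(adj))) > 1e-10) stop_fmt("adjacency must be symmetric")
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # diag zero => u = i and u = j terms vanish
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM` with a static cut.
#' Clusters smaller than `min_module_size` are collected in module 0
#' (unassigned); remaining modules are labelled 1, 2, ... by decreasing
#' size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height static tree-cut height on the `1 - TOM` scale (default
#'   0.5).  With the cubic soft threshold, tightly co-expressed blocks
#'   (`|cor|` around 0.9) sit near dissimilarity `1 - |cor|^3` (about
#'   0.2-0.3), sparsely connected features attach to blocks only around
#'   0.8-0.9, and unrelated blocks join near 1 — so 0.5 separates the two
#'   regimes; raise it to admit more loosely co-expressed modules at the
#'   cost of absorbing weakly connected features.
#' @return list of class `module_assignment`: `labels` (named integer
#'   vector, 0 = unassigned), `sizes` (named count table) and the `hclust`
#'   tree.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.5) {
  if (!is.matrix(tom) || nrow(tom) < 2L) stop_fmt("need a TOM over >= 2 features")
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  big <- big[order(-sizes[big], as.integer(big))]
  labels <- integer(length(raw))
  for (i in seq_along(big)) labels[raw == big[i]] <- i
  names(labels) <- rownames(tom)
  structure(list(labels = labels,
                 sizes = table(labels),
                 tree = tree),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  k <- sum(names(x$sizes) != "0")
  cat(sprintf("module_assignment: %d feature(s), %d module(s) (+ module 0 with %d)\n",
              length(x$labels), k,
              if ("0" %in% names(x$sizes)) x$sizes[["0"]] else 0L))
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component across samples
#' of the per-row standardized (z-scored) module submatrix, scaled to unit
#' Euclidean norm and sign-oriented to correlate positively with the
#' module's mean standardized profile.
#'
#' @param mat expression matrix (the one modules were detected on).
#' @param assignment `module_assignment` from [detect_modules()], or a named
#'   integer vector of labels.
#' @param include_unassigned also summarize module 0 (default TRUE).
#' @return list with `eigengenes` (matrix, modules x samples, rows named
#'   `ME<label>`) and `var_explained` (named vector in (0, 1\]).
#' @export
module_eigengene <- function(mat, assignment, include_unassigned = TRUE) {
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels
            else assignment
  labels <- labels[rownames(mat)]
  if (anyNA(labels)) stop_fmt("assignment does not cover every matrix row")
  mods <- sort(unique(labels))
  if (!include_unassigned) mods <- setdiff(mods, 0L)
  if (!length(mods)) stop_fmt("no module to summarize")
  eg <- matrix(NA_real_, nrow = length(mods), ncol = ncol(mat),
               dimnames = list(paste0("ME", mods), colnames(mat)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    sub <- mat[labels == mods[i], , drop = FALSE]
    v <- row_vars(sub)
    if (any(v == 0))
      stop_fmt("module %s contains zero-variance row(s)", mods[i])
    z <- (sub - rowMeans(sub)) / sqrt(v)
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1L]
    if (sum(e * colMeans(z)) < 0) e <- -e
    eg[i, ] <- e
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}
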