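# Hypergeometric upper-tail overlap test and gene-set enrichment over
# user-supplied annotation sets.

#' One-sided upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` successes when `n` items are drawn
#' without replacement from a universe of `N` containing `K` successes:
#' `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Each term is accumulated in log space (log-binomials plus log-sum-exp),
#' so extreme tails (e.g. 1e-38) are computed without underflow.
#'
#' @param N universe size.
#' @param K successes in the universe (`K <= N`).
#' @param n number of draws (`n <= N`).
#' @param k observed successes (`0 <= k <= n`).
#' @return tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop_fmt("N, K, n, k must be single non-negative integers")
  if (k > n || n > N || K > N)
    stop_fmt("bounds violated: need 0 <= k <= n <= N and K <= N")
  if (k == 0L) return(1)
  i <- seq.int(k, min(n, K))
  if (!length(i) || k > min(n, K)) return(0)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(logsumexp(lt)), 1)
}

#' Hypergeometric point masses (log-space check helper)
#'
#' Probability mass `P(X = k)` for every achievable overlap `k`; the masses
#' sum to 1, which exercises the same log-space accumulation as
#' [hypergeom_tail()].
#'
#' @inheritParams hypergeom_tail
#' @return named numeric vector over `k = max(0, n-(N-K)) ... min(n, K)`.
#' @export
hypergeom_pmf <- function(N, K, n) {
  k <- seq.int(max(0L, n - (N - K)), min(n, K))
  lp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  stats::setNames(exp(lp), k)
}

#' Gene-set enrichment by hypergeometric tests
#'
#' For every annotation set: `N = |universe|`, `K = |set` intersected with
#' `universe|`, `n = |query|`, `k = |query` intersected with `set|`; sets
#' with `K = 0` are skipped.  Benjamini-Hochberg q-values are computed
#' across the tested sets.
#'
#' @param query character vector of genes of interest (must be contained in
#'   `universe`).
#' @param universe character vector, the background gene population.
#' @param sets named list of character vectors (set_id -> genes), e.g. from
#'   [read_gene_sets()].
#' @return data.frame sorted by p: `set_id`, `N`, `K`, `n`, `k`, `p_value`,
#'   `q_value`.
#' @export
enrich_gene_sets <- function(query, universe, sets) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query) || !length(universe))
    stop_fmt("query and universe must be non-empty")
  out_of_univ <- setdiff(query, universe)
  if (length(out_of_univ))
    stop_fmt("query gene(s) outside universe: %s",
             paste(utils::head(out_of_univ, 5), collapse = ", "))
  if (!length(sets)) stop_fmt("no annotation sets supplied")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_fmt("sets must be a named list")
  rows <- lapply(names(sets), function(id) {
    set <- intersect(unique(sets[[id]]), universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, set))
    data.frame(set_id = id, N = length(universe), K = K, n = length(query),
               k = k, p_value = hypergeom_tail(length(universe), K, length(query), k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_fmt("no annotation set intersects the universe")
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$set_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column gene-set TSV
#'
#' Plain annotation format `set_id <TAB> gene_id`, one membership per line
#' (header required), returned as a named list for [enrich_gene_sets()].
#'
#' @param path TSV path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_id", "gene_id") %in% names(tab)))
    stop_fmt("gene-set file %s needs columns set_id, gene_id", path)
  split(tab$gene_id, tab$set_id)
}
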