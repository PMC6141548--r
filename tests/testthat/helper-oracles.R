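# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately re-derive results with literal loops / closed forms,
# separate from the package implementations they check.

# literal evaluation of the five filtering rules for one circRNA row
oracle_filter_route <- function(row_counts, region, cfg) {
  n_expressed_samples <- 0L
  for (j in seq_along(row_counts))
    if (row_counts[j] >= cfg$min_expressed_reads)
      n_expressed_samples <- n_expressed_samples + 1L
  expressed_areas <- 0L
  for (a in unique(region)) {
    in_area <- row_counts[region == a]
    n <- sum(in_area >= cfg$min_expressed_reads)
    if (n >= cfg$min_samples_per_area) expressed_areas <- expressed_areas + 1L
  }
  if (expressed_areas >= cfg$min_expressed_areas) return("rule3")
  if (expressed_areas == 1L &&
      n_expressed_samples >= cfg$min_expressed_samples_single_area) return("rule4")
  if (sum(row_counts) >= cfg$min_total_reads) return("rule5")
  "dropped"
}

oracle_filter <- function(counts, region, cfg) {
  vapply(seq_len(nrow(counts)),
         function(i) oracle_filter_route(counts[i, ], region, cfg), "")
}

# literal median-of-ratios
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- counts[keep, , drop = FALSE]
  geo <- apply(ref, 1, function(r) prod(r)^(1 / length(r)))
  apply(ref, 2, function(col) median(col / geo))
}

# triple-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# exact permutation p-values for a two-group design by full enumeration
oracle_exact_perm <- function(mat, memb2) {
  n <- length(memb2); n2 <- sum(memb2); n1 <- n - n2
  obs <- apply(mat, 1, function(x) mean(x[memb2]) - mean(x[!memb2]))
  combos <- combn(n, n2)
  vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    stats <- apply(combos, 2, function(idx) mean(x[idx]) - mean(x[-idx]))
    sum(abs(stats) >= abs(obs[i])) / ncol(combos)
  }, numeric(1))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hypergeom_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  is_success <- seq_len(N) <= K
  hits <- apply(draws, 2, function(d) sum(is_success[d]))
  mean(hits >= k)
}

make_records <- function(chrom, start, end, strand, reads = 5L,
                         sample_id = "s1", host = NA_character_) {
  data.frame(circ_id = format_circ_id(chrom, start, end, strand),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, junction_reads = as.integer(reads),
             host_gene = host, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

make_design <- function() {
  grid <- expand.grid(region = BRAIN_REGIONS, sex = SEXES, age = AGES_YEARS,
                      stringsAsFactors = FALSE)
  as_sample_table(data.frame(
    sample_id = paste(grid$region, grid$sex, grid$age, sep = "_"),
    region = grid$region, sex = grid$sex, age_years = grid$age))
}

random_count_matrix <- function(n_row, samples, max_count = 40L) {
  m <- matrix(sample(0:max_count, n_row * nrow(samples), replace = TRUE),
              nrow = n_row,
              dimnames = list(sprintf("chr1:%d|%d:+", seq_len(n_row) * 10L,
                                      seq_len(n_row) * 10L + 100L),
                              samples$sample_id))
  storage.mode(m) <- "integer"
  m
}

# rows with expected pairwise correlation rho_w inside each planted module
planted_module_matrix <- function(sizes, n_samples, rho_w = 0.9, n_noise = 0L) {
  rows <- list(); labels <- integer(0)
  for (m in seq_along(sizes)) {
    base <- rnorm(n_samples)
    for (i in seq_len(sizes[m]))
      rows[[length(rows) + 1L]] <- sqrt(rho_w) * base + sqrt(1 - rho_w) * rnorm(n_samples)
    labels <- c(labels, rep(m, sizes[m]))
  }
  for (i in seq_len(n_noise)) {
    rows[[length(rows) + 1L]] <- rnorm(n_samples)
    labels <- c(labels, 0L)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- sprintf("row%04d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", seq_len(n_samples))
  list(mat = mat, labels = labels)
}
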