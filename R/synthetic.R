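# Negative-binomial junction-count simulator with the 8-region x 2-sex x
# 2-age design and full ground truth (spiked effects, planted host-mRNA
# correlations).

#' Simulation configuration
#'
#' Defaults emulate the study design and the statistical structure of a
#' filtered brain circRNA set: 32 libraries (8 regions x 2 sexes x 2 ages,
#' one library per design cell), log-normal baseline abundances with
#' `meanlog = 3.5, sdlog = 1` (about 14% of circRNAs above 100 junction
#' reads), negative-binomial dispersion 0.1, log-normal library size factors
#' (sdlog 0.15), 300 fold-4 spiked circRNAs (100 CB-enriched, 50 male- and
#' 50 female-biased, 50 20-y and 50 10-y biased) and 300 host-mRNA pairs at
#' each of rho = +0.8, -0.8, 0.
#'
#' @param n_circ number of simulated circRNAs.
#' @param regions,sexes,ages design levels (validated against the design
#'   vocabularies).
#' @param replicates libraries per design cell.
#' @param baseline_log_mean,baseline_log_sd log-normal abundance parameters
#'   (natural log of expected junction reads).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param library_size_factors optional per-sample positive multipliers
#'   (default: drawn log-normal, sdlog 0.15).
#' @param spikes list of `list(factor, level, n, fold)` entries; factors
#'   `region`, `sex` or `age`; spiked row sets are disjoint.
#' @param host_rho_sets list of `list(n_pairs, rho)` entries for
#'   [simulate_host_mrna()].
#' @param seed default RNG seed for the simulation operations.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_circ = 2000L,
                       regions = BRAIN_REGIONS, sexes = SEXES, ages = AGES_YEARS,
                       replicates = 1L,
                       baseline_log_mean = 3.5, baseline_log_sd = 1.0,
                       nb_dispersion = 0.1,
                       library_size_factors = NULL,
                       spikes = list(
                         list(factor = "region", level = "CB", n = 100L, fold = 4),
                         list(factor = "sex", level = "M", n = 50L, fold = 4),
                         list(factor = "sex", level = "F", n = 50L, fold = 4),
                         list(factor = "age", level = "20", n = 50L, fold = 4),
                         list(factor = "age", level = "10", n = 50L, fold = 4)),
                       host_rho_sets = list(
                         list(n_pairs = 300L, rho = 0.8),
                         list(n_pairs = 300L, rho = -0.8),
                         list(n_pairs = 300L, rho = 0)),
                       seed = 20181018L) {
  if (!length(regions) || !length(sexes) || !length(ages) || replicates < 1L)
    stop_fmt("invalid design: empty cell")
  if (!all(regions %in% BRAIN_REGIONS) || !all(sexes %in% SEXES) ||
      !all(ages %in% AGES_YEARS))
    stop_fmt("design levels must come from the study vocabularies")
  if (nb_dispersion <= 0) stop_fmt("nb_dispersion must be positive")
  for (s in spikes) {
    if (!all(c("factor", "level", "n", "fold") %in% names(s)))
      stop_fmt("each spike needs factor, level, n, fold")
    if (s$fold <= 0) stop_fmt("spike folds must be positive")
    ok <- switch(s$factor,
                 region = s$level %in% regions,
                 sex = s$level %in% sexes,
                 age = as.character(s$level) %in% as.character(ages),
                 FALSE)
    if (!ok) stop_fmt("spike level '%s' not in design factor '%s'", s$level, s$factor)
  }
  if (sum(vapply(spikes, `[[`, 0, "n")) > n_circ)
    stop_fmt("more spiked rows than circRNAs")
  for (h in host_rho_sets)
    if (abs(h$rho) > 1) stop_fmt("|rho| must be <= 1")
  structure(list(n_circ = as.integer(n_circ), regions = regions, sexes = sexes,
                 ages = as.integer(ages), replicates = as.integer(replicates),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 nb_dispersion = nb_dispersion,
                 library_size_factors = library_size_factors,
                 spikes = spikes, host_rho_sets = host_rho_sets,
                 seed = seed),
            class = "sim_config")
}

.sim_sample_table <- function(cfg) {
  grid <- expand.grid(region = cfg$regions, sex = cfg$sexes, age = cfg$ages,
                      rep = seq_len(cfg$replicates), stringsAsFactors = FALSE)
  id <- paste(grid$region, grid$sex, grid$age, sep = "_")
  if (cfg$replicates > 1L) id <- paste0(id, "_r", grid$rep)
  as_sample_table(data.frame(sample_id = id, region = grid$region,
                             sex = grid$sex, age_years = grid$age,
                             stringsAsFactors = FALSE))
}

#' Simulate a junction-count experiment with ground truth
#'
#' Counts are drawn as `NB(mean = lambda_i * s_j * f_ij, dispersion)`:
#' log-normal baseline `lambda_i`, library size factor `s_j`, and planted
#' fold `f_ij` applied to the samples of a spiked row's target level.
#' Fully reproducible from the seed; the caller's RNG state is untouched.
#'
#' @param cfg [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return list: `counts` (integer matrix with `row_meta` attribute),
#'   `samples` (sample table), `truth` (data.frame circ_id, spike_label,
#'   fold, host_rho — host_rho filled by [simulate_host_mrna()]).
#' @export
simulate_counts <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- .sim_sample_table(cfg)
  n_samp <- nrow(samples)
  with_seed(seed, {
    lambda <- stats::rlnorm(cfg$n_circ, cfg$baseline_log_mean, cfg$baseline_log_sd)
    sf <- cfg$library_size_factors
    if (is.null(sf)) sf <- stats::rlnorm(n_samp, 0, 0.15)
    if (length(sf) != n_samp || any(sf <= 0))
      stop_fmt("library_size_factors must be %d positive values", n_samp)

    # coordinates: unique starts guarantee unique ids
    chrom <- sample(c(paste0("chr", 1:20), "chrX"), cfg$n_circ, replace = TRUE)
    start <- sort(sample.int(5e7, cfg$n_circ)) * 2L
    width <- sample(200:50000, cfg$n_circ, replace = TRUE)
    strand <- sample(c("+", "-"), cfg$n_circ, replace = TRUE)
    circ_id <- format_circ_id(chrom, start, start + width, strand)
    host <- ifelse(stats::runif(cfg$n_circ) < 0.85,
                   sprintf("G%05d", seq_len(cfg$n_circ)), NA_character_)

    # disjoint spiked row sets
    pool <- sample.int(cfg$n_circ)
    fold_mat <- matrix(1, cfg$n_circ, n_samp)
    spike_label <- rep(NA_character_, cfg$n_circ)
    true_fold <- rep(1, cfg$n_circ)
    taken <- 0L
    for (s in cfg$spikes) {
      rows <- pool[taken + seq_len(s$n)]
      taken <- taken + s$n
      cols <- switch(s$factor,
                     region = samples$region == s$level,
                     sex = samples$sex == s$level,
                     age = as.character(samples$age_years) == as.character(s$level))
      fold_mat[rows, cols] <- s$fold
      spike_label[rows] <- paste0(s$factor, ":", s$level)
      true_fold[rows] <- s$fold
    }

    mu <- (lambda * fold_mat) * rep(sf, each = cfg$n_circ)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                     nrow = cfg$n_circ, ncol = n_samp,
                     dimnames = list(circ_id, samples$sample_id))
    storage.mode(counts) <- "integer"
    ord <- order(circ_id, method = "radix")
    counts <- counts[ord, , drop = FALSE]
    meta <- data.frame(circ_id = circ_id, chrom = chrom, start = start,
                       end = start + width, strand = strand, host_gene = host,
                       stringsAsFactors = FALSE)[ord, ]
    rownames(meta) <- NULL
    attr(counts, "row_meta") <- meta
    truth <- data.frame(circ_id = circ_id, spike_label = spike_label,
                        fold = true_fold, host_rho = NA_real_,
                        stringsAsFactors = FALSE)[ord, ]
    rownames(truth) <- NULL
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate host-mRNA expression with controlled circRNA correlation
#'
#' For each `host_rho_sets` entry, `n_pairs` unspiked circRNAs are chosen
#' and a host expression profile is built on the log2 scale as
#' `10 + 1.5 * h` with `h = rho * z + sqrt(1 - rho^2) * u`, where `z` is the
#' standardized circRNA profile and `u` a standardized random profile made
#' orthogonal to `z` — so the sample Pearson correlation between the pair
#' equals the planted `rho` exactly (rho = 1 gives PCC = 1).  Gene names
#' reuse the circRNA's simulated host gene.
#'
#' @param circ_mat circRNA expression matrix on the scale correlations are
#'   later computed on (the pipeline passes `log2(normalized + 1)`).
#' @param truth truth table from [simulate_counts()].
#' @param cfg [sim_config()].
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return list: `mrna` (gene x sample matrix, log2-scale expression),
#'   `host_map` (data.frame circ_id, gene_id), `truth` (input with
#'   `host_rho` filled for the chosen pairs).
#' @export
simulate_host_mrna <- function(circ_mat, truth, cfg = sim_config(),
                               seed = if (is.null(cfg$seed)) NULL else cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  for (h in cfg$host_rho_sets)
    if (abs(h$rho) > 1) stop_fmt("|rho| must be <= 1")
  meta <- attr(circ_mat, "row_meta")
  n <- ncol(circ_mat)
  if (n < 3L) stop_fmt("need >= 3 samples")
  eligible <- rownames(circ_mat)
  eligible <- eligible[eligible %in% truth$circ_id[is.na(truth$spike_label)]]
  eligible <- eligible[row_vars(circ_mat[eligible, , drop = FALSE]) > 0]
  need <- sum(vapply(cfg$host_rho_sets, `[[`, 0, "n_pairs"))
  if (length(eligible) < need)
    stop_fmt("only %d eligible unspiked circRNAs for %d requested pairs",
             length(eligible), need)
  with_seed(seed, {
    chosen_all <- sample(eligible, need)
    offset <- 0L
    rows <- list()
    for (hs in cfg$host_rho_sets) {
      ids <- chosen_all[offset + seq_len(hs$n_pairs)]
      offset <- offset + hs$n_pairs
      rows[[length(rows) + 1L]] <- data.frame(circ_id = ids, rho = hs$rho,
                                              stringsAsFactors = FALSE)
    }
    plan <- do.call(rbind, rows)
    gene_id <- if (!is.null(meta)) meta$host_gene[match(plan$circ_id, meta$circ_id)]
               else rep(NA_character_, nrow(plan))
    gene_id[is.na(gene_id)] <- sprintf("HG%05d", which(is.na(gene_id)))
    mrna <- matrix(NA_real_, nrow(plan), n,
                   dimnames = list(gene_id, colnames(circ_mat)))
    for (i in seq_len(nrow(plan))) {
      x <- circ_mat[plan$circ_id[i], ]
      z <- (x - mean(x)) / stats::sd(x)
      rho <- plan$rho[i]
      if (abs(rho) == 1) {
        h <- sign(rho) * z
      } else {
        e <- stats::rnorm(n)
        u <- e - mean(e) - z * (sum((e - mean(e)) * z) / sum(z^2))
        u <- u / stats::sd(u)
        h <- rho * z + sqrt(1 - rho^2) * u
        h <- h / stats::sd(h)        # exact unit sample sd => exact sample PCC
      }
      mrna[i, ] <- 10 + 1.5 * h
    }
    truth$host_rho[match(plan$circ_id, truth$circ_id)] <- plan$rho
    list(mrna = mrna,
         host_map = data.frame(circ_id = plan$circ_id, gene_id = gene_id,
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}
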