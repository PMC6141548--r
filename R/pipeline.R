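# End-to-end orchestration: ingest -> candidate filter -> expression filter
# -> normalize -> specificity screens -> co-expression -> host correlation
# -> enrichment, with stage logging and seeded determinism.

#' Pipeline configuration
#'
#' All stage thresholds in one validated list.  Either simulate the input
#' experiment (`simulate = TRUE`, using `sim`) or point `counts_path` /
#' `ciri_paths` plus `sample_table_path` at real tables.  A single `seed`
#' fans out to fixed per-stage seeds (simulation, sex permutations, age
#' permutations, host-mRNA simulation), so stages are individually
#' reproducible.
#'
#' @param out_dir directory every stage writes its TSV into.
#' @param seed master seed (small integer).
#' @param simulate generate the experiment with [simulate_counts()].
#' @param sim [sim_config()] used when simulating.
#' @param counts_path junction-count matrix TSV (used when not simulating).
#' @param ciri_paths named character vector (sample_id -> per-sample CIRI2
#'   table); alternative to `counts_path`.
#' @param ciri_dialect dialect passed to [read_ciri_table()].
#' @param sample_table_path sample design TSV.
#' @param mrna_path,host_map_path host-mRNA matrix and circRNA-to-gene map
#'   TSVs (optional; simulated when `simulate = TRUE`).
#' @param gene_sets_path optional two-column annotation TSV for the
#'   enrichment stage.
#' @param filter [filter_config()].
#' @param alpha_spatial,spatial_mode spatial screen threshold and mode.
#' @param alpha_group sex/age screen threshold.
#' @param n_perm label permutations for the permutation null.
#' @param beta,min_module_size,cut_height,coexpr_max_rows co-expression
#'   parameters; at most `coexpr_max_rows` top-variance circRNAs enter the
#'   network.
#' @param min_abs_pcc,max_p host-correlation classification thresholds.
#' @param pseudocount offset for log2 transforms and fold changes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            simulate = TRUE,
                            sim = sim_config(),
                            counts_path = NULL,
                            ciri_paths = NULL,
                            ciri_dialect = "ciri2",
                            sample_table_path = NULL,
                            mrna_path = NULL,
                            host_map_path = NULL,
                            gene_sets_path = NULL,
                            filter = filter_config(),
                            alpha_spatial = 0.01,
                            spatial_mode = "one_vs_rest",
                            alpha_group = 0.05,
                            n_perm = 2000L,
                            beta = 3L,
                            min_module_size = 30L,
                            cut_height = 0.5,
                            coexpr_max_rows = 2000L,
                            min_abs_pcc = 0.3,
                            max_p = 0.1,
                            pseudocount = 1) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop_fmt("configuration error: out_dir is required")
  if (!simulate) {
    if (is.null(sample_table_path))
      stop_fmt("configuration error: sample_table_path required when simulate = FALSE")
    if (is.null(counts_path) && is.null(ciri_paths))
      stop_fmt("configuration error: counts_path or ciri_paths required when simulate = FALSE")
    for (p in c(counts_path, unname(ciri_paths), sample_table_path,
                mrna_path, host_map_path, gene_sets_path))
      if (!file.exists(p)) stop_fmt("configuration error: input not found: %s", p)
  }
  stopifnot(inherits(filter, "filter_config"), inherits(sim, "sim_config"))
  if (alpha_spatial <= 0 || alpha_spatial >= 1 || alpha_group <= 0 || alpha_group >= 1)
    stop_fmt("alphas must lie in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage, writes one TSV per stage output into
#' `cfg$out_dir`, and returns (and writes as `report.json`) a run report
#' with the parameters and the number of circRNAs surviving each stage.
#' Identical config + seed give byte-identical outputs.
#'
#' @param cfg [pipeline_config()].
#' @return run report (named list), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(sim = cfg$seed + 101L, perm_sex = cfg$seed + 202L,
                perm_age = cfg$seed + 303L, mrna = cfg$seed + 404L)
  report <- list(package = "circage",
                 version = as.character(utils::packageVersion("circage")),
                 seed = cfg$seed,
                 parameters = list(
                   filter = unclass(cfg$filter),
                   alpha_spatial = cfg$alpha_spatial,
                   spatial_mode = cfg$spatial_mode,
                   alpha_group = cfg$alpha_group, n_perm = cfg$n_perm,
                   beta = cfg$beta, min_module_size = cfg$min_module_size,
                   cut_height = cfg$cut_height,
                   min_abs_pcc = cfg$min_abs_pcc, max_p = cfg$max_p,
                   pseudocount = cfg$pseudocount))
  stage <- function(name) .msg("stage %s", name)

  stage("ingest")
  truth <- NULL
  if (cfg$simulate) {
    sim <- simulate_counts(cfg$sim, seed = seeds$sim)
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    .write_tsv(truth, file.path(cfg$out_dir, "truth.tsv"))
  } else {
    samples <- read_sample_table(cfg$sample_table_path)
    if (!is.null(cfg$ciri_paths)) {
      recs <- do.call(rbind, lapply(names(cfg$ciri_paths), function(sid)
        candidate_filter(read_ciri_table(cfg$ciri_paths[[sid]], sid,
                                         dialect = cfg$ciri_dialect),
                         cfg$filter$min_candidate_reads)))
      counts <- build_count_matrix(recs, samples)
    } else {
      counts <- read_count_matrix(cfg$counts_path)
    }
  }
  # candidate threshold applied cell-wise: a library supports a circRNA only
  # with >= min_candidate_reads junction reads (per-sample detection rule)
  counts[counts < cfg$filter$min_candidate_reads] <- 0L
  write_count_matrix(counts, file.path(cfg$out_dir, "counts.tsv"))
  write_sample_table(samples, file.path(cfg$out_dir, "sample_table.tsv"))
  report$n_candidates <- nrow(counts)

  stage("expression_filter")
  outcome <- expression_filter(counts, samples, cfg$filter)
  .write_tsv(outcome, file.path(cfg$out_dir, "filter_report.tsv"))
  kept <- apply_filter(counts, outcome)
  report$n_kept <- nrow(kept)
  report$route_counts <- as.list(table(outcome$route[outcome$kept]))

  stage("normalize")
  sf <- size_factors(kept)
  .write_tsv(data.frame(sample_id = names(sf), size_factor = signif(sf, 6)),
             file.path(cfg$out_dir, "size_factors.tsv"))
  norm <- normalize_counts(kept, sf)
  lognorm <- log2_norm(norm, cfg$pseudocount)
  write_count_matrix(norm, file.path(cfg$out_dir, "normalized.tsv"))

  stage("spatial")
  spatial <- spatial_specific(norm, samples, alpha = cfg$alpha_spatial,
                              mode = cfg$spatial_mode)
  .write_tsv(spatial, file.path(cfg$out_dir, "spatial.tsv"))
  report$n_spatial_called <- length(unique(spatial$circ_id[spatial$called]))

  called_sets <- list()
  for (fac in c("sex", "age")) {
    stage(paste0(fac, "bias"))
    gb <- group_biased(norm, samples, factor = fac, alpha = cfg$alpha_group)
    pt <- permutation_test(norm, samples, factor = fac, n_perm = cfg$n_perm,
                           seed = seeds[[paste0("perm_", fac)]])
    gb$mean_diff <- pt$mean_diff[match(gb$circ_id, pt$circ_id)]
    gb$p_perm <- pt$p_perm[match(gb$circ_id, pt$circ_id)]
    gb$called_perm <- gb$p_perm < cfg$alpha_group
    .write_tsv(gb, file.path(cfg$out_dir, paste0(fac, "bias.tsv")))
    called_sets[[fac]] <- gb$circ_id[gb$called]
    cmp <- compare_sets(gb$circ_id[gb$called], gb$circ_id[gb$called_perm])
    report[[paste0("n_", fac, "_called_t")]] <- cmp$size_a
    report[[paste0("n_", fac, "_called_perm")]] <- cmp$size_b
    report[[paste0(fac, "_t_perm_overlap")]] <- cmp$intersection
    report[[paste0(fac, "_t_perm_overlap_ratio")]] <- cmp$overlap_ratio
    # overlap significance of the two detection routes
    report[[paste0(fac, "_t_perm_overlap_p")]] <-
      hypergeom_tail(nrow(gb), cmp$size_a, cmp$size_b, cmp$intersection)
  }

  stage("volcano")
  lfc <- log2_fold_change(norm, samples, factor = "age",
                          pseudocount = cfg$pseudocount)
  .write_tsv(lfc, file.path(cfg$out_dir, "volcano_age.tsv"))
  report$age_direction_counts <- as.list(attr(lfc, "direction_counts"))

  stage("coexpression")
  v <- row_vars(lognorm)
  net_rows <- names(sort(v, decreasing = TRUE))[
    seq_len(min(cfg$coexpr_max_rows, sum(v > 0)))]
  net_mat <- lognorm[net_rows, , drop = FALSE]
  adj <- adjacency(net_mat, beta = cfg$beta)
  tom <- tom_similarity(adj)
  modules <- detect_modules(tom, min_module_size = cfg$min_module_size,
                            cut_height = cfg$cut_height)
  .write_tsv(data.frame(circ_id = names(modules$labels),
                        module = unname(modules$labels)),
             file.path(cfg$out_dir, "modules.tsv"))
  eig <- module_eigengene(net_mat, modules)
  eig_df <- data.frame(module = rownames(eig$eigengenes),
                       var_explained = signif(unname(eig$var_explained), 6),
                       signif(eig$eigengenes, 6), check.names = FALSE)
  .write_tsv(eig_df, file.path(cfg$out_dir, "eigengenes.tsv"))
  if (nrow(eig$eigengenes) > 1L) {
    ec <- stats::cor(t(eig$eigengenes))
    .write_tsv(data.frame(module = rownames(ec), signif(ec, 6),
                          check.names = FALSE),
               file.path(cfg$out_dir, "eigengene_cor.tsv"))
  }
  report$n_modules <- sum(names(modules$sizes) != "0")

  stage("host_correlation")
  mrna <- NULL; host_map <- NULL
  if (cfg$simulate) {
    hm <- simulate_host_mrna(lognorm, truth, cfg$sim, seed = seeds$mrna)
    mrna <- hm$mrna; host_map <- hm$host_map; truth <- hm$truth
    .write_tsv(truth, file.path(cfg$out_dir, "truth.tsv"))
    .write_tsv(cbind(gene_id = rownames(mrna),
                     as.data.frame(signif(mrna, 6))),
               file.path(cfg$out_dir, "mrna.tsv"))
    .write_tsv(host_map, file.path(cfg$out_dir, "host_map.tsv"))
  } else if (!is.null(cfg$mrna_path) && !is.null(cfg$host_map_path)) {
    mtab <- utils::read.delim(cfg$mrna_path, check.names = FALSE)
    mrna <- as.matrix(mtab[, -1L, drop = FALSE]); rownames(mrna) <- mtab[[1L]]
    host_map <- utils::read.delim(cfg$host_map_path, stringsAsFactors = FALSE)
  }
  if (!is.null(mrna)) {
    pairs <- pair_correlations(lognorm, mrna[, colnames(lognorm), drop = FALSE],
                               host_map)
    pairs <- classify_pairs(pairs, cfg$min_abs_pcc, cfg$max_p)
    .write_tsv(pairs, file.path(cfg$out_dir, "host_pairs.tsv"))
    report$host_correlation <- attr(pairs, "summary")
  }

  if (!is.null(cfg$gene_sets_path)) {
    stage("enrichment")
    sets <- read_gene_sets(cfg$gene_sets_path)
    meta <- attr(counts, "row_meta")
    host_of <- function(ids) {
      if (!is.null(meta)) unique(stats::na.omit(meta$host_gene[match(ids, meta$circ_id)]))
      else character()
    }
    universe <- host_of(rownames(kept))
    query <- host_of(called_sets$age)
    if (length(query) && length(universe)) {
      enr <- enrich_gene_sets(query, universe, sets)
      .write_tsv(enr, file.path(cfg$out_dir, "enrichment_age.tsv"))
      report$n_enriched_sets <- sum(enr$q_value <= 0.05)
    }
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .msg("pipeline complete: %d candidates -> %d kept", report$n_candidates,
       report$n_kept)
  invisible(report)
}
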