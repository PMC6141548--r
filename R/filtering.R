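# Candidate-read threshold and the five-rule expression-filter cascade that
# defines the analysis set of "well expressed" circRNAs.

#' Thresholds of the expression-filter cascade
#'
#' The cascade keeps a circRNA when any of three routes fires:
#' \enumerate{
#'   \item a sample "expresses" the circRNA when it has at least
#'     `min_expressed_reads` (default 3) back-splice junction reads;
#'   \item a brain area is "expressed" when at least `min_samples_per_area`
#'     (default 2) of its samples express the circRNA;
#'   \item route `rule3`: at least `min_expressed_areas` (default 2) areas
#'     are expressed;
#'   \item route `rule4`: exactly one area is expressed and the total number
#'     of expressing samples (over all areas) is at least
#'     `min_expressed_samples_single_area` (default 6);
#'   \item route `rule5`: the circRNA's total junction reads across all
#'     samples reach `min_total_reads` (default 30).
#' }
#' `min_candidate_reads` (default 2) is the per-sample candidate threshold
#' applied upstream by [candidate_filter()].
#'
#' @param min_candidate_reads,min_expressed_reads,min_samples_per_area,min_expressed_areas,min_expressed_samples_single_area,min_total_reads
#'   non-negative thresholds, see above.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_candidate_reads = 2L,
                          min_expressed_reads = 3L,
                          min_samples_per_area = 2L,
                          min_expressed_areas = 2L,
                          min_expressed_samples_single_area = 6L,
                          min_total_reads = 30L) {
  cfg <- list(min_candidate_reads = min_candidate_reads,
              min_expressed_reads = min_expressed_reads,
              min_samples_per_area = min_samples_per_area,
              min_expressed_areas = min_expressed_areas,
              min_expressed_samples_single_area = min_expressed_samples_single_area,
              min_total_reads = min_total_reads)
  if (any(!vapply(cfg, function(x) is.numeric(x) && length(x) == 1L && x >= 0,
                  logical(1))))
    stop_fmt("all filter thresholds must be single non-negative numbers")
  structure(cfg, class = "filter_config")
}

#' Per-sample candidate read filter
#'
#' Keeps per-sample records supported by at least `min_reads` head-to-tail
#' junction reads (candidate threshold applied per library before matrix
#' assembly).
#'
#' @param records record data.frame.
#' @param min_reads minimum junction reads per record (default 2).
#' @return filtered record data.frame.
#' @export
candidate_filter <- function(records, min_reads = 2L) {
  validate_circ_records(records)
  out <- records[records$junction_reads >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression-filter cascade over a junction-count matrix
#'
#' Evaluates the three keep routes of [filter_config()] per circRNA.  Routes
#' are reported in first-match order `rule3`, `rule4`, `rule5`; the kept set
#' is their disjunction.
#'
#' @param counts junction-count matrix (circRNA x sample).
#' @param samples sample table covering every matrix column.
#' @param cfg [filter_config()].
#' @return data.frame: `circ_id`, `kept`, `route`
#'   (factor rule3/rule4/rule5/dropped), `expressed_samples`,
#'   `expressed_areas`, `total_reads`.
#' @export
expression_filter <- function(counts, samples, cfg = filter_config()) {
  validate_count_matrix(counts)
  samples <- as_sample_table(samples)
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss))
    stop_fmt("matrix sample(s) missing from sample table: %s",
             paste(miss, collapse = ", "))
  if (!inherits(cfg, "filter_config")) stop_fmt("cfg must be a filter_config")
  region <- samples$region[match(colnames(counts), samples$sample_id)]
  expressed <- counts >= cfg$min_expressed_reads
  area_ind <- stats::model.matrix(~ 0 + factor(region))
  area_samples <- expressed %*% area_ind                    # circ x area
  expressed_areas <- rowSums(area_samples >= cfg$min_samples_per_area)
  expressed_samples <- rowSums(expressed)
  total_reads <- rowSums(counts)
  rule3 <- expressed_areas >= cfg$min_expressed_areas
  rule4 <- expressed_areas == 1 &
    expressed_samples >= cfg$min_expressed_samples_single_area
  rule5 <- total_reads >= cfg$min_total_reads
  route <- rep("dropped", nrow(counts))
  route[rule5] <- "rule5"
  route[rule4] <- "rule4"
  route[rule3] <- "rule3"
  data.frame(circ_id = rownames(counts),
             kept = rule3 | rule4 | rule5,
             route = factor(route, levels = c("rule3", "rule4", "rule5", "dropped")),
             expressed_samples = as.integer(expressed_samples),
             expressed_areas = as.integer(expressed_areas),
             total_reads = as.integer(round(total_reads)),
             stringsAsFactors = FALSE)
}

#' Subset a count matrix to the kept circRNAs
#'
#' @param counts junction-count matrix.
#' @param outcome result of [expression_filter()].
#' @return the kept rows of `counts` (row_meta attribute subset alongside).
#' @export
apply_filter <- function(counts, outcome) {
  keep <- outcome$circ_id[outcome$kept]
  out <- counts[rownames(counts) %in% keep, , drop = FALSE]
  meta <- attr(counts, "row_meta")
  if (!is.null(meta))
    attr(out, "row_meta") <- meta[match(rownames(out), meta$circ_id), , drop = FALSE]
  out
}
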