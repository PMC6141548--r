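# Genomic-context classification and tolerance-based matching of circRNA sets.

#' Classify circRNAs by genomic context
#'
#' Assigns exactly one category per circRNA using annotated gene models:
#' \describe{
#'   \item{exonic}{both back-splice boundaries fall inside exons of one
#'     same-strand gene (with `strict_boundary = TRUE`, the boundaries must
#'     coincide with exon boundaries of that gene);}
#'   \item{intronic}{the circRNA overlaps a same-strand gene but fails the
#'     exonic test;}
#'   \item{antisense}{only opposite-strand genes overlap;}
#'   \item{intergenic}{no gene overlap.}
#' }
#' Precedence is exonic > intronic > antisense > intergenic.  Strand `"."`
#' is compatible with either gene strand.  circRNAs on chromosomes absent
#' from the models are classified intergenic with a warning.
#'
#' @param records record or `row_meta` data.frame (circ_id, chrom, start,
#'   end, strand; internal 0-based half-open coordinates).
#' @param models [gene_models] object.
#' @param strict_boundary require back-splice sites to coincide with
#'   annotated exon boundaries for the exonic call.
#' @return data.frame `circ_id`, `category`
#'   (factor: exonic, intronic, antisense, intergenic).
#' @export
classify_genomic_context <- function(records, models, strict_boundary = FALSE) {
  if (!inherits(models, "gene_models")) stop_fmt("models must be gene_models")
  lev <- c("exonic", "intronic", "antisense", "intergenic")
  n <- nrow(records)
  if (n == 0L)
    return(data.frame(circ_id = character(),
                      category = factor(character(), levels = lev)))
  exons <- models$exons
  genes <- models$genes
  missing_chr <- setdiff(unique(records$chrom), unique(genes$chrom))
  if (length(missing_chr))
    warning(sprintf("circage: %d circRNA chromosome(s) absent from gene models (%s); classified intergenic",
                    length(missing_chr), paste(missing_chr, collapse = ", ")),
            call. = FALSE)
  category <- rep("intergenic", n)
  if (nrow(genes)) {
    lv <- unique(c(records$chrom, genes$chrom))
    circ_gr <- GenomicRanges::GRanges(factor(records$chrom, lv),
                                      IRanges::IRanges(records$start + 1L, records$end))
    gene_gr <- GenomicRanges::GRanges(factor(genes$chrom, lv),
                                      IRanges::IRanges(genes$start + 1L, genes$end))
    exon_gr <- GenomicRanges::GRanges(factor(exons$chrom, lv),
                                      IRanges::IRanges(exons$start + 1L, exons$end))
    hits <- GenomicRanges::findOverlaps(circ_gr, gene_gr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
    strand_ok <- records$strand[qi] == "." | records$strand[qi] == genes$strand[gi]
    has_same <- tabulate(qi[strand_ok], n) > 0L
    has_any <- tabulate(qi, n) > 0L
    category[has_any & !has_same] <- "antisense"
    category[has_same] <- "intronic"

    # exonic: both boundary bases inside exons of one same-strand gene
    start_pt <- GenomicRanges::GRanges(factor(records$chrom, lv),
                                       IRanges::IRanges(records$start + 1L, width = 1L))
    end_pt <- GenomicRanges::GRanges(factor(records$chrom, lv),
                                     IRanges::IRanges(records$end, width = 1L))
    hit_pairs <- function(points, boundary) {
      h <- GenomicRanges::findOverlaps(points, exon_gr, ignore.strand = TRUE)
      ci <- S4Vectors::queryHits(h); ei <- S4Vectors::subjectHits(h)
      ok <- records$strand[ci] == "." | records$strand[ci] == exons$strand[ei]
      if (strict_boundary) {
        at <- if (boundary == "start") records$start[ci] == exons$start[ei]
              else records$end[ci] == exons$end[ei]
        ok <- ok & at
      }
      unique(paste(ci[ok], exons$gene_id[ei[ok]], sep = "\r"))
    }
    exonic_keys <- intersect(hit_pairs(start_pt, "start"), hit_pairs(end_pt, "end"))
    if (length(exonic_keys)) {
      ci <- as.integer(sub("\r.*$", "", exonic_keys))
      category[unique(ci)] <- "exonic"
    }
  }
  data.frame(circ_id = records$circ_id,
             category = factor(category, levels = lev),
             stringsAsFactors = FALSE)
}

#' Match two circRNA sets with coordinate tolerance
#'
#' Two loci match when chromosomes agree, strands are compatible (`"."`
#' matches either strand) and both the start and the end coordinate differ
#' by at most `tolerance_nt` nucleotides — the +/-5 nt convention used to
#' compare back-splice predictions between methods.  With `tolerance_nt = 0`
#' matching reduces to exact identity (up to the strand wildcard).
#'
#' @param query,subject record data.frames (deduplicated by `circ_id`
#'   internally).
#' @param tolerance_nt non-negative integer tolerance on each coordinate.
#' @return list with `pairs` (data.frame query_id, subject_id, start_offset,
#'   end_offset; offsets are subject minus query) and `summary` (n_query,
#'   n_subject, query_matched, subject_matched, jaccard — query-anchored:
#'   query_matched / (n_query + n_subject - query_matched)).
#' @export
match_circ_sets <- function(query, subject, tolerance_nt = 5L) {
  if (is.null(query) || is.null(subject)) stop_fmt("query/subject must be non-null")
  if (!is.numeric(tolerance_nt) || length(tolerance_nt) != 1L || tolerance_nt < 0)
    stop_fmt("tolerance_nt must be a single non-negative integer")
  tol <- as.integer(tolerance_nt)
  q <- query[!duplicated(query$circ_id), , drop = FALSE]
  s <- subject[!duplicated(subject$circ_id), , drop = FALSE]
  pairs <- data.frame(query_id = character(), subject_id = character(),
                      start_offset = integer(), end_offset = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(q) && nrow(s)) {
    lv <- unique(c(q$chrom, s$chrom))
    qw <- GenomicRanges::GRanges(factor(q$chrom, lv),
            IRanges::IRanges(pmax(q$start - tol, 0L) + 1L, q$start + tol + 1L))
    sp <- GenomicRanges::GRanges(factor(s$chrom, lv),
            IRanges::IRanges(s$start + 1L, width = 1L))
    h <- GenomicRanges::findOverlaps(qw, sp, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    keep <- abs(s$end[si] - q$end[qi]) <= tol &
      (q$strand[qi] == "." | s$strand[si] == "." | q$strand[qi] == s$strand[si])
    qi <- qi[keep]; si <- si[keep]
    pairs <- data.frame(query_id = q$circ_id[qi], subject_id = s$circ_id[si],
                        start_offset = s$start[si] - q$start[qi],
                        end_offset = s$end[si] - q$end[qi],
                        stringsAsFactors = FALSE)
    ord <- order(pairs$query_id, pairs$subject_id, method = "radix")
    pairs <- pairs[ord, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  qm <- length(unique(pairs$query_id))
  sm <- length(unique(pairs$subject_id))
  summary <- list(n_query = nrow(q), n_subject = nrow(s),
                  query_matched = qm, subject_matched = sm,
                  jaccard = if (nrow(q) + nrow(s) - qm > 0)
                    qm / (nrow(q) + nrow(s) - qm) else NA_real_)
  list(pairs = pairs, summary = summary)
}
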