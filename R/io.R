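# Readers and writers for every external table the pipeline touches.
#
# Coordinate convention: everything inside the package is 0-based half-open
# [start, end).  CIRI2 tables and GTF are 1-based inclusive and are converted
# at this boundary, in both directions.

#' Brain regions, sexes and ages of the study design
#'
#' Closed vocabularies used to validate sample tables: eight anatomical brain
#' compartments (prefrontal, posterior cingulate, temporal, parietal and
#' occipital cortex, hippocampal CA1, dentate gyrus, cerebellar cortex), two
#' sexes and the two sampled ages (years).
#' @name design_vocab
NULL

#' @rdname design_vocab
#' @export
BRAIN_REGIONS <- c("PFC", "PCC", "TC", "PC", "OC", "CA1", "DG", "CB")

#' @rdname design_vocab
#' @export
SEXES <- c("M", "F")

#' @rdname design_vocab
#' @export
AGES_YEARS <- c(10L, 20L)

#' Format and parse circRNA identifiers
#'
#' A circRNA is identified by the exact back-splice locus tuple
#' `chrom:start|end:strand` with 0-based half-open coordinates.
#'
#' @param chrom,start,end,strand locus components; `end > start >= 0`,
#'   strand one of `+`, `-`, `.`.
#' @return `format_circ_id()` a character vector of ids; `parse_circ_id()` a
#'   data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' id <- format_circ_id("chr1", 99, 500, "+")
#' parse_circ_id(id)
#' @export
format_circ_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d|%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' @param circ_id character vector of ids in `chrom:start|end:strand` form.
#' @rdname format_circ_id
#' @export
parse_circ_id <- function(circ_id) {
  m <- regmatches(circ_id, regexec("^(.+):([0-9]+)\\|([0-9]+):([+.-])$", circ_id))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop_fmt("malformed circ_id: %s", paste(utils::head(circ_id[bad], 3), collapse = ", "))
  data.frame(
    chrom  = vapply(m, `[`, "", 2L),
    start  = as.integer(vapply(m, `[`, "", 3L)),
    end    = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

validate_circ_records <- function(records) {
  need <- c("circ_id", "chrom", "start", "end", "strand", "junction_reads",
            "host_gene", "sample_id")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_fmt("circRNA record table lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(records)) {
    if (any(records$start < 0L) || any(records$end <= records$start))
      stop_fmt("invalid coordinates: need end > start >= 0")
    if (any(records$junction_reads < 0L))
      stop_fmt("negative junction_reads")
    if (!all(records$strand %in% c("+", "-", ".")))
      stop_fmt("strand must be one of +, -, .")
  }
  invisible(records)
}

#' Read a per-sample back-splice junction table
#'
#' Parses one CIRI2-style circRNA prediction table (one sequencing library)
#' into a record data.frame.  Printed coordinates are 1-based inclusive and
#' are converted to the internal 0-based half-open convention.
#'
#' @param path path to a TSV file.
#' @param sample_id sample identifier attached to every record.
#' @param dialect `"ciri2"` expects (at least) the CIRI2 output columns
#'   `circRNA_ID`, `chr`, `circRNA_start`, `circRNA_end`, `#junction_reads`,
#'   `gene_id`, `strand`; `"minimal"` expects exactly
#'   `chrom`, `start`, `end`, `strand`, `junction_reads`, `gene_id`.
#' @return data.frame with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `junction_reads`, `host_gene`, `sample_id`.
#' @export
read_ciri_table <- function(path, sample_id, dialect = c("ciri2", "minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  need <- switch(dialect,
    ciri2   = c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                "#junction_reads", "gene_id", "strand"),
    minimal = c("chrom", "start", "end", "strand", "junction_reads", "gene_id"))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_fmt("format error in %s: missing column(s) %s for dialect '%s'",
             path, paste(miss, collapse = ", "), dialect)
  if (dialect == "minimal" && length(setdiff(names(tab), need)))
    stop_fmt("format error in %s: unexpected extra column(s) %s for dialect 'minimal'",
             path, paste(setdiff(names(tab), need), collapse = ", "))
  if (nrow(tab) == 0L) {
    out <- data.frame(circ_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      junction_reads = integer(), host_gene = character(),
                      sample_id = character(), stringsAsFactors = FALSE)
    .msg("read_ciri_table: %s -> 0 records", basename(path))
    return(out)
  }
  get <- function(col) tab[[col]]
  if (dialect == "ciri2") {
    chrom <- as.character(get("chr"))
    start1 <- get("circRNA_start"); end1 <- get("circRNA_end")
    reads_raw <- get("#junction_reads")
    gene <- as.character(get("gene_id"))
  } else {
    chrom <- as.character(get("chrom"))
    start1 <- get("start"); end1 <- get("end")
    reads_raw <- get("junction_reads")
    gene <- as.character(get("gene_id"))
  }
  strand <- as.character(get("strand"))
  as_int <- function(x, what) {
    v <- suppressWarnings(as.integer(as.character(x)))
    bad <- which(is.na(v) | as.numeric(as.character(x)) != v)
    if (length(bad))
      stop_fmt("format error in %s: non-integer %s at data line %d (value '%s')",
               path, what, bad[1L], as.character(x)[bad[1L]])
    v
  }
  start1 <- as_int(start1, "start")
  end1 <- as_int(end1, "end")
  reads <- as_int(reads_raw, "junction_reads")
  gene[gene %in% c("", "n/a", "NA", "intergenic", "intergenic_region")] <- NA_character_
  records <- data.frame(
    circ_id = format_circ_id(chrom, start1 - 1L, end1, strand),
    chrom = chrom, start = start1 - 1L, end = end1, strand = strand,
    junction_reads = reads, host_gene = gene,
    sample_id = rep(as.character(sample_id), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_circ_records(records)
  .msg("read_ciri_table: %s -> %d records", basename(path), nrow(records))
  records
}

#' Convert internal records back to a printable 1-based table
#'
#' Inverse of the coordinate conversion done by [read_ciri_table()] for the
#' minimal dialect; used by [write_ciri_table()].
#'
#' @param records record data.frame (internal 0-based half-open coordinates).
#' @return data.frame with printed 1-based inclusive coordinates.
#' @export
records_to_minimal <- function(records) {
  validate_circ_records(records)
  data.frame(chrom = records$chrom, start = records$start + 1L,
             end = records$end, strand = records$strand,
             junction_reads = records$junction_reads,
             gene_id = ifelse(is.na(records$host_gene), "n/a", records$host_gene),
             stringsAsFactors = FALSE)
}

#' @param records record data.frame.
#' @param path output path.
#' @rdname records_to_minimal
#' @export
write_ciri_table <- function(records, path) {
  utils::write.table(records_to_minimal(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample design table
#'
#' The table must carry columns `sample_id`, `region`, `sex`, `age_years`
#' with values drawn from the closed design vocabularies
#' ([BRAIN_REGIONS], [SEXES], [AGES_YEARS]).
#'
#' @param path TSV path.
#' @return validated data.frame (sample table).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_sample_table(tab)
}

#' @param df data.frame to validate as a sample table.
#' @rdname read_sample_table
#' @export
as_sample_table <- function(df) {
  need <- c("sample_id", "region", "sex", "age_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("sample table lacks columns: %s", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$region <- as.character(df$region)
  df$sex <- as.character(df$sex)
  df$age_years <- as.integer(df$age_years)
  if (anyDuplicated(df$sample_id))
    stop_fmt("duplicate sample_id: %s",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_region <- setdiff(unique(df$region), BRAIN_REGIONS)
  if (length(bad_region))
    stop_fmt("unknown region value(s) %s; allowed: %s",
             paste(bad_region, collapse = ", "), paste(BRAIN_REGIONS, collapse = ", "))
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex))
    stop_fmt("unknown sex value(s) %s; allowed: %s",
             paste(bad_sex, collapse = ", "), paste(SEXES, collapse = ", "))
  bad_age <- setdiff(unique(df$age_years), AGES_YEARS)
  if (length(bad_age))
    stop_fmt("unknown age_years value(s) %s; allowed: %s",
             paste(bad_age, collapse = ", "), paste(AGES_YEARS, collapse = ", "))
  df[, need]
}

#' @param samples sample table.
#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as_sample_table(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-sample records into a junction-count matrix
#'
#' circRNA identity is the exact tuple (chrom, start, end, strand): records
#' sharing the tuple across samples fill one row; loci differing by a single
#' nucleotide stay distinct (tolerant matching is [match_circ_sets()]).
#' Absent (circRNA, sample) cells are 0.  Rows are ordered lexicographically
#' by `circ_id` (C locale), columns follow the sample table.
#'
#' @param records record data.frame (e.g. from [read_ciri_table()], several
#'   samples concatenated with `rbind`).
#' @param samples sample table covering every `sample_id` in `records`.
#' @return integer matrix (circRNA x sample) with a `row_meta` attribute
#'   (data.frame: circ_id, chrom, start, end, strand, host_gene).
#' @export
build_count_matrix <- function(records, samples) {
  validate_circ_records(records)
  samples <- as_sample_table(samples)
  extra <- setdiff(unique(records$sample_id), samples$sample_id)
  if (length(extra))
    stop_fmt("record sample_id(s) absent from sample table: %s",
             paste(extra, collapse = ", "))
  key <- paste(records$circ_id, records$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k) {
      length(unique(records$junction_reads[key == k])) > 1L
    }, logical(1))
    if (any(conflict))
      stop_fmt("conflicting duplicate counts for (circ_id, sample_id): %s",
               gsub("\r", " / ", names(conflict)[conflict][1L]))
    records <- records[!duplicated(key), , drop = FALSE]
  }
  row_ids <- sort_c(unique(records$circ_id))
  col_ids <- samples$sample_id
  counts <- matrix(0L, nrow = length(row_ids), ncol = length(col_ids),
                   dimnames = list(row_ids, col_ids))
  counts[cbind(match(records$circ_id, row_ids),
               match(records$sample_id, col_ids))] <- records$junction_reads
  first <- records[!duplicated(records$circ_id), , drop = FALSE]
  # prefer a non-missing host gene annotation across samples
  host <- tapply(records$host_gene, records$circ_id, function(h) {
    h <- h[!is.na(h)]
    if (length(h)) h[1L] else NA_character_
  })
  meta <- first[match(row_ids, first$circ_id),
                c("circ_id", "chrom", "start", "end", "strand")]
  meta$host_gene <- unname(host[row_ids])
  rownames(meta) <- NULL
  attr(counts, "row_meta") <- meta
  counts
}

validate_count_matrix <- function(mat, what = "count matrix") {
  if (!is.matrix(mat)) stop_fmt("%s must be a matrix", what)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_fmt("%s must carry circ_id rownames and sample_id colnames", what)
  if (anyDuplicated(rownames(mat))) stop_fmt("%s has duplicate row ids", what)
  if (anyDuplicated(colnames(mat))) stop_fmt("%s has duplicate column ids", what)
  if (any(!is.finite(mat))) stop_fmt("%s has non-finite values", what)
  if (any(mat < 0)) stop_fmt("%s has negative values", what)
  invisible(mat)
}

#' Write / read a circRNA x sample matrix as TSV
#'
#' First column `circ_id`, one column per sample.  Integer matrices are
#' written as integers (bit-exact round trip); real-valued matrices (e.g.
#' normalized expression) are written with 6 significant digits.
#'
#' @param mat matrix with circ_id rownames and sample_id colnames.
#' @param path TSV path.
#' @export
write_count_matrix <- function(mat, path) {
  validate_count_matrix(mat, "matrix")
  df <- as.data.frame(if (is.integer(mat)) mat else signif(mat, 6))
  df <- cbind(circ_id = rownames(mat), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param integer_counts coerce values to integer after reading (junction
#'   counts); `FALSE` keeps reals (normalized matrices).
#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, integer_counts = TRUE) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "circ_id")
    stop_fmt("count matrix %s must have circ_id as first column", path)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$circ_id
  storage.mode(mat) <- if (integer_counts) "integer" else "double"
  validate_count_matrix(mat)
  .msg("read_count_matrix: %s -> %d x %d", basename(path), nrow(mat), ncol(mat))
  mat
}

#' Read gene models from a GTF file
#'
#' Imports exon features (1-based inclusive) and converts them to internal
#' 0-based half-open coordinates, grouped and sorted per gene.
#'
#' @param path GTF path.
#' @return object of class `gene_models`: list with `exons` (data.frame:
#'   gene_id, chrom, strand, start, end, sorted within gene) and `genes`
#'   (per-gene span).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L)
    return(gene_models(data.frame(gene_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer())))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_fmt("failed to parse GTF %s: %s",
                                              path, conditionMessage(e)))
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L)
    return(gene_models(data.frame(gene_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer())))
  gid <- gr$gene_id
  if (is.null(gid) || any(is.na(gid) | gid == ""))
    stop_fmt("GTF %s: exon feature without gene_id attribute", path)
  df <- data.frame(gene_id = as.character(gid),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  gene_models(df)
}

#' @param exons data.frame with columns gene_id, chrom, strand, start, end
#'   (0-based half-open) — programmatic constructor used by tests and
#'   simulations.
#' @rdname read_gene_models
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop_fmt("gene models lack columns: %s", paste(miss, collapse = ", "))
  exons <- exons[, need]
  if (nrow(exons) && any(exons$end <= exons$start))
    stop_fmt("gene models: exon with end <= start")
  if (nrow(exons) && !all(exons$strand %in% c("+", "-")))
    stop_fmt("gene models: strand must be + or -")
  exons <- exons[order(exons$gene_id, exons$start, exons$end, method = "radix"), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  genes <- if (nrow(exons)) {
    agg <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
                 strand = e$strand[1L], start = min(e$start), end = max(e$end),
                 stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    agg
  } else exons
  structure(list(exons = exons, genes = genes), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Write circRNAs as BED (0-based half-open)
#'
#' @param records record data.frame or a `row_meta`-style data.frame; an
#'   optional `category` column fills the BED name field as
#'   `circ_id|category`.
#' @param path output path.
#' @export
write_circ_bed <- function(records, path) {
  name <- records$circ_id
  if (!is.null(records$category))
    name <- paste(name, records$category, sep = "|")
  score <- if (!is.null(records$junction_reads)) records$junction_reads else 0L
  bed <- data.frame(records$chrom, records$start, records$end, name, score,
                    records$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
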