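# Genomic-context classification and tolerance matching.

models_fixture <- function() {
  gene_models(data.frame(
    gene_id = c("GA", "GA", "GB"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "+", "-"),
    start = c(100L, 500L, 5000L),
    end = c(200L, 700L, 6000L)))
}

test_that("genomic context covers the four categories with exonic precedence", {
  gm <- models_fixture()
  recs <- rbind(
    make_records("chr1", 100L, 700L, "+"),   # both boundaries in GA exons -> exonic
    make_records("chr1", 250L, 450L, "+"),   # inside GA's intron -> intronic
    make_records("chr1", 5100L, 5900L, "+"), # only opposite-strand GB -> antisense
    make_records("chr1", 9000L, 9500L, "+"), # no gene -> intergenic
    make_records("chr1", 150L, 650L, "."))   # "." strand matches GA -> exonic
  cls <- classify_genomic_context(recs, gm)
  expect_equal(as.character(cls$category),
               c("exonic", "intronic", "antisense", "intergenic", "exonic"))
  # exactly one category per circRNA, deterministic
  expect_false(anyNA(cls$category))
  expect_identical(cls, classify_genomic_context(recs, gm))
})

test_that("strict boundary mode demands annotated exon boundaries", {
  gm <- models_fixture()
  interior <- make_records("chr1", 150L, 650L, "+")  # inside exons, not at edges
  expect_equal(as.character(classify_genomic_context(interior, gm)$category), "exonic")
  expect_equal(as.character(
    classify_genomic_context(interior, gm, strict_boundary = TRUE)$category),
    "intronic")
  exact <- make_records("chr1", 100L, 700L, "+")
  expect_equal(as.character(
    classify_genomic_context(exact, gm, strict_boundary = TRUE)$category),
    "exonic")
})

test_that("unknown chromosomes fall back to intergenic with a warning", {
  gm <- models_fixture()
  rec <- make_records("chr99", 10L, 500L, "+")
  expect_warning(cls <- classify_genomic_context(rec, gm), "absent from gene models")
  expect_equal(as.character(cls$category), "intergenic")
})

test_that("match_circ_sets applies the +/-5 nt rule on both coordinates", {
  q <- make_records("chr1", 1000L, 2000L, "+")
  exact <- match_circ_sets(q, q, tolerance_nt = 5)
  expect_equal(nrow(exact$pairs), 1L)                       # reflexive

  s5 <- make_records("chr1", 1005L, 2000L, "+")             # delta start = 5 -> match
  expect_equal(nrow(match_circ_sets(q, s5, 5)$pairs), 1L)
  expect_equal(match_circ_sets(q, s5, 5)$pairs$start_offset, 5L)

  s6 <- make_records("chr1", 1006L, 2000L, "+")             # delta start = 6 -> no match
  expect_equal(nrow(match_circ_sets(q, s6, 5)$pairs), 0L)

  both <- make_records("chr1", 995L, 2005L, "+")            # both offsets within 5
  expect_equal(nrow(match_circ_sets(q, both, 5)$pairs), 1L)
  other_strand <- make_records("chr1", 1000L, 2000L, "-")
  expect_equal(nrow(match_circ_sets(q, other_strand, 5)$pairs), 0L)
  wildcard <- make_records("chr1", 1000L, 2000L, ".")
  expect_equal(nrow(match_circ_sets(q, wildcard, 5)$pairs), 1L)
  expect_error(match_circ_sets(q, q, tolerance_nt = -1), "non-negative")
})

test_that("matching is symmetric and tolerance 0 equals exact identity", {
  set.seed(42)
  rand_set <- function(n) {
    start <- sample.int(5000, n) * 3L
    make_records(sample(c("chr1", "chr2"), n, TRUE), start,
                 start + sample(100:500, n, TRUE),
                 sample(c("+", "-"), n, TRUE),
                 sample_id = sprintf("r%d", seq_len(n)))
  }
  for (i in 1:5) {
    a <- rand_set(40); b <- rand_set(40)
    ab <- match_circ_sets(a, b, 5)$pairs
    ba <- match_circ_sets(b, a, 5)$pairs
    expect_setequal(paste(ab$query_id, ab$subject_id),
                    paste(ba$subject_id, ba$query_id))
    z <- match_circ_sets(a, b, 0)$pairs
    expect_setequal(z$query_id[z$query_id == z$subject_id],
                    intersect(a$circ_id, b$circ_id))
    expect_true(all(abs(ab$start_offset) <= 5 & abs(ab$end_offset) <= 5))
  }
})
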