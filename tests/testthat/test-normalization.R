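# Median-of-ratios size factors and fold-change summaries.

test_that("size factors hit the analytic cases", {
  mat <- matrix(c(5L, 8L, 20L, 5L, 8L, 20L), ncol = 2,
                dimnames = list(paste0("c", 1:3), c("a", "b")))
  expect_equal(size_factors(mat), c(a = 1, b = 1))       # identical columns

  mat2 <- cbind(a = c(5L, 8L, 20L), b = c(10L, 16L, 40L))
  rownames(mat2) <- paste0("c", 1:3)
  sf <- size_factors(mat2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))      # forced by median-of-ratios
  expect_equal(unname(sf["b"] / sf["a"]), 2)
})

test_that("size factors equal the literal median-of-ratios oracle", {
  set.seed(31)
  for (i in 1:20) {
    mat <- matrix(sample(1:500, 80, replace = TRUE), nrow = 20,
                  dimnames = list(paste0("c", 1:20), paste0("s", 1:4)))
    expect_equal(unname(size_factors(mat)), unname(oracle_size_factors(mat)),
                 tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(32)
  # odd reference-row count: the raw-ratio median used here coincides with
  # DESeq2's log-scale median (they differ only in even-size interpolation)
  mat <- matrix(rnbinom(606, mu = 60, size = 5) + 1L, nrow = 101,
                dimnames = list(paste0("c", 1:101), paste0("s", 1:6)))
  expect_equal(unname(size_factors(mat)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 1e-10)
})

test_that("scaling one sample's counts scales its relative size factor exactly", {
  set.seed(33)
  m <- 4L
  mat <- matrix(sample(1:200, 15L * m, replace = TRUE), nrow = 15,
                dimnames = list(paste0("c", 1:15), paste0("s", 1:m)))
  sf0 <- size_factors(mat)
  mat2 <- mat; mat2[, 2] <- mat2[, 2] * 3L
  sf1 <- size_factors(mat2)
  # the geometric-mean reference moves with the scaled sample, so the raw
  # factor scales by c^(1 - 1/m) and every other factor by c^(-1/m);
  # factors relative to any fixed sample scale by exactly c
  expect_equal(unname(sf1[2] / sf0[2]), 3^(1 - 1 / m), tolerance = 1e-12)
  expect_equal(unname((sf1[2] / sf1[1]) / (sf0[2] / sf0[1])), 3,
               tolerance = 1e-12)
  expect_equal(unname(sf1[3] / sf0[3]), 3^(-1 / m), tolerance = 1e-12)
})

test_that("rows with zeros are excluded; all-zero-containing matrices error", {
  mat <- rbind(c(0L, 10L), c(5L, 0L))
  dimnames(mat) <- list(c("c1", "c2"), c("a", "b"))
  expect_error(size_factors(mat), "no row with all-positive")
})

test_that("normalization divides by factors and round-trips", {
  samples <- make_design()
  set.seed(34)
  mat <- random_count_matrix(10L, samples, max_count = 100L) + 1L
  sf <- size_factors(mat)
  norm <- normalize_counts(mat, sf)
  expect_equal(norm[, 1], mat[, 1] / sf[1])
  expect_equal(sweep(norm, 2, sf, "*"), mat + 0, ignore_attr = TRUE)
  expect_equal(normalize_counts(mat, setNames(rep(1, 32), colnames(mat))),
               mat + 0, ignore_attr = TRUE)
  small <- matrix(c(10L, 2L), ncol = 1, dimnames = list(c("c1", "c2"), "a"))
  expect_equal(unname(normalize_counts(small, c(a = 2))[1, 1]), 5)
  expect_error(normalize_counts(mat, sf[-1]), "missing size factor")
})

test_that("normalized columns of proportional samples are constant", {
  profile <- c(3, 10, 50, 7, 120)
  mat <- outer(profile, c(1, 2, 4))
  dimnames(mat) <- list(paste0("c", 1:5), paste0("s", 1:3))
  storage.mode(mat) <- "integer"
  norm <- normalize_counts(mat, size_factors(mat))
  expect_equal(norm[, 1], norm[, 2], ignore_attr = TRUE)
  expect_equal(norm[, 2], norm[, 3], ignore_attr = TRUE)
})

test_that("log2 fold change follows the closed form and is antisymmetric", {
  samples <- make_design()
  old <- samples$sample_id[samples$age_years == 20]
  young <- samples$sample_id[samples$age_years == 10]
  mat <- matrix(1, nrow = 3, ncol = 32,
                dimnames = list(paste0("c", 1:3), samples$sample_id))
  mat[2, old] <- 3; mat[2, young] <- 1        # log2((3+1)/(1+1)) = 1
  mat[3, old] <- 1; mat[3, young] <- 3
  res <- log2_fold_change(mat, samples, factor = "age")
  expect_equal(res$log2fc, c(0, 1, -1))
  expect_equal(as.character(res$direction), c("none", "20", "10"))
  counts <- attr(res, "direction_counts")
  expect_equal(unname(counts[c("10", "20", "none")]), c(1L, 1L, 1L),
               ignore_attr = TRUE)

  # swapping the group labelling negates the fold change
  flipped <- samples; flipped$age_years <- ifelse(samples$age_years == 10, 20L, 10L)
  res2 <- log2_fold_change(mat, flipped, factor = "age")
  expect_equal(res2$log2fc, -res$log2fc)
})
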