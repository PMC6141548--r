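# Welch tests, one-vs-rest spatial screen, group-biased screens,
# permutation null, set comparison.

test_that("two_group_t_test matches the Welch reference to 1e-12", {
  expect_equal(two_group_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               with(stats::t.test(c(1, 2, 3, 4), c(2, 3, 4, 5)),
                    list(t = unname(statistic), p = p.value)),
               tolerance = 1e-12)
  set.seed(91)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- two_group_t_test(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # paired route
  x <- rnorm(8); y <- rnorm(8)
  got <- two_group_t_test(x, y, paired = TRUE)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate variance cases are handled deterministically", {
  expect_equal(two_group_t_test(c(2, 2, 2), c(2, 2, 2)), list(t = 0, p = 1))
  expect_equal(two_group_t_test(c(5, 5, 5), c(2, 2, 2)), list(t = Inf, p = 0))
  expect_equal(two_group_t_test(c(1, 1), c(3, 3))$p, 0)
  expect_error(two_group_t_test(1, c(1, 2)), "n >= 2")
  expect_error(two_group_t_test(c(1, 2), c(1, 2, 3), paired = TRUE), "equal-length")
})

test_that("spatial screen calls a planted cerebellar circRNA and only one region", {
  samples <- make_design()
  set.seed(92)
  cb <- samples$region == "CB"
  mat <- matrix(rnorm(5 * 32, mean = 5, sd = 0.3), nrow = 5,
                dimnames = list(paste0("c", 1:5), samples$sample_id))
  mat[1, cb] <- rnorm(sum(cb), mean = 50, sd = 0.3)
  res <- spatial_specific(mat, samples, log2_transform = FALSE)
  called <- res[res$called, ]
  expect_true("c1" %in% called$circ_id)
  expect_equal(called$region[called$circ_id == "c1"], "CB")
  # at most one region per circRNA
  expect_lte(max(table(called$circ_id)), 1L)
  # flat rows: each is a null, called with probability about 8 * alpha / 2
  expect_lte(sum(called$circ_id %in% paste0("c", 2:5)), 1L)
})

test_that("vs_each calls are a subset of one_vs_rest calls", {
  samples <- make_design()
  set.seed(93)
  mat <- matrix(rnorm(200 * 32, 5), nrow = 200,
                dimnames = list(sprintf("c%03d", 1:200), samples$sample_id))
  mat[1:20, samples$region == "CB"] <- mat[1:20, samples$region == "CB"] + 3
  ovr <- spatial_specific(mat, samples, alpha = 0.05, log2_transform = FALSE)
  vse <- spatial_specific(mat, samples, alpha = 0.05, mode = "vs_each",
                          log2_transform = FALSE)
  called_ovr <- unique(ovr$circ_id[ovr$called])
  called_vse <- unique(vse$circ_id[vse$called])
  expect_true(all(called_vse %in% called_ovr))
  expect_gt(length(called_vse), 0L)
})

test_that("spatial screen validates the design", {
  samples <- make_design()[-c(1, 9, 17), ]     # leave PFC with one sample
  mat <- matrix(rnorm(2 * nrow(samples)), nrow = 2,
                dimnames = list(c("a", "b"), samples$sample_id))
  expect_error(spatial_specific(mat, samples, log2_transform = FALSE),
               ">= 2 samples")
})

test_that("group-biased screen matches row-wise two_group_t_test and calls planted rows", {
  samples <- make_design()
  set.seed(94)
  mat <- matrix(rnorm(50 * 32, 5), nrow = 50,
                dimnames = list(sprintf("c%02d", 1:50), samples$sample_id))
  male <- samples$sample_id[samples$sex == "M"]
  mat[1, colnames(mat) %in% male] <- mat[1, colnames(mat) %in% male] + 10
  res <- group_biased(mat, samples, factor = "sex", log2_transform = FALSE)
  expect_true(res$called[res$circ_id == "c01"])
  expect_equal(res$enriched_group[res$circ_id == "c01"], "M")
  for (i in c(1, 7, 23)) {
    ref <- two_group_t_test(mat[i, samples$sex == "F"], mat[i, samples$sex == "M"])
    expect_equal(res$t_stat[i], ref$t, tolerance = 1e-12)
    expect_equal(res$p_t[i], ref$p, tolerance = 1e-12)
  }
  single <- samples; single$sex <- "M"
  expect_error(group_biased(mat, single, factor = "sex"), "both levels")
})

test_that("null calling rate of the group screen is near alpha", {
  samples <- make_design()
  set.seed(95)
  mat <- matrix(rnorm(3000 * 32), nrow = 3000,
                dimnames = list(sprintf("c%04d", 1:3000), samples$sample_id))
  res <- group_biased(mat, samples, factor = "age", alpha = 0.05,
                      log2_transform = FALSE)
  frac <- mean(res$called)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("permutation p-values are exact for 3-vs-3 exhaustive enumeration", {
  sub <- make_design()[c(1:3, 17:19), ]        # 3 young vs 3 old samples
  set.seed(96)
  mat <- matrix(rnorm(40 * 6, 4), nrow = 40,
                dimnames = list(sprintf("c%02d", 1:40), sub$sample_id))
  mat[1, as.character(sub$age_years) == "20"] <- mat[1, as.character(sub$age_years) == "20"] + 5
  res <- permutation_test(mat, sub, factor = "age", exhaustive = TRUE,
                          log2_transform = FALSE)
  memb2 <- sub$age_years[match(colnames(mat), sub$sample_id)] == 20
  expect_equal(res$p_perm, oracle_exact_perm(mat, memb2), tolerance = 1e-12)
  # identity and its mirror split always tie in |stat|: the exact two-sided
  # permutation p-value is bounded below by 2 / C(6, 3)
  expect_equal(min(res$p_perm), 2 / choose(6, 3))
})

test_that("permutation test is seeded, bounded and degenerate-safe", {
  samples <- make_design()
  set.seed(97)
  mat <- matrix(rnorm(30 * 32), nrow = 30,
                dimnames = list(sprintf("c%02d", 1:30), samples$sample_id))
  mat[1, ] <- 7                                 # constant row -> p = 1
  r1 <- permutation_test(mat, samples, "sex", n_perm = 300, seed = 5,
                         log2_transform = FALSE)
  r2 <- permutation_test(mat, samples, "sex", n_perm = 300, seed = 5,
                         log2_transform = FALSE)
  expect_identical(r1, r2)
  expect_equal(r1$p_perm[1], 1)
  expect_true(all(r1$p_perm >= 1 / 301 & r1$p_perm <= 1))
  expect_error(permutation_test(mat, samples, "sex", n_perm = 0), "n_perm")
})

test_that("set comparison reports intersection and ratio over b", {
  cmp <- compare_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(cmp$intersection, 2L)
  expect_equal(cmp$overlap_ratio, 2 / 3)
  expect_equal(compare_sets(c("a"), c("b"))$intersection, 0L)
  expect_equal(compare_sets(c("a", "b"), c("b", "a"))$overlap_ratio, 1)
  expect_true(is.na(compare_sets("a", character(0))$overlap_ratio))
})
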