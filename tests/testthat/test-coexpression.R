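# Soft-threshold adjacency, TOM, module detection, eigengenes.

test_that("adjacency is |cor|^beta with the cubic default", {
  set.seed(61)
  mat <- matrix(rnorm(6 * 10), nrow = 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  mat[2, ] <- mat[1, ]                       # duplicated profile -> a = 1
  a <- adjacency(mat)
  expect_equal(a[1, 2], 1)
  expect_equal(attr(a, "soft_power"), 3L)
  expect_equal(unname(diag(a)), rep(0, 6))

  r <- cor(t(mat))
  expect_equal(a[3, 4], abs(r[3, 4])^3, tolerance = 1e-12)
  # closed form: correlation one-half gives 1/8
  x <- rnorm(50); e <- rnorm(50)
  expect_equal(abs(0.5)^3, 0.125)

  # brute-force element-wise oracle on a random instance
  set.seed(62)
  m2 <- matrix(rnorm(15 * 8), nrow = 15,
               dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
  a2 <- adjacency(m2)
  oracle <- abs(cor(t(m2)))^3; diag(oracle) <- 0
  expect_equal(a2, oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("adjacency rejects zero-variance rows and ignores affine rescaling", {
  mat <- rbind(g1 = rnorm(8), g2 = rep(3, 8))
  colnames(mat) <- paste0("s", 1:8)
  expect_error(adjacency(mat), "zero-variance.*g2")
  set.seed(63)
  m <- matrix(rnorm(5 * 8), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  m2 <- m; m2[3, ] <- 10 - 4 * m2[3, ]       # affine transform of one row
  expect_equal(adjacency(m), adjacency(m2), tolerance = 1e-12)
})

test_that("TOM matches the definition on hand-built and random networks", {
  # two nodes tied at a = 1 sharing identical unit-weight neighborhoods
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- 1
  a[1, 4] <- a[4, 1] <- a[2, 4] <- a[4, 2] <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1)                 # full topological overlap
  # no edge, no shared neighbours
  b <- matrix(0, 4, 4); b[3, 4] <- b[4, 3] <- 1
  expect_equal(tom_similarity(b)[1, 2], 0)

  set.seed(64)
  r <- matrix(runif(100), 10, 10); r <- (r + t(r)) / 2; diag(r) <- 0
  tomr <- tom_similarity(r)
  expect_equal(tomr, oracle_tom(r), tolerance = 1e-12)
  expect_equal(tomr, t(tomr))
  expect_true(all(tomr >= 0 & tomr <= 1))
  expect_equal(unname(diag(tomr)), rep(1, 10))

  r[1, 2] <- 0.9                             # break symmetry
  expect_error(tom_similarity(r), "symmetric")
})

test_that("planted blocks are recovered as modules; scattered rows go to module 0", {
  set.seed(65)
  pm <- planted_module_matrix(sizes = c(40L, 35L), n_samples = 30,
                              rho_w = 0.95)
  tom <- tom_similarity(adjacency(pm$mat))
  mod <- detect_modules(tom, min_module_size = 20L)
  expect_equal(sum(names(mod$sizes) != "0"), 2L)
  # labels ordered by decreasing size
  expect_gte(mod$sizes[["1"]], mod$sizes[["2"]])
  expect_equal(unname(mod$sizes[c("1", "2")]), c(40L, 35L), ignore_attr = TRUE)

  noise <- planted_module_matrix(sizes = integer(0), n_samples = 20, n_noise = 12L)
  tn <- tom_similarity(adjacency(noise$mat))
  modn <- detect_modules(tn, min_module_size = 20L)
  expect_true(all(modn$labels == 0L))
  expect_error(detect_modules(tom[1, 1, drop = FALSE]), ">= 2")
})

test_that("eigengenes are unit-norm first PCs with the positive-mean sign convention", {
  set.seed(66)
  profile <- rnorm(12)
  mat <- t(vapply(1:8, function(i) 2 * profile + i, numeric(12)))
  dimnames(mat) <- list(paste0("g", 1:8), paste0("s", 1:12))
  labels <- setNames(rep(1L, 8), rownames(mat))
  eg <- module_eigengene(mat, labels)
  e <- eg$eigengenes["ME1", ]
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  z <- (profile - mean(profile)) / sd(profile)
  expect_equal(unname(e), z / sqrt(sum(z^2)), tolerance = 1e-10)  # proportional to profile
  expect_equal(unname(eg$var_explained["ME1"]), 1, tolerance = 1e-12)

  # random module: agreement with an independent decomposition, sign convention
  m2 <- matrix(rnorm(10 * 12), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  lab2 <- setNames(rep(1L, 10), rownames(m2))
  eg2 <- module_eigengene(m2, lab2)
  z2 <- t(scale(t(m2)))
  pc <- prcomp(t(z2), center = FALSE, scale. = FALSE)
  ref <- pc$x[, 1] / sqrt(sum(pc$x[, 1]^2))
  got <- eg2$eigengenes["ME1", ]
  expect_equal(abs(unname(got)), abs(unname(ref)), tolerance = 1e-10)
  expect_gt(sum(got * colMeans(z2)), 0)      # sign: positive mean-profile correlation
  expect_gt(eg2$var_explained["ME1"], 0)
  expect_lte(eg2$var_explained["ME1"], 1)

  flat <- rbind(g1 = rep(2, 6), g2 = rnorm(6))
  colnames(flat) <- paste0("s", 1:6)
  expect_error(module_eigengene(flat, setNames(c(1L, 1L), rownames(flat))),
               "zero-variance")
})
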