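test_that("size factors match analytic cases and the brute-force oracle", {
  m <- matrix(c(2L, 4L, 2L, 4L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(median_of_ratios_size_factors(m)), c(1, 1))

  m2 <- matrix(c(2L, 4L, 4L, 8L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(median_of_ratios_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))

  set.seed(13)
  m3 <- matrix(rnbinom(306, mu = 40, size = 2) + 1L, 51, 6,
               dimnames = list(sprintf("g%d", 1:51), sprintf("s%d", 1:6)))
  expect_equal(unname(median_of_ratios_size_factors(m3)),
               unname(size_factor_oracle(m3)))

  # invariance to gene order; equivariance to scaling one sample
  perm <- sample(51)
  expect_equal(median_of_ratios_size_factors(m3[perm, ]),
               median_of_ratios_size_factors(m3))
  m4 <- m3
  m4[, 3] <- m4[, 3] * 3L
  sf3 <- median_of_ratios_size_factors(m3)
  sf4 <- median_of_ratios_size_factors(m4)
  expect_equal(unname((sf4 / sf3)[3] / exp(mean(log(sf4 / sf3)))), 3 / 3^(1 / 6),
               tolerance = 1e-10)
})

test_that("size factors agree with the DESeq2 reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- matrix(rnbinom(80 * 8, mu = 60, size = 3) + 1L, 80, 8,
              dimnames = list(sprintf("g%d", 1:80), sprintf("s%d", 1:8)))
  ours <- median_of_ratios_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("size factors fail informatively without a common reference gene", {
  m <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(median_of_ratios_size_factors(m), "pseudo_reference")
  expect_silent(sf <- median_of_ratios_size_factors(m, pseudo_reference = TRUE))
  expect_true(all(sf > 0))
})

test_that("vst maps zero to zero, is monotone, and hits the small-phi limit", {
  m <- matrix(c(0L, 1L, 5L, 100L), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  sf <- c(s1 = 1)
  v <- vst_transform(m, sf, phi_common = 0.3)
  expect_identical(v[1, 1], 0)
  expect_true(all(diff(v[, 1]) > 0))

  v_small <- vst_transform(m, sf, phi_common = 1e-8)
  expect_equal(v_small[, 1], 2 * sqrt(m[, 1]) / log(2), tolerance = 1e-3)
  expect_error(vst_transform(m, sf, phi_common = -1), "positive")
})

test_that("vst flattens the NB mean-variance relationship", {
  set.seed(77)
  mus <- 10^seq(1, 4, length.out = 12)
  counts <- t(vapply(mus, function(mu) rnbinom(400, mu = mu, size = 10),
                     numeric(400)))
  dimnames(counts) <- list(sprintf("g%02d", seq_along(mus)), sprintf("s%03d", 1:400))
  storage.mode(counts) <- "integer"
  v <- vst_transform(counts, sf = setNames(rep(1, 400), colnames(counts)),
                     phi_common = 0.1)
  vars <- apply(v, 1, var)
  expect_lt(max(vars) / min(vars), 2)
  # raw counts for contrast: variance spans orders of magnitude
  expect_gt(max(apply(counts, 1, var)) / min(apply(counts, 1, var)), 100)
})

test_that("residualization removes exactly the nuisance structure", {
  set.seed(3)
  n <- 24
  samples <- toy_samples(sprintf("s%02d", 1:n),
                         nas = rep(0:7, 3), fibrosis = rep(0:3, 6),
                         batch = rep(c("b1", "b2", "b3"), each = 8))
  # single batch: nothing to remove
  s1 <- samples
  s1$batch <- "b1"
  expr <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(paste0("g", 1:5), samples$sample_id))
  expect_identical(residualize_covariates(expr, s1, remove = "batch"), expr)

  # planted additive batch offsets only: removed to numerical zero
  off <- c(b1 = 0, b2 = 1.5, b3 = -0.7)
  expr2 <- matrix(5, 3, n, dimnames = list(paste0("g", 1:3), samples$sample_id)) +
    matrix(off[samples$batch], 3, n, byrow = TRUE)
  adj <- residualize_covariates(expr2, samples, remove = "batch")
  for (b in unique(samples$batch))
    expect_lt(max(abs(rowMeans(adj[, samples$batch == b]) - rowMeans(adj))), 1e-9)

  # planted batch + NAS effects: keep covariate structure survives exactly
  expr3 <- matrix(2, 2, n, dimnames = list(c("gA", "gB"), samples$sample_id)) +
    rbind(0.5 * samples$nas, -0.3 * samples$nas) +
    matrix(off[samples$batch], 2, n, byrow = TRUE)
  adj3 <- residualize_covariates(expr3, samples, remove = "batch", keep = "nas")
  slopeA <- coef(lm(adj3["gA", ] ~ samples$nas))[2]
  slopeB <- coef(lm(adj3["gB", ] ~ samples$nas))[2]
  expect_equal(unname(slopeA), 0.5, tolerance = 1e-6)
  expect_equal(unname(slopeB), -0.3, tolerance = 1e-6)

  # idempotence
  twice <- residualize_covariates(adj3, samples, remove = "batch", keep = "nas")
  expect_equal(twice, adj3, tolerance = 1e-9)
})

test_that("residualization names aliased columns on rank-deficient designs", {
  n <- 12
  samples <- toy_samples(sprintf("s%02d", 1:n), nas = rep(0:5, 2),
                         fibrosis = rep(0:1, 6),
                         batch = rep(c("b1", "b2"), each = 6),
                         sex = rep(c("F", "M"), each = 6))  # sex aliased with batch
  expr <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("g1", "g2"), samples$sample_id))
  expect_error(residualize_covariates(expr, samples, remove = c("batch", "sex")),
               "aliased")
})
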