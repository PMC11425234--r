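make_design <- function(samples) {
  cbind("(Intercept)" = 1, nas = as.numeric(samples$nas),
        fibrosis = as.numeric(samples$fibrosis))
}

test_that("constant and degenerate genes are handled without error", {
  n <- 30
  samples <- toy_samples(sprintf("s%02d", 1:n), nas = rep(0:5, 5),
                         fibrosis = rep(0:2, 10))
  X <- make_design(samples)
  sf <- setNames(rep(1, n), samples$sample_id)

  fit <- fit_gene_model(rep(16L, n), X, sf)
  expect_equal(unname(fit$beta[["nas"]]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$beta[["fibrosis"]]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$beta[["(Intercept)"]]), log2(16), tolerance = 1e-6)

  fit0 <- fit_gene_model(rep(0L, n), X, sf)
  expect_true(is.na(fit0$converged))
  expect_true(all(is.na(fit0$beta)))
})

test_that("a planted doubling per covariate unit is recovered as beta = 1 log2", {
  nas <- rep(0:5, each = 4)
  samples <- toy_samples(sprintf("s%02d", seq_along(nas)), nas = nas,
                         fibrosis = rep(0:1, 12))
  X <- cbind("(Intercept)" = 1, nas = as.numeric(nas))
  y <- as.integer(2^(3 + nas))  # exact doubling, noiseless
  fit <- fit_gene_model(y, X, setNames(rep(1, length(y)), samples$sample_id))
  expect_equal(unname(fit$beta[["nas"]]), 1, tolerance = 1e-4)
})

test_that("the NB fit agrees with an independent joint-MLE oracle", {
  set.seed(60)
  n <- 80
  nas <- sample(0:8, n, replace = TRUE)
  X <- cbind("(Intercept)" = 1, nas = as.numeric(nas))
  sf <- exp(rnorm(n, 0, 0.2))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- sprintf("s%02d", 1:n)
  for (g in 1:5) {
    mu <- 2^(4 + 0.25 * nas) * sf
    y <- rnbinom(n, mu = mu, size = 1 / 0.15)
    fit <- fit_gene_model(y, X, sf)
    # generic-optimizer joint ML over (beta, log phi)
    negll <- function(par) {
      eta <- X %*% par[1:2] + log(sf)
      m <- exp(eta)
      phi <- exp(par[3])
      -sum(lgamma(y + 1 / phi) - lgamma(1 / phi) - lfactorial(y) +
             y * log(phi * m) - (y + 1 / phi) * log1p(phi * m))
    }
    ora <- optim(c(log(16), 0.17, log(0.1)), negll, method = "BFGS")
    expect_equal(unname(fit$beta[["nas"]]), ora$par[2] / log(2), tolerance = 0.01)
    expect_equal(fit$phi, exp(ora$par[3]), tolerance = 0.15)
  }
})

test_that("the NB fit matches MASS::glm.nb on well-behaved genes", {
  skip_if_not_installed("MASS")
  set.seed(61)
  n <- 100
  nas <- sample(0:8, n, replace = TRUE)
  fib <- pmin(4, pmax(0, round(nas / 2 + rnorm(n, 0, 0.5))))
  X <- cbind("(Intercept)" = 1, nas = as.numeric(nas), fibrosis = as.numeric(fib))
  sf <- setNames(rep(1, n), sprintf("s%03d", 1:n))
  mu <- 2^(5 + 0.3 * nas)
  y <- rnbinom(n, mu = mu, size = 1 / 0.1)
  fit <- fit_gene_model(y, X, sf)
  ref <- MASS::glm.nb(y ~ nas + fib)
  expect_equal(unname(fit$beta[["nas"]]), unname(coef(ref)["nas"]) / log(2),
               tolerance = 0.01)
  expect_equal(fit$phi, 1 / ref$theta, tolerance = 0.1)
})

test_that("Wald statistics follow the normal quantile identities", {
  fit <- structure(list(beta = c(nas = 0), se = c(nas = 0.2), converged = TRUE),
                   class = "gene_fit")
  w <- wald_test(fit, "nas")
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)
  fit$beta <- c(nas = 1.959964 * 0.2)
  expect_equal(wald_test(fit, "nas")$p, 0.05, tolerance = 1e-6)
  fit$se <- c(nas = 0)
  expect_true(is.na(wald_test(fit, "nas")$p))
})

test_that("BH adjustment matches hand calculations and the sort-cummin oracle", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
  # permutation invariance + NA passthrough
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  p[c(2, 9)] <- NA
  adj <- adjust_bh(p)
  expect_true(all(is.na(adj[c(2, 9)])))
  expect_equal(adj[-c(2, 9)], bh_oracle(p[-c(2, 9)]))
})

test_that("the severity DEG rule matches exhaustive manual evaluation", {
  de <- data.frame(
    gene_id = paste0("g", 1:8),
    beta_nas = c(0.15, 0.15, 0.05, -0.3, -0.05, 0.3, 0.15, 0.05),
    padj_nas = c(0.01, 0.5, 0.01, 0.01, 0.01, 0.2, 0.01, 0.5),
    beta_fib = c(0, 0.05, 0.05, 0, 0.3, 0.25, -0.3, -0.25),
    padj_fib = c(0.5, 0.5, 0.5, 0.5, 0.01, 0.01, 0.01, 0.01))
  out <- call_severity_degs(de)
  # manual: g1 up(nas); g2 none; g3 none; g4 down(nas); g5 up(fib);
  # g6 up(fib only; nas not significant); g7 up-by-nas but down-by-fib ->
  # ambiguous; g8 down(fib)
  expect_identical(out$deg_call,
                   c("up", "none", "none", "down", "up", "up", "ambiguous", "down"))
  # monotone in |beta|: inflating a qualifying beta never revokes the call
  de2 <- de
  de2$beta_nas[1] <- 5
  expect_identical(call_severity_degs(de2)$deg_call[1], "up")
})

test_that("pattern clustering separates the three planted profiles", {
  cfg <- gen_config(n_genes = 90, n_cohorts = 1, samples_per_cohort = 120,
                    frac_severity_genes = 1,
                    cluster_mix = c(1 / 3, 1 / 3, 1 / 3),
                    beta_nas_range = c(0.4, 0.5), beta_fib_range = c(0.2, 0.3),
                    batch_sd = 0, sex_effect_sd = 0,
                    dispersion_params = c(location = log(0.01), scale = 0),
                    seed = 91)
  h <- generate_human_cohorts(cfg)
  v <- vst_transform(h$counts, truth_size_factors(h))
  labels <- cluster_deg_patterns(v, h$samples, k = 3)
  truth <- h$truth$genes$cluster
  purity <- sum(apply(table(truth, labels), 2, max)) / length(labels)
  expect_equal(purity, 1.0)

  # k = 1 collapses to a single cluster; duplicates co-cluster
  expect_true(all(cluster_deg_patterns(v, h$samples, k = 1) == 1))
  dup <- v[c(1, 1, 2, 2, 3, 3), ]
  rownames(dup) <- paste0("d", 1:6)
  ld <- cluster_deg_patterns(dup, h$samples, k = 3)
  expect_identical(unname(ld[1]), unname(ld[2]))
  expect_identical(unname(ld[3]), unname(ld[4]))
  expect_error(cluster_deg_patterns(v[1:2, ], h$samples, k = 3), "fewer genes")
})

test_that("two-group mouse DE detects planted fold changes and controls the null", {
  set.seed(14)
  n_g <- 150
  mu <- exp(rnorm(n_g, 4, 1))
  grp <- rep(c("ctrl", "trt"), each = 6)
  mk <- function(fc) {
    m <- cbind(matrix(rnbinom(n_g * 6, mu = mu, size = 20), n_g),
               matrix(rnbinom(n_g * 6, mu = mu * fc, size = 20), n_g))
    dimnames(m) <- list(sprintf("g%03d", 1:n_g), sprintf("s%02d", 1:12))
    storage.mode(m) <- "integer"
    m
  }
  # null: planted fold change 1 everywhere -> about alpha*m raw positives at most
  null <- two_group_mouse_degs(mk(1), grp)
  expect_lte(sum(null$deg_call != "none"), 3)
  # planted 4-fold gene
  m4 <- mk(1)
  m4[1, 7:12] <- as.integer(rnbinom(6, mu = mu[1] * 4, size = 20))
  out <- two_group_mouse_degs(m4, grp)
  expect_identical(out$deg_call[1], "up")
  expect_error(two_group_mouse_degs(mk(1), rep("ctrl", 12)), "two groups")
  expect_error(two_group_mouse_degs(mk(1), c(rep("ctrl", 11), "trt")), ">= 2")
})
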