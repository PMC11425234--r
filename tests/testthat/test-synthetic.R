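test_that("severity pairs stay on scale and correlate as designed", {
  expect_error(sample_severity_pair(0), "n must be")
  sp <- sample_severity_pair(10000, seed = 1)
  expect_true(all(sp$nas %in% 0:8))
  expect_true(all(sp$fibrosis %in% 0:4))
  rho <- cor(sp$nas, sp$fibrosis, method = "spearman")
  expect_gte(rho, 0.7)
  expect_lte(rho, 0.95)
  # the fibrosis rule clamps: NAS 0 with eps 0 gives 0, NAS 8 with eps +3 gives 4
  clamp <- function(nas, eps) pmin(pmax(round(nas / 2 + eps), 0), 4)
  expect_identical(clamp(0, 0), 0)
  expect_identical(clamp(8, 3), 4)
  expect_identical(sample_severity_pair(50, seed = 7), sample_severity_pair(50, seed = 7))
})

test_that("null configuration yields exchangeable cohorts with zero truth", {
  cfg <- gen_config(n_genes = 100, n_cohorts = 1, samples_per_cohort = 20,
                    frac_severity_genes = 0, batch_sd = 0, sex_effect_sd = 0,
                    seed = 5)
  h <- generate_human_cohorts(cfg)
  expect_true(all(h$truth$genes$beta_nas == 0))
  expect_true(all(h$truth$genes$beta_fib == 0))
  expect_true(all(h$truth$genes$cluster == "none"))
  expect_true(all(h$truth$batch_offsets == 0))
})

test_that("generation is deterministic and truth is complete and consistent", {
  cfg <- gen_config(n_genes = 150, n_cohorts = 2, samples_per_cohort = 15, seed = 33)
  a <- generate_human_cohorts(cfg)
  b <- generate_human_cohorts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)

  tg <- a$truth$genes
  # cluster labels partition genes; signs match labels
  expect_true(all(tg$beta_nas[tg$cluster == "down"] < 0))
  expect_true(all(tg$beta_nas[tg$cluster == "up"] > 0))
  expect_true(all(tg$beta_nas[tg$cluster == "up_then_down"] > 0))
  expect_true(all(tg$beta_nas[tg$cluster == "none"] == 0))
  expect_true(all(tg$beta_fib[tg$cluster == "none"] == 0))
  expect_true(all(tg$phi > 0))
  validate_counts(a$counts)
  validate_sample_table(a$samples, a$counts)
})

test_that("dispersion near zero approaches the Poisson mean-variance limit", {
  cfg <- gen_config(n_genes = 40, n_cohorts = 1, samples_per_cohort = 500,
                    frac_severity_genes = 0, batch_sd = 0, sex_effect_sd = 0,
                    baseline_logmean_params = c(location = 6, scale = 0.5),
                    dispersion_params = c(location = log(1e-8), scale = 0),
                    libsize_params = c(location = 0, scale = 0), seed = 21)
  h <- generate_human_cohorts(cfg)
  # identical covariates per sample are not guaranteed, but with zero betas
  # every sample is exchangeable: variance ~ mean per gene
  m <- rowMeans(h$counts)
  v <- apply(h$counts, 1, var)
  expect_true(all(abs(v / m - 1) < 0.35))
})

test_that("NB moments match the planted dispersion within tolerance", {
  cfg <- gen_config(n_genes = 30, n_cohorts = 1, samples_per_cohort = 500,
                    frac_severity_genes = 0, batch_sd = 0, sex_effect_sd = 0,
                    baseline_logmean_params = c(location = 7, scale = 0.3),
                    dispersion_params = c(location = log(0.2), scale = 0),
                    libsize_params = c(location = 0, scale = 0), seed = 8)
  h <- generate_human_cohorts(cfg)
  m <- rowMeans(h$counts)
  v <- apply(h$counts, 1, var)
  expected <- m + 0.2 * m^2
  expect_true(mean(abs(v / expected - 1) < 0.2) > 0.8)
})

test_that("mouse time-course inherits ortholog-linked effects and rises with time", {
  cfg <- gen_config(n_genes = 200, n_cohorts = 1, samples_per_cohort = 30, seed = 0)
  h <- generate_human_cohorts(cfg)
  orth <- synthetic_ortholog_map(rownames(h$counts), frac_mapped = 0.8, seed = 1)
  mouse <- generate_mouse_timecourse(cfg, orth, h$truth, n_per_timepoint = 6)

  tg <- mouse$truth$genes
  ht <- h$truth$genes
  inh <- tg[tg$inherited, ]
  expect_gt(nrow(inh), 0)
  expect_identical(inh$beta_nas,
                   ht$beta_nas[match(inh$human_gene, ht$gene_id)])
  # mean expression of monotone-up signature genes strictly increases with time
  up_mouse <- tg$gene_id[tg$cluster == "up"]
  lib <- mouse$truth$samples$libsize
  norm <- sweep(mouse$counts[up_mouse, , drop = FALSE], 2, lib, "/")
  tp <- mouse$truth$samples$timepoint
  prof <- vapply(sort(unique(tp)), function(w)
    mean(log1p(norm[, tp == w, drop = FALSE])), numeric(1))
  expect_true(all(diff(prof) > 0))
})

test_that("mouse generator handles degenerate ortholog maps", {
  cfg <- gen_config(n_genes = 50, n_cohorts = 1, samples_per_cohort = 20, seed = 2)
  h <- generate_human_cohorts(cfg)
  expect_error(generate_mouse_timecourse(cfg, NULL, h$truth), "empty")
  sev_gene <- h$truth$genes$gene_id[h$truth$genes$cluster != "none"][1]
  one <- ortholog_map(sev_gene, "mgX")
  mouse <- generate_mouse_timecourse(cfg, one, h$truth, n_background = 30)
  expect_identical(sum(mouse$truth$genes$inherited), 1L)
  expect_identical(nrow(mouse$counts), 31L)

  # identical planted severity at two timepoints: same expected expression
  flat <- generate_mouse_timecourse(cfg, one, h$truth, timepoints = c(4, 8),
                                    severity_nas = c(3, 3),
                                    n_per_timepoint = 50, n_background = 10)
  tp <- flat$truth$samples$timepoint
  m1 <- mean(flat$counts["mgX", tp == 4])
  m2 <- mean(flat$counts["mgX", tp == 8])
  expect_lt(abs(log2(m1 / m2)), 0.5)
})
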