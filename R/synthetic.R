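# Synthetic multi-cohort generator. Emulates the statistical structure the
# staging meta-analysis assumes: negative-binomial counts whose log2 means
# shift per unit of NAS and fibrosis, nuisance batch and sex effects, and a
# mouse time-course whose ortholog-linked genes carry increasing planted
# severity. Every planted value is recorded in a ground-truth object.

#' Generator configuration
#'
#' Parameters of the synthetic human-cohort generator. Effects are specified
#' in log2 units throughout so planted values are directly comparable to the
#' DEG-calling thresholds (log2 fold change per unit of NAS or fibrosis).
#'
#' Defaults describe the study conditions the package is validated under:
#' two cohorts of 75 liver samples (306 samples across four cohorts in the
#' motivating human meta-analysis; two cohorts keep the batch term exercised
#' at desk scale), 2000 genes of which 15% carry severity effects split into
#' the three recurrent progression patterns (monotone-down, monotone-up, and
#' early-up genes whose expression subsides in late fibrosis), per-NAS-unit
#' effects of 0.15-0.40 log2 and per-fibrosis-unit effects of 0.20-0.50 log2,
#' moderate batch (SD 0.3 log2) and sex (SD 0.2 log2) nuisance effects, and
#' log-normal baselines, dispersions and library sizes typical of bulk liver
#' RNA-seq.
#'
#' @param n_genes Number of genes.
#' @param n_cohorts Number of human cohorts (batches).
#' @param samples_per_cohort Samples per cohort: a single count, or one count
#'   per cohort (so a smaller held-out cohort can share one generator run,
#'   and hence one set of planted gene effects, with the training cohorts).
#' @param frac_severity_genes Fraction of genes carrying severity effects.
#' @param cluster_mix Three fractions summing to 1: proportion of severity
#'   genes that are monotone-down, monotone-up, and up-then-down.
#' @param beta_nas_range Interval for |log2 change per NAS unit| of severity
#'   genes.
#' @param beta_fib_range Interval for |log2 change per fibrosis-stage unit|.
#' @param batch_sd SD (log2 units) of per-gene, per-cohort batch offsets
#'   (first cohort is the reference with offset 0).
#' @param sex_effect_sd SD (log2 units) of per-gene sex effects.
#' @param baseline_logmean_params `c(location, scale)` of the per-gene
#'   baseline log2 mean (normal on the log2 scale, i.e. log-normal mean).
#' @param dispersion_params `c(location, scale)` of the per-gene NB
#'   dispersion on the natural-log scale (log-normal phi).
#' @param libsize_params `c(location, scale)` of the per-sample library-size
#'   factor on the natural-log scale (log-normal, geometric mean ~1).
#' @param seed Integer seed; identical configurations generate identical data.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(n_genes = 2000L,
                       n_cohorts = 2L,
                       samples_per_cohort = 75L,
                       frac_severity_genes = 0.15,
                       cluster_mix = c(down = 0.40, up = 0.45, up_then_down = 0.15),
                       beta_nas_range = c(0.15, 0.40),
                       beta_fib_range = c(0.20, 0.50),
                       batch_sd = 0.3,
                       sex_effect_sd = 0.2,
                       baseline_logmean_params = c(location = 5, scale = 1.5),
                       dispersion_params = c(location = log(0.05), scale = 0.5),
                       libsize_params = c(location = 0, scale = 0.2),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              frac_severity_genes = frac_severity_genes,
              cluster_mix = cluster_mix,
              beta_nas_range = beta_nas_range,
              beta_fib_range = beta_fib_range,
              batch_sd = batch_sd,
              sex_effect_sd = sex_effect_sd,
              baseline_logmean_params = baseline_logmean_params,
              dispersion_params = dispersion_params,
              libsize_params = libsize_params,
              seed = as.integer(seed))
  if (!length(cfg$samples_per_cohort) %in% c(1L, cfg$n_cohorts))
    stop("samples_per_cohort must have length 1 or n_cohorts")
  if (cfg$n_genes < 1L || cfg$n_cohorts < 1L || any(cfg$samples_per_cohort < 1L))
    stop("n_genes, n_cohorts and samples_per_cohort must all be >= 1")
  if (cfg$frac_severity_genes < 0 || cfg$frac_severity_genes > 1)
    stop("frac_severity_genes must be in [0, 1]")
  if (length(cfg$cluster_mix) != 3L || any(cfg$cluster_mix < 0) ||
      abs(sum(cfg$cluster_mix) - 1) > 1e-9)
    stop("cluster_mix must be three non-negative fractions summing to 1")
  if (cfg$batch_sd < 0 || cfg$sex_effect_sd < 0)
    stop("batch_sd and sex_effect_sd must be non-negative")
  if (length(cfg$beta_nas_range) != 2L || length(cfg$beta_fib_range) != 2L ||
      cfg$beta_nas_range[1L] > cfg$beta_nas_range[2L] ||
      cfg$beta_fib_range[1L] > cfg$beta_fib_range[2L])
    stop("beta ranges must be ordered intervals")
  class(cfg) <- "gen_config"
  cfg
}

#' Sample correlated NAS / fibrosis severity pairs
#'
#' NAS (0-8) is drawn uniformly over its scale; the fibrosis stage is a noisy
#' deterministic function of NAS, `clamp(round(NAS/2 + eps), 0, 4)` with
#' `eps ~ Normal(0, 0.5)`, mimicking the clinical correlation between the two
#' ordinal severity scores.
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @return List with integer vectors `nas` (0-8) and `fibrosis` (0-4).
#' @export
sample_severity_pair <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  set.seed(seed)
  r_severity_pair(as.integer(n))
}

# RNG-stream version used inside the generators (no set.seed).
r_severity_pair <- function(n) {
  nas <- sample(0:8, n, replace = TRUE)
  eps <- rnorm(n, 0, 0.5)
  fibrosis <- pmin(pmax(as.integer(round(nas / 2 + eps)), 0L), 4L)
  list(nas = as.integer(nas), fibrosis = fibrosis)
}

# Per-gene effective NAS profile: up-then-down genes reverse slope above NAS 5.
nas_effect_design <- function(nas, up_then_down) {
  if (up_then_down) pmin(nas, 5) - pmax(nas - 5, 0) else nas
}

#' Generate synthetic human cohorts with known ground truth
#'
#' Counts for gene g in sample j are negative-binomial with
#' `log2 mean = baseline_g + beta_nas_g * NAS_j + beta_fib_g * fibrosis_j +
#' batch_offset + sex_effect_g * sex_j + log2(libsize_j)` and per-gene
#' dispersion `phi_g`. Up-then-down genes use a piecewise NAS slope that
#' reverses sign above NAS 5 (their fibrosis effect is 0: these genes rise in
#' early disease and subside in the late fibrotic stage). All planted values
#' are recorded in the returned ground truth; the output is deterministic
#' under `cfg$seed`.
#'
#' @param cfg A [gen_config()] object.
#' @return List with elements `counts` (integer matrix), `samples` (sample
#'   metadata data frame) and `truth` (list with `genes`, `samples`, and
#'   `batch_offsets` components holding every planted value).
#' @export
generate_human_cohorts <- function(cfg) {
  if (!inherits(cfg, "gen_config")) cfg <- do.call(gen_config, cfg)
  set.seed(cfg$seed)
  n_g <- cfg$n_genes
  spc <- rep_len(cfg$samples_per_cohort, cfg$n_cohorts)
  n_s <- sum(spc)
  genes <- sprintf("HG%05d", seq_len(n_g))

  # planted per-gene truth
  n_sev <- round(cfg$frac_severity_genes * n_g)
  cluster <- rep("none", n_g)
  if (n_sev > 0L) {
    sev_idx <- sort(sample.int(n_g, n_sev))
    n_down <- round(cfg$cluster_mix[1L] * n_sev)
    n_up <- round(cfg$cluster_mix[2L] * n_sev)
    n_utd <- n_sev - n_down - n_up
    lab <- sample(rep(c("down", "up", "up_then_down"), c(n_down, n_up, n_utd)))
    cluster[sev_idx] <- lab
  }
  beta_nas <- numeric(n_g)
  beta_fib <- numeric(n_g)
  is_down <- cluster == "down"
  is_up <- cluster == "up"
  is_utd <- cluster == "up_then_down"
  beta_nas[is_down] <- -runif(sum(is_down), cfg$beta_nas_range[1L], cfg$beta_nas_range[2L])
  beta_fib[is_down] <- -runif(sum(is_down), cfg$beta_fib_range[1L], cfg$beta_fib_range[2L])
  beta_nas[is_up] <- runif(sum(is_up), cfg$beta_nas_range[1L], cfg$beta_nas_range[2L])
  beta_fib[is_up] <- runif(sum(is_up), cfg$beta_fib_range[1L], cfg$beta_fib_range[2L])
  beta_nas[is_utd] <- runif(sum(is_utd), cfg$beta_nas_range[1L], cfg$beta_nas_range[2L])
  # up_then_down genes: fibrosis marks late disease, where these genes subside

  baseline <- rnorm(n_g, cfg$baseline_logmean_params[1L], cfg$baseline_logmean_params[2L])
  phi <- exp(rnorm(n_g, cfg$dispersion_params[1L], cfg$dispersion_params[2L]))
  sex_effect <- rnorm(n_g, 0, cfg$sex_effect_sd)
  batch_offsets <- matrix(0, n_g, cfg$n_cohorts,
                          dimnames = list(genes, paste0("cohort", seq_len(cfg$n_cohorts))))
  if (cfg$n_cohorts > 1L)
    batch_offsets[, -1L] <- rnorm(n_g * (cfg$n_cohorts - 1L), 0, cfg$batch_sd)

  # per-sample covariates
  cohort <- rep(paste0("cohort", seq_len(cfg$n_cohorts)), times = spc)
  sev <- r_severity_pair(n_s)
  sex <- sample(c(0L, 1L), n_s, replace = TRUE)
  libsize <- exp(rnorm(n_s, cfg$libsize_params[1L], cfg$libsize_params[2L]))
  sample_ids <- sprintf("%s_S%03d", cohort,
                        unlist(lapply(spc, seq_len)))

  # log2 mean matrix
  nas_lin <- outer(beta_nas, sev$nas)
  if (any(is_utd)) {
    nas_eff <- nas_effect_design(sev$nas, up_then_down = TRUE)
    nas_lin[is_utd, ] <- outer(beta_nas[is_utd], nas_eff)
  }
  log2mu <- baseline + nas_lin + outer(beta_fib, sev$fibrosis) +
    batch_offsets[, match(cohort, colnames(batch_offsets)), drop = FALSE] +
    outer(sex_effect, sex) +
    matrix(log2(libsize), n_g, n_s, byrow = TRUE)
  mu <- 2^pmin(log2mu, 30)  # guard against overflow in extreme tails

  counts <- matrix(rnbinom(n_g * n_s, mu = as.vector(mu), size = rep(1 / phi, n_s)),
                   nrow = n_g, dimnames = list(genes, sample_ids))
  storage.mode(counts) <- "integer"

  samples <- data.frame(sample_id = sample_ids,
                        batch = cohort,
                        sex = c("F", "M")[sex + 1L],
                        species = "human",
                        nas = sev$nas,
                        fibrosis = sev$fibrosis,
                        group = NA_character_,
                        stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(gene_id = genes, cluster = cluster,
                       beta_nas = beta_nas, beta_fib = beta_fib,
                       phi = phi, baseline = baseline, sex_effect = sex_effect,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids, batch = cohort, sex = sex,
                         nas = sev$nas, fibrosis = sev$fibrosis,
                         libsize = libsize, stringsAsFactors = FALSE),
    batch_offsets = batch_offsets)
  list(counts = counts, samples = samples, truth = truth)
}

#' Build a synthetic human-mouse ortholog table
#'
#' Maps a fraction of the human genes one-to-one onto synthetic mouse symbols
#' (`HGxxxxx` -> `mgxxxxx`).
#'
#' @param human_genes Character vector of human gene identifiers.
#' @param frac_mapped Fraction of genes with a mouse ortholog.
#' @param seed Integer seed.
#' @return Ortholog map data frame (see [ortholog_map()]).
#' @export
synthetic_ortholog_map <- function(human_genes, frac_mapped = 0.85, seed = 1L) {
  set.seed(seed)
  n <- max(1L, round(frac_mapped * length(human_genes)))
  mapped <- sort(sample(human_genes, n))
  ortholog_map(mapped, sub("^HG", "mg", mapped))
}

#' Generate a synthetic mouse time-course inheriting human severity effects
#'
#' Mouse genes orthologous to human severity genes inherit the human planted
#' effect (direction and magnitude); planted severity increases with
#' timepoint, emulating progressive diet-induced liver disease. Non-ortholog
#' background genes carry no severity effect. Group labels are
#' `week<timepoint>`; histology scores in the sample table are `NA` (mice are
#' ungraded), the planted severity lives in the ground truth.
#'
#' @param cfg A [gen_config()] object (baseline/dispersion/library-size
#'   parameters and the seed are reused; a distinct RNG stream is derived).
#' @param orth Ortholog map (human_gene, mouse_gene).
#' @param human_truth `truth` component of [generate_human_cohorts()] output.
#' @param timepoints Numeric vector of weeks on diet; the first is the control
#'   timepoint.
#' @param n_per_timepoint Mice per timepoint.
#' @param severity_nas Planted NAS per timepoint; defaults to an even ramp
#'   from 0 to 8 across the timepoints.
#' @param n_background Number of mouse-only background genes without human
#'   orthologs.
#' @return List with `counts`, `samples`, `truth` as for
#'   [generate_human_cohorts()].
#' @export
generate_mouse_timecourse <- function(cfg, orth, human_truth,
                                      timepoints = c(0, 4, 8, 12, 16),
                                      n_per_timepoint = 4L,
                                      severity_nas = NULL,
                                      n_background = 200L) {
  if (!inherits(cfg, "gen_config")) cfg <- do.call(gen_config, cfg)
  if (is.null(orth) || nrow(orth) == 0L)
    stop("ortholog map is empty")
  ht <- human_truth$genes
  keep <- orth$human_gene %in% ht$gene_id
  orth <- orth[keep, , drop = FALSE]
  if (nrow(orth) == 0L)
    stop("ortholog map links no gene present in the human ground truth")
  set.seed((cfg$seed + 104729L) %% 2147483647L)

  # inherited genes: one row per mouse gene; fan-in resolved to the first
  # human partner in sorted order
  orth <- orth[order(orth$mouse_gene, orth$human_gene), , drop = FALSE]
  orth <- orth[!duplicated(orth$mouse_gene), , drop = FALSE]
  idx <- match(orth$human_gene, ht$gene_id)
  mouse_genes <- orth$mouse_gene
  n_bg <- as.integer(n_background)
  bg_genes <- sprintf("mBG%05d", seq_len(n_bg))
  genes <- c(mouse_genes, bg_genes)
  n_g <- length(genes)

  cluster <- c(ht$cluster[idx], rep("none", n_bg))
  beta_nas <- c(ht$beta_nas[idx], rep(0, n_bg))
  beta_fib <- c(ht$beta_fib[idx], rep(0, n_bg))
  baseline <- c(ht$baseline[idx],
                rnorm(n_bg, cfg$baseline_logmean_params[1L], cfg$baseline_logmean_params[2L]))
  phi <- c(ht$phi[idx],
           exp(rnorm(n_bg, cfg$dispersion_params[1L], cfg$dispersion_params[2L])))
  inherited <- c(ht$cluster[idx] != "none", rep(FALSE, n_bg))

  n_tp <- length(timepoints)
  if (is.null(severity_nas))
    severity_nas <- round(seq(0, 8, length.out = n_tp))
  if (length(severity_nas) != n_tp)
    stop("severity_nas must have one entry per timepoint")
  if (n_per_timepoint < 1L) stop("n_per_timepoint must be >= 1")
  nas <- rep(as.integer(severity_nas), each = n_per_timepoint)
  fibrosis <- pmin(pmax(as.integer(round(nas / 2)), 0L), 4L)
  week <- rep(timepoints, each = n_per_timepoint)
  n_s <- n_tp * n_per_timepoint
  sample_ids <- sprintf("mouse_w%02d_R%d", week,
                        rep(seq_len(n_per_timepoint), times = n_tp))
  libsize <- exp(rnorm(n_s, cfg$libsize_params[1L], cfg$libsize_params[2L]))

  is_utd <- cluster == "up_then_down"
  nas_lin <- outer(beta_nas, nas)
  if (any(is_utd))
    nas_lin[is_utd, ] <- outer(beta_nas[is_utd], nas_effect_design(nas, TRUE))
  log2mu <- baseline + nas_lin + outer(beta_fib, fibrosis) +
    matrix(log2(libsize), n_g, n_s, byrow = TRUE)
  mu <- 2^pmin(log2mu, 30)
  counts <- matrix(rnbinom(n_g * n_s, mu = as.vector(mu), size = rep(1 / phi, n_s)),
                   nrow = n_g, dimnames = list(genes, sample_ids))
  storage.mode(counts) <- "integer"

  samples <- data.frame(sample_id = sample_ids,
                        batch = "mouse",
                        sex = "M",
                        species = "mouse",
                        nas = NA_integer_,
                        fibrosis = NA_integer_,
                        group = sprintf("week%d", week),
                        stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(gene_id = genes,
                       human_gene = c(orth$human_gene, rep(NA_character_, n_bg)),
                       inherited = inherited, cluster = cluster,
                       beta_nas = beta_nas, beta_fib = beta_fib,
                       phi = phi, baseline = baseline,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids, timepoint = week,
                         nas = nas, fibrosis = fibrosis, libsize = libsize,
                         stringsAsFactors = FALSE))
  list(counts = counts, samples = samples, truth = truth)
}
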