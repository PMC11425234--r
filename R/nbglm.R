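# Per-gene negative-binomial GLM (log link) with ordinal severity covariates
# and nuisance terms. Coefficients are estimated by IRLS from a Poisson start,
# the dispersion by per-gene maximum likelihood (bounded search on log-phi),
# alternating two rounds of (beta | phi) updates. No dispersion or fold-change
# shrinkage is applied, so every estimate has an exact closed-form target.
# Betas are reported in log2 units per covariate unit; standard errors come
# from the inverse observed information at the optimum.

LOG2 <- log(2)

# NB log-likelihood in phi (dispersion) for fixed means mu.
nb_loglik_phi <- function(phi, y, mu) {
  a <- 1 / phi
  sum(lgamma(y + a) - lgamma(a) - lfactorial(y) +
        y * log(phi * mu) - (y + a) * log1p(phi * mu))
}

# IRLS (Fisher scoring) for the NB GLM with fixed dispersion.
nb_irls <- function(y, X, offset, phi, beta0, max_iter = 50L, tol = 1e-10) {
  beta <- beta0
  eta <- pmin(drop(X %*% beta) + offset, 30)
  mu <- exp(eta)
  dev_old <- -2 * nb_loglik_phi(max(phi, 1e-12), y, mu)
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(
      solve(crossprod(X, w * X), crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(beta = beta, mu = mu, converged = FALSE))
    beta_new <- drop(fit)
    eta <- pmin(drop(X %*% beta_new) + offset, 30)
    mu <- pmax(exp(eta), 1e-300)
    dev <- -2 * nb_loglik_phi(max(phi, 1e-12), y, mu)
    beta <- beta_new
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1))
      return(list(beta = beta, mu = mu, converged = TRUE))
    dev_old <- dev
  }
  list(beta = beta, mu = mu, converged = FALSE)
}

#' Fit the per-gene negative-binomial severity model
#'
#' Fits `count ~ NB(mu, phi)` with `log mu = X beta + log(sf)` by iteratively
#' reweighted least squares starting from the Poisson fit, alternating two
#' rounds of dispersion updates (maximum likelihood over `log(phi)` bounded
#' in `[log 1e-8, log 10]`) with coefficient updates. Betas and standard
#' errors are reported in log2 units; standard errors use the inverse
#' observed information at the optimum.
#'
#' @param y Integer count vector for one gene.
#' @param X Design matrix (rows = samples), including the intercept.
#' @param sf Positive size factors, one per sample.
#' @return List of class `gene_fit`: `beta`, `se` (log2 units, named by
#'   design column), `phi`, `converged`, and `mu` (fitted means). All-zero
#'   genes return `NA` estimates with `converged = NA` (a missing fit, not an
#'   error).
#' @export
fit_gene_model <- function(y, X, sf) {
  stopifnot(length(y) == nrow(X), length(sf) == nrow(X), all(sf > 0))
  p <- ncol(X)
  na_fit <- list(beta = setNames(rep(NA_real_, p), colnames(X)),
                 se = setNames(rep(NA_real_, p), colnames(X)),
                 phi = NA_real_, converged = NA, mu = NULL)
  class(na_fit) <- "gene_fit"
  if (all(y == 0L)) return(na_fit)
  offset <- log(sf)

  pois <- tryCatch(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offset),
    error = function(e) NULL)
  if (is.null(pois)) return(na_fit)
  beta <- pois$coefficients
  beta[is.na(beta)] <- 0
  mu <- pmax(exp(pmin(drop(X %*% beta) + offset, 30)), 1e-300)

  phi <- 1e-4
  converged <- FALSE
  for (round in 1:2) {
    opt <- optimize(function(lp) nb_loglik_phi(exp(lp), y, mu),
                    interval = c(log(1e-8), log(10)), maximum = TRUE,
                    tol = 1e-8)
    phi <- exp(opt$maximum)
    fit <- nb_irls(y, X, offset, phi, beta)
    beta <- fit$beta
    mu <- fit$mu
    converged <- fit$converged
  }

  # observed information for the log-link NB with fixed phi
  u <- mu * (1 + phi * y) / (1 + phi * mu)^2
  info <- crossprod(X, u * X)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  if (any(!is.finite(se))) converged <- FALSE
  out <- list(beta = setNames(beta / LOG2, colnames(X)),
              se = setNames(se / LOG2, colnames(X)),
              phi = phi, converged = converged, mu = mu)
  class(out) <- "gene_fit"
  out
}

#' Wald test for a fitted coefficient
#'
#' `z = beta / se` (scale-invariant, computed on whichever log scale the fit
#' reports) with a two-sided p-value from the standard normal.
#'
#' @param fit A `gene_fit` from [fit_gene_model()].
#' @param coef Name of the coefficient to test (e.g. `"nas"`, `"fibrosis"`).
#' @return List with `statistic` and `p`; both `NA` when the fit is missing,
#'   unconverged, or the standard error is zero.
#' @export
wald_test <- function(fit, coef) {
  b <- fit$beta[[coef]]
  s <- fit$se[[coef]]
  if (is.na(b) || is.na(s) || !isTRUE(fit$converged) || s == 0)
    return(list(statistic = NA_real_, p = NA_real_))
  z <- b / s
  list(statistic = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement. Missing p-values are
#' excluded from the number of tests and stay missing.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Per-gene differential expression against severity covariates
#'
#' Fits the NB severity GLM for every gene with design
#' `~ batch + sex + nas + fibrosis` (nuisance terms dropped automatically
#' when single-level), Wald-tests the two severity coefficients, and adjusts
#' each severity covariate's p-values separately by Benjamini-Hochberg. NAS
#' and fibrosis enter as numeric linear covariates so coefficients are log2
#' fold changes per unit of score.
#'
#' @param counts Count matrix, genes in rows.
#' @param samples Sample table paired with `counts` columns (no missing
#'   severity scores).
#' @param sf Size factors; computed by [median_of_ratios_size_factors()]
#'   when `NULL`.
#' @param covariates Nuisance covariates preceding the severity terms.
#' @return A `DETable` data frame: per gene `base_mean`, `beta_nas`,
#'   `se_nas`, `beta_fib`, `se_fib`, `phi`, `p_nas`, `p_fib`, `padj_nas`,
#'   `padj_fib`, `converged`, and a `deg_call` column initialized to
#'   `"none"` (filled by [call_severity_degs()]).
#' @export
de_severity <- function(counts, samples, sf = NULL,
                        covariates = c("batch", "sex")) {
  validate_counts(counts)
  validate_sample_table(samples, counts)
  if (anyNA(samples$nas) || anyNA(samples$fibrosis))
    stop("severity DE requires graded samples (no missing nas/fibrosis)")
  if (is.null(sf)) sf <- median_of_ratios_size_factors(counts)
  X <- covariate_design(samples, c(covariates, "nas", "fibrosis"))
  if (qr(X)$rank < ncol(X))
    stop("severity design is rank deficient on the supplied samples")
  n_g <- nrow(counts)
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(sweep(counts, 2L, sf, "/")),
                    beta_nas = NA_real_, se_nas = NA_real_,
                    beta_fib = NA_real_, se_fib = NA_real_,
                    phi = NA_real_, p_nas = NA_real_, p_fib = NA_real_,
                    padj_nas = NA_real_, padj_fib = NA_real_,
                    converged = NA, deg_call = "none",
                    stringsAsFactors = FALSE)
  for (g in seq_len(n_g)) {
    fit <- fit_gene_model(counts[g, ], X, sf)
    if (is.na(fit$converged)) next
    res$beta_nas[g] <- fit$beta[["nas"]]
    res$se_nas[g] <- fit$se[["nas"]]
    res$beta_fib[g] <- fit$beta[["fibrosis"]]
    res$se_fib[g] <- fit$se[["fibrosis"]]
    res$phi[g] <- fit$phi
    res$converged[g] <- fit$converged
    res$p_nas[g] <- wald_test(fit, "nas")$p
    res$p_fib[g] <- wald_test(fit, "fibrosis")$p
  }
  res$padj_nas <- adjust_bh(res$p_nas)
  res$padj_fib <- adjust_bh(res$p_fib)
  rownames(res) <- NULL
  res
}

#' DEG-calling thresholds
#'
#' Defaults follow the severity DEG rule: log2 fold change > ±0.1 per unit of
#' NAS or > ±0.2 per unit of fibrosis stage, adjusted p < 0.05; the two-group
#' mouse rule uses |log2FC| > 1 at the same adjusted-p cutoff.
#'
#' @param lfc_nas,lfc_fib,alpha,mouse_lfc Positive thresholds.
#' @return List of class `deg_thresholds`.
#' @export
deg_thresholds <- function(lfc_nas = 0.1, lfc_fib = 0.2, alpha = 0.05,
                           mouse_lfc = 1.0) {
  if (any(c(lfc_nas, lfc_fib, alpha, mouse_lfc) <= 0))
    stop("all thresholds must be positive")
  structure(list(lfc_nas = lfc_nas, lfc_fib = lfc_fib, alpha = alpha,
                 mouse_lfc = mouse_lfc), class = "deg_thresholds")
}

#' Call severity-associated DEGs
#'
#' A gene is called `up` when `beta_nas > lfc_nas` with `padj_nas < alpha`
#' OR `beta_fib > lfc_fib` with `padj_fib < alpha` (strict inequalities);
#' `down` symmetrically with negative betas. Genes qualifying in opposite
#' directions on the two covariates are flagged `ambiguous` and excluded
#' from downstream DEG sets; everything else is `none`.
#'
#' @param de `DETable` from [de_severity()].
#' @param th Thresholds from [deg_thresholds()].
#' @return The table with `deg_call` filled in
#'   (`up` / `down` / `none` / `ambiguous`).
#' @export
call_severity_degs <- function(de, th = deg_thresholds()) {
  up_nas <- !is.na(de$padj_nas) & de$beta_nas > th$lfc_nas & de$padj_nas < th$alpha
  dn_nas <- !is.na(de$padj_nas) & de$beta_nas < -th$lfc_nas & de$padj_nas < th$alpha
  up_fib <- !is.na(de$padj_fib) & de$beta_fib > th$lfc_fib & de$padj_fib < th$alpha
  dn_fib <- !is.na(de$padj_fib) & de$beta_fib < -th$lfc_fib & de$padj_fib < th$alpha
  up <- up_nas | up_fib
  down <- dn_nas | dn_fib
  call <- rep("none", nrow(de))
  call[up & !down] <- "up"
  call[down & !up] <- "down"
  call[up & down] <- "ambiguous"
  de$deg_call <- call
  de
}

#' Cluster DEG severity patterns
#'
#' Per-gene severity profile: expression is z-scored across samples, then
#' averaged within each observed NAS level; profiles are grouped by
#' agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) into `k` clusters. Deterministic given the input order.
#'
#' @param expr Expression matrix restricted to DEGs (genes in rows).
#' @param samples Sample table paired with `expr` columns.
#' @param k Number of clusters (default 3: the down / up / up-then-down
#'   progression patterns).
#' @return Named integer vector of cluster labels (1..k), plus the profile
#'   matrix in attribute `"profiles"`.
#' @export
cluster_deg_patterns <- function(expr, samples, k = 3L) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) < k) stop("fewer genes (", nrow(expr), ") than clusters (", k, ")")
  if (anyNA(samples$nas)) stop("pattern clustering requires graded samples")
  z <- t(scale(t(expr)))
  z[is.na(z)] <- 0  # constant genes: flat profile
  levels_nas <- sort(unique(samples$nas))
  prof <- sapply(levels_nas, function(l) rowMeans(z[, samples$nas == l, drop = FALSE]))
  prof <- matrix(prof, nrow = nrow(expr),
                 dimnames = list(rownames(expr), paste0("nas", levels_nas)))
  if (k == 1L) {
    labels <- setNames(rep(1L, nrow(expr)), rownames(expr))
  } else {
    hc <- hclust(dist(prof, method = "euclidean"), method = "ward.D2")
    labels <- cutree(hc, k = k)
  }
  attr(labels, "profiles") <- prof
  labels
}

#' Two-group differential expression (mouse timepoint vs control)
#'
#' Same NB GLM with a single binary group covariate; DEGs are genes with
#' `|log2FC| > mouse_lfc` and adjusted p < alpha.
#'
#' @param counts Count matrix, genes in rows.
#' @param group Factor-like vector with exactly two levels; the first level
#'   (after `factor()`) is the reference.
#' @param th Thresholds from [deg_thresholds()].
#' @param sf Size factors; computed when `NULL`.
#' @return Data frame with `gene_id`, `base_mean`, `log2fc`, `se`, `phi`,
#'   `p`, `padj`, `deg_call`.
#' @export
two_group_mouse_degs <- function(counts, group, th = deg_thresholds(), sf = NULL) {
  validate_counts(counts)
  f <- factor(group)
  if (nlevels(f) != 2L) stop("exactly two groups required, got ", nlevels(f))
  if (any(table(f) < 2L)) stop("each group needs >= 2 samples")
  if (length(f) != ncol(counts)) stop("group length must match samples")
  if (is.null(sf)) sf <- median_of_ratios_size_factors(counts)
  X <- cbind("(Intercept)" = 1, grp = as.numeric(f == levels(f)[2L]))
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(sweep(counts, 2L, sf, "/")),
                    log2fc = NA_real_, se = NA_real_, phi = NA_real_,
                    p = NA_real_, padj = NA_real_, deg_call = "none",
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(counts))) {
    fit <- fit_gene_model(counts[g, ], X, sf)
    if (is.na(fit$converged)) next
    res$log2fc[g] <- fit$beta[["grp"]]
    res$se[g] <- fit$se[["grp"]]
    res$phi[g] <- fit$phi
    res$p[g] <- wald_test(fit, "grp")$p
  }
  res$padj <- adjust_bh(res$p)
  sig <- !is.na(res$padj) & res$padj < th$alpha & abs(res$log2fc) > th$mouse_lfc
  res$deg_call[sig & res$log2fc > 0] <- "up"
  res$deg_call[sig & res$log2fc < 0] <- "down"
  rownames(res) <- NULL
  res
}
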