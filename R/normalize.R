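# Library-size normalization and variance stabilization. Size factors use the
# median-of-ratios estimator; the VST is the closed-form asinh integral of the
# NB variance function at a single common dispersion. Nuisance covariates are
# removed on the vst scale by OLS residualization, for visualization and
# scoring only -- differential expression always models covariates explicitly
# on the counts.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes of
#' `count_gj / geomean_g`, where reference genes are those with a nonzero
#' count in every sample (so the geometric mean is defined). Factors are then
#' rescaled to geometric mean 1.
#'
#' @param counts Count matrix, genes in rows.
#' @param pseudo_reference If `TRUE` and no gene is expressed in all samples,
#'   fall back to a pseudo-reference built from positive counts only (the
#'   geometric mean over each gene's nonzero entries, medians taken over each
#'   sample's positive counts).
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
median_of_ratios_size_factors <- function(counts, pseudo_reference = FALSE) {
  validate_counts(counts)
  ref <- rowSums(counts == 0L) == 0L
  if (!any(ref)) {
    if (!pseudo_reference)
      stop("no gene has nonzero counts in every sample; ",
           "re-run with pseudo_reference = TRUE to use a positive-count pseudo-reference")
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    loggeo <- rowMeans(logc, na.rm = TRUE)
    use <- is.finite(loggeo)
    sf <- apply(logc[use, , drop = FALSE] - loggeo[use], 2L,
                function(x) exp(median(x, na.rm = TRUE)))
  } else {
    logc <- log(counts[ref, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- apply(logc - loggeo, 2L, function(x) exp(median(x)))
  }
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor estimation failed: non-positive factor")
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

# Method-of-moments per-gene dispersion on normalized counts; used for the
# common-dispersion default of the VST.
moments_dispersion <- function(counts, sf) {
  q <- sweep(counts, 2L, sf, "/")
  m <- rowMeans(q)
  v <- rowSums((q - m)^2) / (ncol(q) - 1L)
  phi <- (v - m) / m^2
  phi[!is.finite(phi)] <- NA
  phi
}

#' Variance-stabilizing transformation for NB counts
#'
#' Closed-form VST at a single common dispersion `phi`: the integral of
#' `1/sqrt(v(mu))` for the NB variance `v(mu) = mu + phi mu^2` gives
#' `value = (2 / (sqrt(phi) * ln 2)) * asinh(sqrt(phi * count / sf))`,
#' expressed in log2-like units. A count of 0 maps to 0; as `phi -> 0` the
#' transform approaches `2 * sqrt(count/sf) / ln 2` (the Poisson square-root
#' limit), and for large counts it approaches `log2(count/sf)` plus a
#' constant.
#'
#' @param counts Count matrix, genes in rows.
#' @param sf Size factors (defaults to [median_of_ratios_size_factors()]).
#' @param phi_common Common dispersion (> 0); defaults to the median of
#'   per-gene method-of-moments dispersions (falling back to 1e-6 when no
#'   gene yields a positive estimate).
#' @param log1p_fallback If `TRUE`, use `log2(count/sf + 1)` instead of the
#'   asinh form.
#' @return Numeric matrix of transformed values with attribute
#'   `"phi_common"`.
#' @export
vst_transform <- function(counts, sf = NULL, phi_common = NULL,
                          log1p_fallback = FALSE) {
  validate_counts(counts)
  if (is.null(sf)) sf <- median_of_ratios_size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  q <- sweep(counts, 2L, sf, "/")
  if (log1p_fallback) {
    out <- log2(q + 1)
    attr(out, "phi_common") <- NA_real_
    return(out)
  }
  if (is.null(phi_common)) {
    phi <- moments_dispersion(counts, sf)
    phi <- phi[!is.na(phi) & phi > 0]
    phi_common <- if (length(phi) > 0L) median(phi) else 1e-6
  }
  if (!is.numeric(phi_common) || length(phi_common) != 1L || phi_common <= 0)
    stop("phi_common must be a single positive number")
  out <- (2 / (sqrt(phi_common) * log(2))) * asinh(sqrt(phi_common * q))
  attr(out, "phi_common") <- phi_common
  out
}

# Build a design matrix for the named sample-table covariates. batch and sex
# enter as factor dummies (dropped when single-level), nas and fibrosis as
# numeric scores.
covariate_design <- function(samples, covariates, intercept = TRUE) {
  cols <- list()
  assign <- character(0)
  for (cv in covariates) {
    x <- samples[[cv]]
    if (is.null(x)) stop("unknown covariate: ", cv)
    if (cv %in% c("nas", "fibrosis")) {
      if (anyNA(x)) stop("covariate '", cv, "' has missing values")
      cols[[cv]] <- as.numeric(x)
      assign <- c(assign, cv)
    } else {
      f <- factor(x)
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1L])
        for (k in seq_len(ncol(mm))) {
          cols[[colnames(mm)[k]]] <- mm[, k]
          assign <- c(assign, cv)
        }
      }
    }
  }
  X <- if (length(cols) > 0L) do.call(cbind, cols) else
    matrix(numeric(0), nrow(samples), 0L)
  if (intercept) {
    X <- cbind("(Intercept)" = rep(1, nrow(samples)), X)
    assign <- c("(Intercept)", assign)
  }
  attr(X, "assign_covariate") <- assign
  X
}

#' Remove nuisance covariates from an expression matrix
#'
#' Per gene, fits an ordinary-least-squares model on the full design built
#' from `remove` and `keep` covariates (plus an intercept) and subtracts the
#' fitted contribution of the `remove` covariates only. Biological structure
#' carried by `keep` covariates is untouched. Operates on a log-like scale
#' (e.g. vst values), where additive effects are meaningful; the adjusted
#' matrix is for visualization and scoring, not for re-fitting count models.
#'
#' @param expr Expression matrix, genes in rows.
#' @param samples Sample table paired with `expr` columns.
#' @param remove Covariate names whose fitted contribution is subtracted
#'   (e.g. `c("batch", "sex")`).
#' @param keep Covariate names retained in the design so their structure is
#'   not absorbed into the removal (e.g. `c("nas", "fibrosis")`).
#' @return Adjusted expression matrix of the same shape.
#' @export
residualize_covariates <- function(expr, samples, remove, keep = character(0)) {
  stopifnot(is.matrix(expr))
  validate_sample_table(samples)
  if (!identical(as.character(samples$sample_id), colnames(expr)))
    stop("sample table must match expression columns")
  X <- covariate_design(samples, c(remove, keep), intercept = TRUE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  assign <- attr(X, "assign_covariate")
  rm_cols <- which(assign %in% remove)
  if (length(rm_cols) == 0L) return(expr)
  beta <- qr.coef(qrX, t(expr))             # p x genes
  removed <- X[, rm_cols, drop = FALSE] %*% beta[rm_cols, , drop = FALSE]
  expr - t(removed)
}
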