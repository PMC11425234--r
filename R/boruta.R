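# Boruta all-relevant feature selection. Each iteration appends "shadow"
# features (independently permuted copies of every active candidate column),
# fits an importance estimator on [real | shadow], and records a hit for each
# real feature whose importance strictly exceeds the maximum shadow
# importance. Hits are tested against Binomial(n_done, 1/2) two-sided with
# Bonferroni correction over the candidate features; features rejected
# downward are removed from subsequent iterations, features confirmed upward
# stay in the model but are no longer tested.

#' Boruta parameters
#'
#' @param n_iter Number of shadow iterations (>= 10; default 100).
#' @param alpha Significance level of the binomial decision test.
#' @param estimator Importance estimator: `function(X, y, seed)` returning
#'   one non-negative importance per column of `X` (the per-iteration `seed`
#'   keeps stochastic estimators reproducible). Defaults to
#'   [rf_importance()], a random-forest impurity importance (500 trees: with
#'   hundreds of candidate features the per-feature importance of smaller
#'   ensembles is too unstable for the strictly-exceeds-shadow-max hit rule).
#'   Pluggable so the selection logic can be exercised with deterministic
#'   stubs.
#' @param seed Integer seed; shadow permutations and the default estimator
#'   are both driven from it, so results are deterministic.
#' @param correction Multiplicity correction of the decision test;
#'   `"bonferroni"` (over candidate features) or `"none"`.
#' @return List of class `boruta_params`.
#' @export
boruta_params <- function(n_iter = 100L, alpha = 0.05, estimator = rf_importance,
                          seed = 1L, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  n_iter <- as.integer(n_iter)
  if (n_iter < 10L) stop("n_iter must be >= 10")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_iter = n_iter, alpha = alpha, estimator = estimator,
                 seed = as.integer(seed), correction = correction),
            class = "boruta_params")
}

#' Random-forest impurity importance (default Boruta estimator)
#'
#' Regression forest with 500 trees, single-threaded and seeded for
#' reproducibility.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Numeric target.
#' @param num_trees Number of trees.
#' @param seed Integer seed.
#' @return Non-negative importance per column of `X`.
#' @export
rf_importance <- function(X, y, num_trees = 500L, seed = 1L) {
  df <- data.frame(..y = y, X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                        num.trees = num_trees, importance = "impurity",
                        seed = seed, num.threads = 1L,
                        respect.unordered.factors = "order")
  imp <- fit$variable.importance[colnames(X)]
  pmax(as.numeric(imp), 0)
}

#' Boruta shadow-feature selection
#'
#' @param features Numeric matrix, samples x candidate genes (named columns).
#' @param target Numeric severity target (e.g. NAS + fibrosis).
#' @param params [boruta_params()].
#' @return A `boruta_result` data frame: per feature `feature`, `status`
#'   (`confirmed` / `tentative` / `rejected`), `hit_count`, `n_iter_done`,
#'   `decision_iteration` (NA while tentative).
#' @export
boruta_select <- function(features, target, params = boruta_params()) {
  stopifnot(is.matrix(features))
  if (is.null(colnames(features))) stop("features must have column names")
  if (nrow(features) < 20L) stop("Boruta requires >= 20 samples")
  if (ncol(features) < 1L) stop("no candidate features")
  if (length(target) != nrow(features)) stop("target length must match samples")
  if (sd(target) == 0) stop("target has zero variance")

  p <- ncol(features)
  status <- setNames(rep("tentative", p), colnames(features))
  hits <- setNames(rep(0L, p), colnames(features))
  n_done <- setNames(rep(0L, p), colnames(features))
  decision <- setNames(rep(NA_integer_, p), colnames(features))
  m <- if (params$correction == "bonferroni") p else 1L

  set.seed(params$seed)
  for (it in seq_len(params$n_iter)) {
    active <- status != "rejected"
    if (!any(active)) break
    Xa <- features[, active, drop = FALSE]
    shadows <- apply(Xa, 2L, sample)
    colnames(shadows) <- paste0("shadow_", colnames(Xa))
    est_seed <- sample.int(2147483646L, 1L)
    imp <- params$estimator(cbind(Xa, shadows), target, seed = est_seed)
    pa <- ncol(Xa)
    shadow_max <- max(imp[(pa + 1L):(2L * pa)])
    hit <- imp[seq_len(pa)] > shadow_max
    hits[active] <- hits[active] + as.integer(hit)
    n_done[active] <- n_done[active] + 1L

    tent <- status == "tentative"
    if (any(tent)) {
      h <- hits[tent]; n <- n_done[tent]
      p_up <- stats::pbinom(h - 1L, n, 0.5, lower.tail = FALSE)
      p_dn <- stats::pbinom(h, n, 0.5)
      p_two <- pmin(1, 2 * pmin(p_up, p_dn))
      decide <- p_two < params$alpha / m
      if (any(decide)) {
        who <- names(h)[decide]
        upward <- (h > n / 2)[decide]
        status[who[upward]] <- "confirmed"
        status[who[!upward]] <- "rejected"
        decision[who] <- it
      }
    }
  }
  out <- data.frame(feature = names(status), status = unname(status),
                    hit_count = unname(hits), n_iter_done = unname(n_done),
                    decision_iteration = unname(decision),
                    stringsAsFactors = FALSE)
  class(out) <- c("boruta_result", "data.frame")
  out
}
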