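# Single-sample gene-set enrichment (ssGSEA) from the rank-weighted
# running-sum definition. For one sample, genes are sorted by descending
# expression (ties broken deterministically by gene identifier); rank weight
# r_i = n - position + 1; the enrichment score is the summed difference of
# the weighted in-set ECDF and the unweighted out-of-set ECDF:
#   ES = sum_i [ P_in(i) - P_out(i) ],
#   P_in(i)  = sum_{j <= i, g_j in S} r_j^alpha / sum_{g in S} r_g^alpha,
#   P_out(i) = |{j <= i, g_j not in S}| / (n - |S|).
# At alpha = 0 this reduces to the summed difference of unweighted ECDFs.

#' ssGSEA scoring parameters
#'
#' @param alpha Rank-weight exponent (>= 0); 0.25 by convention of the
#'   single-sample enrichment method.
#' @param normalize `"none"` (raw ES; the default staging statistic, since
#'   staging uses within-analysis ranks) or `"range"` (min-max scaling of the
#'   scored cohort to `[0, 1]`, for cross-cohort plotting).
#' @return List of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 0.25, normalize = c("none", "range")) {
  normalize <- match.arg(normalize)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single number >= 0")
  structure(list(alpha = alpha, normalize = normalize),
            class = "scoring_params")
}

#' ssGSEA enrichment score for a single sample
#'
#' @param expr_values Named numeric vector: one expression value per gene.
#' @param gene_set Character vector of set members.
#' @param params [scoring_params()].
#' @return The raw enrichment score (a real number; +1 when the set occupies
#'   the top of the ranking exhaustively, -1 at the bottom).
#' @export
ssgsea_sample <- function(expr_values, gene_set, params = scoring_params()) {
  genes <- names(expr_values)
  if (is.null(genes)) stop("expr_values must be named by gene")
  n <- length(expr_values)
  if (n < 2L) stop("need >= 2 genes")
  in_set <- genes %in% gene_set
  k <- sum(in_set)
  if (k == 0L) stop("gene set has empty intersection with the expression genes")
  if (k == n) stop("gene set covers every expression gene; ES undefined")
  ord <- order(-expr_values, genes)  # descending value, ties by identifier
  in_ord <- in_set[ord]
  r <- n - seq_len(n) + 1           # rank weight: top gene gets n
  w <- ifelse(in_ord, r^params$alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - k)
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample of an expression matrix
#'
#' Signature members missing from the matrix are dropped with a warning (the
#' in-set weight denominator renormalizes automatically); more than 50%
#' missing is an error. Ranks are by descending ES with average-rank ties.
#'
#' @param expr Expression matrix, genes in rows, samples in columns
#'   (vst-scale values by default convention).
#' @param signature `gene_signature`, or a character vector of member genes.
#' @param params [scoring_params()].
#' @return An `EnrichmentTable` data frame: `sample_id`, `es`, `es_normalized`
#'   (`NA` unless range normalization is enabled), `rank`.
#' @export
ssgsea_matrix <- function(expr, signature, params = scoring_params()) {
  stopifnot(is.matrix(expr))
  members <- if (inherits(signature, "gene_signature")) signature$gene
             else as.character(signature)
  members <- unique(members)
  present <- members[members %in% rownames(expr)]
  missing <- setdiff(members, present)
  if (length(present) < length(members) / 2)
    stop("more than 50% of signature genes absent from the matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  if (length(missing) > 0L)
    warning(length(missing), " signature gene(s) absent from the matrix; dropped")
  es <- apply(expr, 2L, function(v) {
    ssgsea_sample(setNames(v, rownames(expr)), present, params)
  })
  es_norm <- rep(NA_real_, length(es))
  if (params$normalize == "range") {
    rng <- range(es)
    es_norm <- if (diff(rng) == 0) rep(0.5, length(es)) else
      (es - rng[1L]) / diff(rng)
  }
  out <- data.frame(sample_id = colnames(expr), es = unname(es),
                    es_normalized = es_norm,
                    rank = rank(-es, ties.method = "average"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
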