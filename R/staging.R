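# Rank-based disease stratification: validate enrichment scores against
# histology scores by Spearman correlation, map query (mouse) samples onto
# the human severity scale through their k nearest reference neighbors in
# enrichment score, and count concordant cross-species DEGs per timepoint.

#' Spearman validation of enrichment scores against severity
#'
#' Spearman rho with average-rank tie handling; the p-value uses the
#' large-sample t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2
#' degrees of freedom. An exact permutation p-value is available for small
#' cohorts (n <= 8, where full enumeration is feasible).
#'
#' @param scores `EnrichmentTable` from [ssgsea_matrix()], or a numeric
#'   vector of enrichment scores.
#' @param severity Numeric severity vector (e.g. NAS), paired with the
#'   scores; pairs with missing values are dropped.
#' @param exact If `TRUE`, compute the two-sided permutation p-value by full
#'   enumeration (requires n <= 8).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_validate <- function(scores, severity, exact = FALSE) {
  es <- if (is.data.frame(scores)) scores$es else as.numeric(scores)
  if (length(es) != length(severity))
    stop("scores and severity must be paired")
  ok <- !is.na(es) & !is.na(severity)
  es <- es[ok]; severity <- severity[ok]
  n <- length(es)
  if (n < 3L) stop("need >= 3 paired observations")
  if (sd(severity) == 0) stop("severity is constant")
  rho <- cor(es, severity, method = "spearman")
  if (exact) {
    if (n > 8L) stop("exact permutation p-value supported for n <= 8")
    rx <- rank(es); ry <- rank(severity)
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(ix) cor(rx[ix], ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# All permutations of 1..n as an n! x n matrix (recursive construction).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Map query samples onto the human severity scale
#'
#' For each query sample, the `k` reference samples nearest in enrichment
#' score (absolute difference; ties broken by reference order) are its
#' neighbors; the mapped NAS and fibrosis are the medians of the neighbors'
#' scores. Ranks are computed over the pooled reference + query score vector
#' (descending ES, average ties). Reference and query scores must come from
#' one pooled scoring run on a shared transformed scale.
#'
#' @param query `EnrichmentTable` of query (e.g. mouse) samples.
#' @param reference `EnrichmentTable` of reference (human) samples.
#' @param reference_samples Sample table with `nas` and `fibrosis` for the
#'   reference samples (rows matched by `sample_id`).
#' @param k Number of neighbors (default 5).
#' @return A `StagingResult` data frame: per query sample `sample_id`, `es`,
#'   `rank` (within the pooled ordering), `mapped_nas`, `mapped_fibrosis`,
#'   and `neighbors` (comma-separated reference sample ids).
#' @export
rank_map_to_human <- function(query, reference, reference_samples, k = 5L) {
  idx <- match(reference$sample_id, reference_samples$sample_id)
  if (anyNA(idx)) stop("reference samples missing from the sample table")
  ref_nas <- reference_samples$nas[idx]
  ref_fib <- reference_samples$fibrosis[idx]
  graded <- !is.na(ref_nas)
  if (sum(graded) < k)
    stop("k = ", k, " exceeds the ", sum(graded), " graded reference samples")
  ref_es <- reference$es[graded]
  ref_ids <- reference$sample_id[graded]
  ref_nas <- ref_nas[graded]
  ref_fib <- ref_fib[graded]

  pooled <- c(reference$es, query$es)
  pooled_rank <- rank(-pooled, ties.method = "average")
  q_rank <- pooled_rank[length(reference$es) + seq_along(query$es)]

  mapped <- t(vapply(seq_along(query$es), function(i) {
    d <- abs(ref_es - query$es[i])
    nb <- order(d)[seq_len(k)]
    c(median(ref_nas[nb]), median(ref_fib[nb], na.rm = TRUE))
  }, numeric(2L)))
  neighbors <- vapply(seq_along(query$es), function(i) {
    d <- abs(ref_es - query$es[i])
    paste(ref_ids[order(d)[seq_len(k)]], collapse = ",")
  }, character(1L))

  data.frame(sample_id = query$sample_id, es = query$es, rank = q_rank,
             mapped_nas = mapped[, 1L], mapped_fibrosis = mapped[, 2L],
             neighbors = neighbors, stringsAsFactors = FALSE)
}

#' Cross-species DEG overlap per timepoint
#'
#' Common DEGs are ortholog pairs where both species call a DEG; they are
#' concordant-up when both are `up`, concordant-down when both `down`, and
#' discordant otherwise.
#'
#' @param human_de Human severity `DETable` with `deg_call` filled.
#' @param mouse_de_by_timepoint Named list of mouse two-group DE tables (one
#'   per timepoint).
#' @param orth Ortholog map data frame.
#' @return Data frame with one row per timepoint: `timepoint`,
#'   `n_common_up`, `n_common_down`, `n_discordant`.
#' @export
cross_species_deg_overlap <- function(human_de, mouse_de_by_timepoint, orth) {
  if (is.null(orth) || nrow(orth) == 0L) stop("ortholog map is empty")
  human_call <- setNames(human_de$deg_call, human_de$gene_id)
  out <- lapply(names(mouse_de_by_timepoint), function(tp) {
    mde <- mouse_de_by_timepoint[[tp]]
    mouse_call <- setNames(mde$deg_call, mde$gene_id)
    h <- human_call[orth$human_gene]
    m <- mouse_call[orth$mouse_gene]
    common <- !is.na(h) & !is.na(m) & h %in% c("up", "down") & m %in% c("up", "down")
    data.frame(timepoint = tp,
               n_common_up = sum(common & h == "up" & m == "up"),
               n_common_down = sum(common & h == "down" & m == "down"),
               n_discordant = sum(common & h != m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
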