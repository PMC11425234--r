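# Independent oracles and small fixture builders shared across test files.

# Brute-force double-loop ssGSEA summation, written directly from the
# running-sum definition (no cumulative-sum shortcuts).
ssgsea_oracle <- function(vals, set, alpha) {
  g <- names(vals)
  n <- length(g)
  ord <- order(-vals, g)
  r <- n - seq_len(n) + 1
  in_set <- g[ord] %in% set
  denom <- sum(r[in_set]^alpha)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- 0
    p_out <- 0
    for (j in seq_len(i)) {
      if (in_set[j]) p_in <- p_in + r[j]^alpha else p_out <- p_out + 1
    }
    es <- es + p_in / denom - p_out / (n - sum(in_set))
  }
  es
}

# Benjamini-Hochberg by explicit sort and cumulative minimum.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(ps * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Median-of-ratios by explicit loops over reference genes. With an odd
# reference-gene count the median is an order statistic, so the plain-ratio
# median equals the log-scale median exactly.
size_factor_oracle <- function(counts) {
  ref <- apply(counts, 1L, function(x) all(x > 0))
  geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(col) median(col / geo))
  sf / exp(mean(log(sf)))
}

# True library sizes of a generator run, rescaled to geometric mean 1, for
# experiments that must isolate the model under test from size-factor
# estimation.
truth_size_factors <- function(sim) {
  sf <- sim$truth$samples$libsize
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- sim$samples$sample_id
  sf
}

# Deterministic stub importance estimator: named real features score the
# value given in `scores`, every shadow scores `shadow_value`.
stub_estimator <- function(scores, shadow_value = 1) {
  function(X, y, seed = 1L) {
    nm <- colnames(X)
    imp <- numeric(length(nm))
    is_shadow <- startsWith(nm, "shadow_")
    imp[is_shadow] <- shadow_value
    imp[!is_shadow] <- scores[nm[!is_shadow]]
    imp
  }
}

# Small deterministic count matrix for IO tests.
toy_counts <- function(n_genes = 6L, n_samples = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 5),
              nrow = n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# Minimal valid sample table.
toy_samples <- function(ids, nas = NULL, fibrosis = NULL, batch = "b1",
                        sex = "F", species = "human") {
  n <- length(ids)
  data.frame(sample_id = ids,
             batch = rep_len(batch, n),
             sex = rep_len(sex, n),
             species = rep_len(species, n),
             nas = if (is.null(nas)) rep(NA_integer_, n) else as.integer(nas),
             fibrosis = if (is.null(fibrosis)) rep(NA_integer_, n) else as.integer(fibrosis),
             group = NA_character_,
             stringsAsFactors = FALSE)
}
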