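# End-to-end driver: simulate (or load) -> normalize -> differential
# expression -> signature -> score -> stage. Writes every intermediate
# artifact as TSV/GMT under an output directory together with a run log
# recording versions, seeds and parameters; deterministic under the config
# seed.

#' Pipeline configuration
#'
#' In simulation mode (the default), three human cohorts are generated in one
#' run sharing one set of planted gene effects: two training cohorts and a
#' smaller held-out validation cohort. In input mode (`input` non-NULL),
#' artifacts are read from the named paths instead.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param gen Named list of [gen_config()] overrides for the generator
#'   (training + held-out cohorts are appended automatically).
#' @param heldout_samples Size of the held-out validation cohort.
#' @param frac_ortholog Fraction of human genes given a mouse ortholog in the
#'   synthetic ortholog table.
#' @param mouse Named list of [generate_mouse_timecourse()] overrides
#'   (`timepoints`, `n_per_timepoint`, `severity_nas`, `n_background`).
#' @param thresholds [deg_thresholds()].
#' @param boruta_n_iter,boruta_alpha Boruta iteration count and decision
#'   alpha.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param k Neighbor count of the rank mapping.
#' @param input `NULL` (simulate), or a named list of paths with required
#'   keys `counts`, `samples`, `ortholog_map` and optional keys
#'   `heldout_counts`, `heldout_samples`, `mouse_counts`, `mouse_samples`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            gen = list(),
                            heldout_samples = 60L,
                            frac_ortholog = 0.85,
                            mouse = list(),
                            thresholds = deg_thresholds(),
                            boruta_n_iter = 100L,
                            boruta_alpha = 0.05,
                            ssgsea_alpha = 0.25,
                            k = 5L,
                            input = NULL) {
  if (!is.null(input)) {
    required <- c("counts", "samples", "ortholog_map")
    miss <- setdiff(required, names(input))
    if (length(miss) > 0L)
      stop("pipeline config missing required input key(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), gen = gen,
                 heldout_samples = as.integer(heldout_samples),
                 frac_ortholog = frac_ortholog, mouse = mouse,
                 thresholds = thresholds,
                 boruta_n_iter = as.integer(boruta_n_iter),
                 boruta_alpha = boruta_alpha,
                 ssgsea_alpha = ssgsea_alpha, k = as.integer(k),
                 input = input),
            class = "pipeline_config")
}

derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Run the full staging pipeline
#'
#' Executes simulate (or load) -> normalize -> DE -> signature -> score ->
#' stage, writing every intermediate artifact under `out_dir` and returning
#' them invisibly. Stage failures abort with the stage name and cause.
#'
#' @param config [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param quiet Suppress progress log lines on standard error.
#' @return (Invisibly) a list with the generated/loaded data, the DE table,
#'   Boruta result, signature, held-out enrichment + validation, mouse
#'   staging and cross-species overlap counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) log_msg(...)
  emit <- function(writer, obj, name) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  th <- config$thresholds
  run_log <- c(sprintf("masldstage %s | R %s.%s",
                       as.character(utils::packageVersion("masldstage")),
                       R.version$major, R.version$minor),
               sprintf("seed=%d boruta_n_iter=%d boruta_alpha=%g ssgsea_alpha=%g k=%d",
                       config$seed, config$boruta_n_iter, config$boruta_alpha,
                       config$ssgsea_alpha, config$k),
               sprintf("thresholds: lfc_nas=%g lfc_fib=%g alpha=%g mouse_lfc=%g",
                       th$lfc_nas, th$lfc_fib, th$alpha, th$mouse_lfc))

  # ---- simulate or load ----
  if (is.null(config$input)) {
    say("simulate: generating human cohorts and mouse time-course")
    sim <- stage("simulate", {
      gen_args <- config$gen
      gen_args$seed <- derive_seed(config$seed, 0L)
      base_cohorts <- if (is.null(gen_args$n_cohorts)) 2L else as.integer(gen_args$n_cohorts)
      base_spc <- if (is.null(gen_args$samples_per_cohort)) 75L else
        as.integer(gen_args$samples_per_cohort)
      gen_args$n_cohorts <- base_cohorts + 1L
      gen_args$samples_per_cohort <- c(rep_len(base_spc, base_cohorts),
                                       config$heldout_samples)
      cfg <- do.call(gen_config, gen_args)
      human <- generate_human_cohorts(cfg)
      heldout_batch <- paste0("cohort", cfg$n_cohorts)
      is_held <- human$samples$batch == heldout_batch
      orth <- synthetic_ortholog_map(rownames(human$counts),
                                     frac_mapped = config$frac_ortholog,
                                     seed = derive_seed(config$seed, 1L))
      mouse_args <- config$mouse
      mouse_args$cfg <- cfg
      mouse_args$orth <- orth
      mouse_args$human_truth <- human$truth
      mouse <- do.call(generate_mouse_timecourse, mouse_args)
      list(cfg = cfg,
           counts = human$counts[, !is_held, drop = FALSE],
           samples = droplevels(human$samples[!is_held, , drop = FALSE]),
           heldout_counts = human$counts[, is_held, drop = FALSE],
           heldout_samples = human$samples[is_held, , drop = FALSE],
           truth = human$truth, orth = orth, mouse = mouse)
    })
    emit(write_counts, sim$counts, "counts_train.tsv")
    emit(write_sample_table, sim$samples, "samples_train.tsv")
    emit(write_counts, sim$heldout_counts, "counts_heldout.tsv")
    emit(write_sample_table, sim$heldout_samples, "samples_heldout.tsv")
    emit(write_ortholog_map, sim$orth, "ortholog_map.tsv")
    emit(write_counts, sim$mouse$counts, "counts_mouse.tsv")
    emit(write_sample_table, sim$mouse$samples, "samples_mouse.tsv")
    if (!is.null(out_dir)) {
      utils::write.table(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sim$mouse$truth$samples,
                         file.path(out_dir, "truth_mouse_samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    say("load: reading input artifacts")
    sim <- stage("load", {
      paths <- config$input
      out <- list(counts = read_counts(paths$counts),
                  samples = read_sample_table(paths$samples),
                  orth = read_ortholog_map(paths$ortholog_map))
      if (!is.null(paths$heldout_counts)) {
        out$heldout_counts <- read_counts(paths$heldout_counts)
        out$heldout_samples <- read_sample_table(paths$heldout_samples)
      }
      if (!is.null(paths$mouse_counts)) {
        out$mouse <- list(counts = read_counts(paths$mouse_counts),
                          samples = read_sample_table(paths$mouse_samples))
      }
      out
    })
  }

  # ---- normalize ----
  say("normalize: size factors + vst")
  norm <- stage("normalize", {
    sf <- median_of_ratios_size_factors(sim$counts)
    vst <- vst_transform(sim$counts, sf)
    list(sf = sf, vst = vst)
  })
  emit(write_expression, norm$vst, "vst_train.tsv")

  # ---- differential expression ----
  say("de: per-gene NB severity model on ", nrow(sim$counts), " genes")
  de <- stage("de", {
    tab <- de_severity(sim$counts, sim$samples, sf = norm$sf)
    call_severity_degs(tab, th)
  })
  if (!is.null(out_dir))
    utils::write.table(de, file.path(out_dir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  deg_genes <- de$gene_id[de$deg_call %in% c("up", "down")]
  run_log <- c(run_log, sprintf("severity DEGs: %d (up %d, down %d, ambiguous %d)",
                                length(deg_genes), sum(de$deg_call == "up"),
                                sum(de$deg_call == "down"),
                                sum(de$deg_call == "ambiguous")))
  say("de: ", length(deg_genes), " DEGs")

  # ---- DEG pattern clusters (on batch/sex-adjusted vst) ----
  clusters <- stage("cluster", {
    if (length(deg_genes) >= 3L) {
      adj <- residualize_covariates(norm$vst, sim$samples,
                                    remove = c("batch", "sex"),
                                    keep = c("nas", "fibrosis"))
      cluster_deg_patterns(adj[deg_genes, , drop = FALSE], sim$samples, k = 3L)
    } else NULL
  })
  if (!is.null(clusters) && !is.null(out_dir))
    utils::write.table(data.frame(gene_id = names(clusters),
                                  cluster = as.integer(clusters)),
                       file.path(out_dir, "deg_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- signature: Boruta + curation ----
  say("signature: Boruta over ", length(deg_genes), " DEG candidates")
  sig_res <- stage("signature", {
    if (length(deg_genes) == 0L) stop("no DEG candidates for Boruta")
    adj <- residualize_covariates(norm$vst, sim$samples,
                                  remove = c("batch", "sex"),
                                  keep = c("nas", "fibrosis"))
    features <- t(adj[deg_genes, , drop = FALSE])
    target <- sim$samples$nas + sim$samples$fibrosis
    bp <- boruta_params(n_iter = config$boruta_n_iter,
                        alpha = config$boruta_alpha,
                        seed = derive_seed(config$seed, 2L))
    boruta <- boruta_select(features, target, bp)
    sig <- curate_signature(boruta, de, sim$orth)
    list(boruta = boruta, signature = sig)
  })
  run_log <- c(run_log,
               sprintf("Boruta confirmed: %d of %d candidates",
                       sum(sig_res$boruta$status == "confirmed"), length(deg_genes)),
               sprintf("unified signature: %d genes", nrow(sig_res$signature)))
  say("signature: ", nrow(sig_res$signature), " genes after curation")
  if (!is.null(out_dir)) {
    utils::write.table(sig_res$boruta, file.path(out_dir, "boruta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sig_res$signature, file.path(out_dir, "signature_provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(sig_res$signature, file.path(out_dir, "signature.gmt"))
  }

  params <- scoring_params(alpha = config$ssgsea_alpha)

  # ---- score held-out cohort + Spearman validation ----
  validation <- NULL
  heldout_es <- NULL
  if (!is.null(sim$heldout_counts) && nrow(sig_res$signature) > 0L) {
    say("score: ssGSEA on held-out cohort")
    heldout_es <- stage("score", {
      vst_h <- vst_transform(sim$heldout_counts)
      ssgsea_matrix(vst_h, sig_res$signature, params)
    })
    validation <- stage("validate", {
      list(nas = spearman_validate(heldout_es, sim$heldout_samples$nas),
           fibrosis = spearman_validate(heldout_es, sim$heldout_samples$fibrosis))
    })
    run_log <- c(run_log,
                 sprintf("held-out Spearman rho: NAS %.4f (p=%.3g), fibrosis %.4f (p=%.3g)",
                         validation$nas$rho, validation$nas$p,
                         validation$fibrosis$rho, validation$fibrosis$p))
    say(sprintf("validate: Spearman rho vs NAS = %.4f", validation$nas$rho))
    if (!is.null(out_dir)) {
      utils::write.table(heldout_es, file.path(out_dir, "es_heldout.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(score = c("nas", "fibrosis"),
                   rho = c(validation$nas$rho, validation$fibrosis$rho),
                   p = c(validation$nas$p, validation$fibrosis$p),
                   n = c(validation$nas$n, validation$fibrosis$n)),
        file.path(out_dir, "validation.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # ---- cross-species staging ----
  staging <- NULL
  overlap <- NULL
  if (!is.null(sim$mouse) && nrow(sig_res$signature) > 0L) {
    say("stage: pooled human-mouse scoring and rank mapping")
    staging <- stage("stage", {
      oto <- sim$orth[sim$orth$one_to_one, , drop = FALSE]
      shared <- oto[oto$human_gene %in% rownames(sim$counts) &
                    oto$mouse_gene %in% rownames(sim$mouse$counts), , drop = FALSE]
      vst_ref <- vst_transform(sim$counts)[shared$human_gene, , drop = FALSE]
      vst_query <- vst_transform(sim$mouse$counts)[shared$mouse_gene, , drop = FALSE]
      rownames(vst_query) <- shared$human_gene
      pooled <- cbind(vst_ref, vst_query)
      es <- ssgsea_matrix(pooled, sig_res$signature, params)
      ref_es <- es[seq_len(ncol(vst_ref)), , drop = FALSE]
      query_es <- es[ncol(vst_ref) + seq_len(ncol(vst_query)), , drop = FALSE]
      rank_map_to_human(query_es, ref_es, sim$samples, k = config$k)
    })
    if (!is.null(out_dir))
      utils::write.table(staging, file.path(out_dir, "staging_mouse.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    say("overlap: per-timepoint mouse DEGs vs human severity DEGs")
    overlap <- stage("overlap", {
      grp <- sim$mouse$samples$group
      tps <- unique(grp)
      if (length(tps) >= 2L) {
        control <- tps[1L]
        mde <- lapply(tps[-1L], function(tp) {
          sel <- grp %in% c(control, tp)
          two_group_mouse_degs(sim$mouse$counts[, sel, drop = FALSE],
                               factor(grp[sel], levels = c(control, tp)), th)
        })
        names(mde) <- tps[-1L]
        cross_species_deg_overlap(de, mde, sim$orth)
      } else NULL
    })
    if (!is.null(overlap) && !is.null(out_dir))
      utils::write.table(overlap, file.path(out_dir, "overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(out_dir))
    writeLines(run_log, file.path(out_dir, "run_log.txt"))
  invisible(list(sim = sim, sf = norm$sf, vst = norm$vst, de = de,
                 clusters = clusters, boruta = sig_res$boruta,
                 signature = sig_res$signature, heldout_es = heldout_es,
                 validation = validation, staging = staging, overlap = overlap,
                 run_log = run_log))
}
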