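#' Run the full discriminant-analysis workflow
#'
#' Orchestrates the complete analysis on a study dataset (or a simulated
#' one): per-tissue quantitation filtering and imputation, PCA/Hotelling-T2
#' screening, OPLS-DA of the lighting-group contrast within each eye with
#' the full overfitting diagnostics, multilevel PLS-DA train/test validation
#' of the eye contrast within each lighting group, paired univariate t tests
#' with BH correction, and Venn comparisons of the two lighting conditions
#' per tissue. Machine-readable reports (JSON/CSV) are written to `out_dir`.
#'
#' The top-level `seed` fans out to per-stage substreams derived from the
#' stage label, so adding a stage never perturbs the randomness of earlier
#' ones; all seeds are recorded in the run report.
#'
#' @param config list: either `dataset` (a [study_dataset()]) or `preset`
#'   (a [scenario_presets()] name) with optional `sim_seed`; optional
#'   settings `seed` (default 1), `filter_threshold` (0.2), `folds` (7),
#'   `n_perm` (100), `n_models` (1000), `train_pairs` (9), `ncomp_paired`
#'   (2), `fdr` (0.1), `qc_alpha` (0.05).
#' @param out_dir output directory, created if needed.
#' @return Object of class `run_report` (invisibly): per-stratum results and
#'   the list of files written.
#' @export
run_full_analysis <- function(config, out_dir) {
  cfg <- utils::modifyList(list(
    seed = 1, filter_threshold = 0.2, folds = 7, n_perm = 100,
    n_models = 1000, train_pairs = 9, ncomp_paired = 2, fdr = 0.10,
    qc_alpha = 0.05, sim_seed = NULL
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    files <<- c(files, name)
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", label, conditionMessage(e)))
  }

  dataset <- stage("ingest", {
    if (!is.null(cfg$dataset)) {
      stopifnot(inherits(cfg$dataset, "study_dataset"))
      cfg$dataset
    } else if (!is.null(cfg$preset)) {
      presets <- scenario_presets(seed = cfg$sim_seed %||%
                                    substream(cfg$seed, stage_offset("simulate")))
      if (!cfg$preset %in% names(presets))
        stopf("unknown preset '%s'", cfg$preset)
      generate_study(presets[[cfg$preset]])$dataset
    } else stopf("config must provide 'dataset' or 'preset'")
  })

  tissues <- unique(dataset$samples$tissue)
  groups <- unique(dataset$samples$group)

  prep <- stage("filter", {
    out <- lapply(tissues, function(ti) {
      d <- subset_samples(dataset, tissue = ti)
      prepare_log_matrix(d, threshold = cfg$filter_threshold)
    })
    names(out) <- tissues
    out
  })
  emit(lapply(prep, function(pr) list(
    threshold = pr$report$threshold,
    retained = pr$report$retained_count,
    excluded = pr$report$excluded)), "filter_report.json")

  qc <- stage("qc", {
    lapply(prep, function(pr) {
      fit <- pcaqc(scale_columns(pr$logx), ncomp = 2)
      t2 <- hotelling_t2(fit, alpha = cfg$qc_alpha)
      list(explained_proportion = fit$explained_proportion,
           t2 = as.list(t2$t2), limit = t2$limit, flagged = t2$flagged)
    })
  })
  emit(qc, "qc.json")

  opls_results <- list()
  stage("oplsda", {
    for (ti in tissues) {
      if (length(groups) < 2) stopf("group contrast needs both lighting groups")
      for (eye in unique(dataset$samples$eye)) {
        meta <- prep[[ti]]$dataset$samples
        keep <- meta$eye == eye
        if (!any(keep)) stopf("missing stratum: tissue %s, eye %s", ti, eye)
        m <- oplsda(prep[[ti]]$logx[keep, , drop = FALSE], meta$group[keep],
                    folds = cfg$folds, n_perm = cfg$n_perm,
                    seed = substream(cfg$seed, stage_offset(paste0("oplsda_", ti, "_", eye))))
        key <- sprintf("model_%s_%s", ti, eye)
        opls_results[[key]] <- m
        emit(list(n = sum(keep), classes = m$levels, R2Y = m$R2Y,
                  Q2 = m$cv$Q2, cv_anova = list(F = m$cv$cv_anova_F,
                                                p = m$cv$cv_anova_p),
                  q2p = list(median = m$permutation$median,
                             max = m$permutation$max,
                             n_perm = m$permutation$n_perm),
                  verdict = unclass(m$verdict),
                  scores = list(t_p = unname(m$t_p), t_o = unname(m$t_o[, 1])),
                  loadings = list(w_p = unname(m$w_p), p_p = unname(m$p_p))),
             paste0(key, ".json"))
      }
    }
  })

  paired_results <- list()
  stage("paired_validation", {
    for (ti in tissues) for (g in groups) {
      meta <- prep[[ti]]$dataset$samples
      keep <- meta$group == g
      if (!any(keep)) stopf("missing stratum: tissue %s, group %s", ti, g)
      v <- validate_paired(prep[[ti]]$logx[keep, , drop = FALSE],
                           meta$eye[keep], meta$subject_id[keep],
                           n_models = cfg$n_models,
                           train_pairs = cfg$train_pairs,
                           ncomp = cfg$ncomp_paired,
                           seed = substream(cfg$seed, stage_offset(paste0("paired_", ti, "_", g))),
                           positive = "FDEP")
      key <- sprintf("validation_%s_%s", ti, g)
      paired_results[[key]] <- v
      emit(list(n_models = v$scheme$n_models,
                train_pairs = v$scheme$train_pairs,
                test_pairs = v$scheme$test_pairs,
                median_auroc = v$median_auroc, median_p = v$median_p,
                satisfactory = v$satisfactory,
                aurocs = v$aurocs, pvalues = v$pvalues),
           paste0(key, ".json"))
    }
  })

  univ_results <- list()
  stage("univariate", {
    for (ti in tissues) for (g in groups) {
      d <- subset_samples(prep[[ti]]$dataset, group = g)
      res <- univariate_tests(d, contrast = "eye", fdr = cfg$fdr)
      key <- sprintf("univariate_%s_%s", ti, g)
      univ_results[[key]] <- res
      path <- file.path(out_dir, paste0(key, ".csv"))
      utils::write.csv(as.data.frame(res), path, row.names = FALSE)
      files <- c(files, paste0(key, ".csv"))
    }
    for (ti in tissues) {
      if (length(groups) == 2) {
        v <- venn_compare(univ_results[[sprintf("univariate_%s_%s", ti, groups[1])]],
                          univ_results[[sprintf("univariate_%s_%s", ti, groups[2])]],
                          name_a = groups[1], name_b = groups[2])
        emit(unclass(v), sprintf("venn_%s.json", ti))
      }
    }
  })

  report <- structure(list(
    files = files,
    opls = opls_results, paired = paired_results, univariate = univ_results,
    provenance = list(seed = cfg$seed,
                      settings = cfg[setdiff(names(cfg), "dataset")],
                      package_version = as.character(utils::packageVersion("oculomet")))
  ), class = "run_report")
  emit(list(files = files, seed = cfg$seed,
            settings = cfg[setdiff(names(cfg), "dataset")],
            package_version = report$provenance$package_version),
       "run_report.json")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d files written\n", length(x$files)))
  for (k in names(x$paired))
    cat(sprintf("  %s: median AUROC %.3f, satisfactory %s\n",
                k, x$paired[[k]]$median_auroc, x$paired[[k]]$satisfactory))
  for (k in names(x$opls))
    cat(sprintf("  %s: Q2 %.3f, verdict %s\n",
                k, x$opls[[k]]$cv$Q2, x$opls[[k]]$verdict$overall))
  invisible(x)
}
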