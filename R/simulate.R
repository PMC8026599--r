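#' Simulation configuration for paired two-eye metabolomics studies
#'
#' Describes a synthetic targeted-metabolomics study with the paired design:
#' `n_subjects_per_group` subjects per lighting group, one form-deprived
#' (FDEP) and one control eye each, sampled per tissue. Concentrations
#' follow a log10-scale model: class baseline + analyte offset +
#' tissue-specific offset + subject random intercept + eye effect (FDEP) +
#' group effect (BEW) + residual noise with exchangeable within-class
#' correlation. Effects are additive on the log10 scale, i.e.
#' multiplicative on concentrations. Values below the class LLOQ (set at a
#' quantile of the realized distribution to hit `censor_target_fraction`)
#' are censored; analytes listed in `heavy_censor_analytes` are censored at
#' `heavy_censor_fraction` of their own distribution, emulating
#' low-abundance species that the quantitation filter then removes.
#'
#' @param seed RNG seed; the generated study is bit-identical for equal
#'   seed and configuration.
#' @param n_subjects_per_group subjects per lighting group (>= 3).
#' @param groups,tissues design levels.
#' @param registry analyte panel ([p180_registry()] by default).
#' @param baseline_logmean named per-class log10 baseline (defaults span
#'   realistic micromolar ranges).
#' @param analyte_offset_sd,tissue_offset_sd SDs of per-analyte and
#'   per-analyte-per-tissue offsets (log10 units).
#' @param subject_sd SD of the subject random intercept (log10 units).
#' @param residual_sd residual SD (log10 units; 0.3 corresponds to roughly
#'   a 70% concentration CV).
#' @param class_cor exchangeable residual correlation within a class.
#' @param eye_effect named vector of log10 shifts in the FDEP eye, or a
#'   list with one such vector per group for group-dependent eye effects.
#' @param group_effect named vector of log10 shifts under BEW lighting.
#' @param censor_target_fraction target below-LLOQ fraction per class
#'   (in \[0, 0.5)).
#' @param uloq_tail upper-tail fraction flagged above ULOQ.
#' @param heavy_censor_analytes,heavy_censor_fraction analytes censored at
#'   their own `heavy_censor_fraction` quantile.
#' @return Object of class `sim_config`.
#' @seealso [generate_study()], [scenario_presets()]
#' @export
sim_config <- function(seed = 1, n_subjects_per_group = 14,
                       groups = c("SW", "BEW"),
                       tissues = c("vitreous", "retina"),
                       registry = p180_registry(),
                       baseline_logmean = NULL,
                       analyte_offset_sd = 0.4, tissue_offset_sd = 0.2,
                       subject_sd = 0.15, residual_sd = 0.3,
                       class_cor = 0.3,
                       eye_effect = numeric(0), group_effect = numeric(0),
                       censor_target_fraction = 0.05, uloq_tail = 0.005,
                       heavy_censor_analytes = character(0),
                       heavy_censor_fraction = 0.35) {
  if (!inherits(registry, "panel_registry")) registry <- panel_registry(registry)
  if (!is_count(n_subjects_per_group) || n_subjects_per_group < 3)
    stopf("n_subjects_per_group must be an integer >= 3")
  for (nm in c("analyte_offset_sd", "subject_sd", "residual_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stopf("%s must be > 0", nm)
  }
  if (tissue_offset_sd < 0) stopf("tissue_offset_sd must be >= 0")
  if (class_cor < 0 || class_cor >= 1) stopf("class_cor must be in [0, 1)")
  if (censor_target_fraction < 0 || censor_target_fraction >= 0.5)
    stopf("censor_target_fraction must be in [0, 0.5)")

  default_base <- c(acylcarnitine_free = 1.5, acylcarnitine = -0.5,
                    hexoses = 3.3, amino_acid = 2.0, biogenic_amine = 0.3,
                    lysoPC = 0.6, PC_aa = 1.3, PC_ae = 0.6,
                    sphingomyelin = 1.1)
  if (is.null(baseline_logmean)) baseline_logmean <- default_base
  baseline_logmean <- unlist(baseline_logmean)
  missing_cls <- setdiff(unique(registry$class), names(baseline_logmean))
  if (length(missing_cls))
    stopf("baseline_logmean missing class(es): %s", paste(missing_cls, collapse = ", "))

  norm_eff <- function(x) {
    if (is.list(x) && !is.null(names(x)) && all(names(x) %in% groups))
      return(lapply(x, function(v) unlist(v)))
    v <- unlist(x)
    if (length(v) == 0) v <- stats::setNames(numeric(0), character(0))
    out <- rep(list(v), length(groups)); names(out) <- groups
    out
  }
  eye_effect <- norm_eff(eye_effect)
  group_effect <- unlist(group_effect)
  if (length(group_effect) == 0) group_effect <- stats::setNames(numeric(0), character(0))
  all_eff_ids <- unique(c(unlist(lapply(eye_effect, names)), names(group_effect),
                          heavy_censor_analytes))
  unknown <- setdiff(all_eff_ids, registry$analyte_id)
  if (length(unknown))
    stopf("effect/censoring references unknown analyte(s): %s",
          paste(unknown, collapse = ", "))

  structure(list(
    seed = seed, n_subjects_per_group = n_subjects_per_group,
    groups = groups, tissues = tissues, registry = registry,
    baseline_logmean = baseline_logmean,
    analyte_offset_sd = analyte_offset_sd, tissue_offset_sd = tissue_offset_sd,
    subject_sd = subject_sd, residual_sd = residual_sd, class_cor = class_cor,
    eye_effect = eye_effect, group_effect = group_effect,
    censor_target_fraction = censor_target_fraction, uloq_tail = uloq_tail,
    heavy_censor_analytes = heavy_censor_analytes,
    heavy_censor_fraction = heavy_censor_fraction
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d subjects/group x %d groups x 2 eyes x %d tissue(s); %d analytes\n",
              x$n_subjects_per_group, length(x$groups), length(x$tissues),
              nrow(x$registry)))
  cat(sprintf("  eye-affected: %s; group-affected: %d analytes; censor target %.0f%%\n",
              paste(sprintf("%s:%d", names(x$eye_effect),
                            vapply(x$eye_effect, length, 1L)), collapse = ", "),
              length(x$group_effect), 100 * x$censor_target_fraction))
  invisible(x)
}

#' Generate a synthetic paired study
#'
#' Draws a full study dataset from a [sim_config()]: log10 concentrations
#' from the additive model, LOQ censoring per class, and the ground truth
#' needed to score downstream analyses.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [study_dataset()]) and `truth` (class
#'   `synthetic_truth`: affected analytes with signed effects per contrast,
#'   subject intercepts, class LLOQ/ULOQ on the log10 scale, realized
#'   per-analyte censoring fractions).
#' @examples
#' sim <- generate_study(scenario_presets()$strong)
#' sim$dataset
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reg <- config$registry
  p <- nrow(reg); ids <- reg$analyte_id; classes <- reg$class
  cls_levels <- unique(classes)

  with_seed(config$seed, {
    offset <- stats::rnorm(p, 0, config$analyte_offset_sd)
    tissue_offset <- lapply(config$tissues, function(t)
      stats::rnorm(p, 0, max(config$tissue_offset_sd, 1e-12)))
    names(tissue_offset) <- config$tissues
    subj_ids <- unlist(lapply(config$groups, function(g)
      sprintf("%s_S%02d", g, seq_len(config$n_subjects_per_group))))
    subj_group <- rep(config$groups, each = config$n_subjects_per_group)
    subj_int <- stats::setNames(stats::rnorm(length(subj_ids), 0, config$subject_sd),
                                subj_ids)

    samples <- do.call(rbind, lapply(config$tissues, function(ti) {
      do.call(rbind, lapply(seq_along(subj_ids), function(s) {
        data.frame(sample_id = sprintf("%s_%s_%s", subj_ids[s], c("FDEP", "control"),
                                       substr(ti, 1, 3)),
                   subject_id = subj_ids[s], eye = c("FDEP", "control"),
                   group = subj_group[s], tissue = ti,
                   stringsAsFactors = FALSE)
      }))
    }))
    n <- nrow(samples)

    eff_vec <- function(map) {
      v <- numeric(p); names(v) <- ids
      if (length(map)) v[names(map)] <- map
      v
    }
    M <- matrix(0, n, p)
    for (i in seq_len(n)) {
      row <- config$baseline_logmean[classes] + offset +
        tissue_offset[[samples$tissue[i]]] + subj_int[[samples$subject_id[i]]]
      if (samples$eye[i] == "FDEP")
        row <- row + eff_vec(config$eye_effect[[samples$group[i]]])
      if (samples$group[i] == "BEW")
        row <- row + eff_vec(config$group_effect)
      M[i, ] <- row
    }

    rho <- config$class_cor
    Zc <- matrix(stats::rnorm(n * length(cls_levels)), n, length(cls_levels))
    Zj <- matrix(stats::rnorm(n * p), n, p)
    eps <- config$residual_sd *
      (sqrt(rho) * Zc[, match(classes, cls_levels), drop = FALSE] +
         sqrt(1 - rho) * Zj)
    logc <- M + eps
  })

  conc <- 10^logc
  flags <- matrix("OK", nrow(conc), ncol(conc))
  lloq_log <- uloq_log <- stats::setNames(numeric(length(cls_levels)), cls_levels)
  for (cl in cls_levels) {
    cols <- which(classes == cl)
    pool <- logc[, cols]
    lloq_log[cl] <- stats::quantile(pool, config$censor_target_fraction)
    uloq_log[cl] <- stats::quantile(pool, 1 - config$uloq_tail)
    below <- logc[, cols, drop = FALSE] < lloq_log[cl] &
      config$censor_target_fraction > 0
    above <- logc[, cols, drop = FALSE] > uloq_log[cl]
    f <- flags[, cols, drop = FALSE]
    f[below] <- "BELOW_LLOQ"; f[above] <- "ABOVE_ULOQ"
    flags[, cols] <- f
  }
  for (id in config$heavy_censor_analytes) {
    j <- match(id, ids)
    cut <- stats::quantile(logc[, j], config$heavy_censor_fraction)
    flags[logc[, j] < cut, j] <- "BELOW_LLOQ"
  }
  conc[flags == "BELOW_LLOQ"] <- NA_real_
  over <- flags == "ABOVE_ULOQ"
  if (any(over)) {
    cap <- 10^uloq_log[classes[col(conc)[over]]]
    conc[over] <- cap
  }

  dataset <- study_dataset(conc, flags, samples, reg)
  truth <- structure(list(
    eye_effect = config$eye_effect, group_effect = config$group_effect,
    affected = list(
      eye = lapply(config$eye_effect, function(v) v[v != 0]),
      group = config$group_effect[config$group_effect != 0]),
    subject_intercepts = subj_int,
    lloq_log10 = lloq_log, uloq_log10 = uloq_log,
    realized_censor_fraction = colMeans(flags == "BELOW_LLOQ"),
    seed = config$seed
  ), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: eye-affected %s; group-affected %d; mean censoring %.1f%%\n",
              paste(sprintf("%s:%d", names(x$affected$eye),
                            vapply(x$affected$eye, length, 1L)), collapse = ", "),
              length(x$affected$group),
              100 * mean(x$realized_censor_fraction)))
  invisible(x)
}

#' Named scenario presets
#'
#' Three ready-made configurations: `null` (the study shape with no eye or
#' group effects, including a block of heavily censored low-abundance
#' analytes so that roughly 150 of 188 survive the quantitation filter),
#' `paper_like` (the same shape plus eye effects on biogenic amines and
#' amino acids under both lights, group-dependent glycerophospholipid eye
#' effects opposite in sign between lights, and lighting-group effects on
#' hexoses, lipids and amines), and `strong` (large, 1.0 log10-unit effects
#' on a small analyte set, for smoke tests and parameter-recovery checks).
#'
#' @param seed base seed stored in each preset.
#' @return Named list of [sim_config()] objects.
#' @export
scenario_presets <- function(seed = 1) {
  heavy <- c(sprintf("AC%02d", 20:39), sprintf("PC_ae_C%02d", 30:38),
             sprintf("lysoPC_C%02d", 10:14), sprintf("SM_C%02d", 12:15))

  shared_eye <- c(DOPA = 0.45, Orn = 0.45, Met_SO = 0.45, total_DMA = 0.45,
                  Arg = 0.45, Lys = 0.45, Trp = 0.45)
  bew_eye <- c(shared_eye,
               SDMA = 0.45, Serotonin = 0.45, Glu = 0.45,
               SM_C01 = 0.4, SM_C02 = 0.4, SM_C03 = 0.4,
               PC_aa_C01 = 0.4, PC_aa_C02 = 0.4, PC_ae_C01 = 0.4)
  sw_eye <- c(shared_eye,
              Taurine = 0.45, t4_OH_Pro = 0.45, Tyr = 0.45, Pro = 0.45,
              His = 0.45, Phe = 0.45, Ala = 0.45, Thr = 0.45, Val = 0.45,
              Ile = 0.45,
              PC_aa_C01 = -0.4, PC_aa_C02 = -0.4, PC_aa_C03 = -0.4,
              PC_aa_C04 = -0.4, PC_ae_C01 = -0.4, PC_ae_C02 = -0.4,
              PC_ae_C03 = -0.4)
  grp_eff <- c(H1 = 0.5,
               stats::setNames(rep(0.4, 8), sprintf("PC_aa_C%02d", 5:12)),
               stats::setNames(rep(0.4, 4), sprintf("SM_C%02d", 4:7)),
               stats::setNames(rep(-0.4, 5), sprintf("AC%02d", 1:5)),
               Putrescine = 0.35, Spermidine = 0.35, alpha_AAA = 0.35,
               Ala = 0.35, Val = 0.35, Thr = 0.35, His = 0.35, Tyr = 0.35)

  strong_eye <- stats::setNames(rep(1.0, 15),
                                c("DOPA", "Orn", "Met_SO", "total_DMA", "SDMA",
                                  "Arg", "Lys", "Trp", "Taurine", "Tyr", "Glu",
                                  "Serotonin", "PC_aa_C01", "SM_C01", "H1"))
  strong_grp <- stats::setNames(rep(1.0, 10),
                                c(sprintf("AC%02d", 1:5), sprintf("PC_aa_C%02d", 5:8),
                                  "Putrescine"))

  list(
    null = sim_config(seed = seed, heavy_censor_analytes = heavy),
    paper_like = sim_config(seed = seed,
                            eye_effect = list(SW = sw_eye, BEW = bew_eye),
                            group_effect = grp_eff,
                            heavy_censor_analytes = heavy),
    strong = sim_config(seed = seed, eye_effect = strong_eye,
                        group_effect = strong_grp,
                        censor_target_fraction = 0.02)
  )
}

#' Serialize / restore a simulation configuration
#'
#' @param config a [sim_config()].
#' @param path JSON file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  obj <- unclass(config)
  # named atomic vectors must become lists to serialize as JSON objects
  obj$baseline_logmean <- as.list(obj$baseline_logmean)
  obj$eye_effect <- lapply(obj$eye_effect, as.list)
  obj$group_effect <- as.list(obj$group_effect)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$registry <- panel_registry(as.data.frame(raw$registry))
  raw$baseline_logmean <- unlist(raw$baseline_logmean)
  raw$eye_effect <- lapply(raw$eye_effect, unlist)
  raw$group_effect <- unlist(raw$group_effect)
  raw$heavy_censor_analytes <- as.character(unlist(raw$heavy_censor_analytes))
  do.call(sim_config, raw)
}
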