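#' Per-metabolite t tests on log concentrations
#'
#' Runs a two-sided Student t test per analyte on log-transformed
#' concentrations: paired within subjects for the eye contrast
#' (form-deprived minus control), two-sample for the lighting-group contrast
#' (BEW minus SW). P-values are Benjamini-Hochberg adjusted within the
#' analysis family (one call = one tissue x contrast x stratum family) to
#' keep the false discovery rate under `fdr`.
#'
#' @param dataset a complete (imputed) [study_dataset()]; subset to the
#'   stratum of interest first, e.g.
#'   `subset_samples(d, tissue = "vitreous", group = "BEW")`.
#' @param contrast `"eye"` (paired by subject) or `"group"` (two-sample).
#' @param fdr false discovery rate (default 0.10).
#' @param log_base base of the log transform (default 10).
#' @param var_equal equal-variance (Student) two-sample test; `FALSE` gives
#'   Welch.
#' @return Object of class `univariate_result`: a data.frame with columns
#'   `analyte_id`, `class`, `mean_log_diff`, `t`, `p`, `p_adj`,
#'   `significant`, `direction`; attributes record the contrast and fdr.
#' @export
univariate_tests <- function(dataset, contrast = c("eye", "group"),
                             fdr = 0.10, log_base = 10, var_equal = TRUE) {
  contrast <- match.arg(contrast)
  logx <- log_transform(dataset$concentrations, base = log_base)
  meta <- dataset$samples
  p_analytes <- ncol(logx)
  est <- tvec <- pvec <- numeric(p_analytes)

  if (contrast == "eye") {
    if (length(unique(meta$tissue)) > 1 || length(unique(meta$group)) > 1)
      warning("eye contrast computed across mixed tissue/group strata; subset first for per-stratum families",
              call. = FALSE)
    subj <- unique(meta$subject_id)
    i_fd <- match(paste(subj, "FDEP"), paste(meta$subject_id, meta$eye))
    i_ct <- match(paste(subj, "control"), paste(meta$subject_id, meta$eye))
    if (anyNA(i_fd) || anyNA(i_ct))
      stopf("incomplete pairs: every subject needs one FDEP and one control sample")
    if (length(subj) < 3) stopf("paired test requires at least 3 pairs, got %d", length(subj))
    d <- logx[i_fd, , drop = FALSE] - logx[i_ct, , drop = FALSE]
    for (j in seq_len(p_analytes)) {
      est[j] <- mean(d[, j])
      if (stats::sd(d[, j]) < .Machine$double.eps^0.5) {
        if (abs(est[j]) < .Machine$double.eps^0.5) { tvec[j] <- 0; pvec[j] <- 1 }
        else {
          warning(sprintf("analyte '%s': zero-variance nonzero differences; p set to 0",
                          dataset$analytes$analyte_id[j]), call. = FALSE)
          tvec[j] <- sign(est[j]) * Inf; pvec[j] <- 0
        }
      } else {
        tt <- stats::t.test(d[, j])
        tvec[j] <- unname(tt$statistic); pvec[j] <- tt$p.value
      }
    }
  } else {
    g <- meta$group
    if (sum(g == "BEW") < 2 || sum(g == "SW") < 2)
      stopf("group contrast requires at least 2 samples per group")
    for (j in seq_len(p_analytes)) {
      a <- logx[g == "BEW", j]; b <- logx[g == "SW", j]
      est[j] <- mean(a) - mean(b)
      if (stats::sd(c(a - mean(a), b - mean(b))) < .Machine$double.eps^0.5) {
        if (abs(est[j]) < .Machine$double.eps^0.5) { tvec[j] <- 0; pvec[j] <- 1 }
        else {
          warning(sprintf("analyte '%s': zero within-group variance; p set to 0",
                          dataset$analytes$analyte_id[j]), call. = FALSE)
          tvec[j] <- sign(est[j]) * Inf; pvec[j] <- 0
        }
      } else {
        tt <- stats::t.test(a, b, var.equal = var_equal)
        tvec[j] <- unname(tt$statistic); pvec[j] <- tt$p.value
      }
    }
  }

  adj <- bh_adjust(pvec, q = fdr)
  out <- data.frame(
    analyte_id = dataset$analytes$analyte_id,
    class = dataset$analytes$class,
    mean_log_diff = est, t = tvec, p = pvec, p_adj = adj$adjusted,
    significant = seq_len(p_analytes) %in% adj$rejected,
    direction = ifelse(est > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  structure(out, contrast = contrast, fdr = fdr,
            class = c("univariate_result", "data.frame"))
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("Univariate %s contrast: %d analytes, %d significant at FDR %.0f%%\n",
              attr(x, "contrast"), nrow(x), sum(x$significant),
              100 * attr(x, "fdr")))
  sig <- x[x$significant, c("analyte_id", "class", "mean_log_diff", "p", "p_adj", "direction")]
  if (nrow(sig)) print(utils::head(as.data.frame(sig), 15), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment and rejection set
#'
#' Adjusted p-values come from `stats::p.adjust(method = "BH")`; the
#' rejection set is every p with adjusted value at or below `q`, which
#' coincides with the classical step-up rule (reject the `i` smallest
#' p-values where `i` is the largest index with `p_(i) <= i q / m`).
#'
#' @param p vector of p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.10).
#' @return list with `adjusted` p-values and the `rejected` index set.
#' @export
bh_adjust <- function(p, q = 0.10) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, rejected = which(adjusted <= q))
}

#' Venn-style comparison of two univariate result sets
#'
#' Partitions the significant analytes of two analyses over a common
#' universe into condition-specific and shared sets, the shared set split by
#' direction concordance (e.g. glycerophospholipids increased under one
#' light and reduced under the other appear as shared discordant).
#'
#' @param res_a,res_b [univariate_tests()] results over overlapping analyte
#'   universes.
#' @param name_a,name_b labels for reporting.
#' @return Object of class `venn_partition` with data.frames `only_A`,
#'   `only_B`, `shared_concordant`, `shared_discordant` (columns
#'   `analyte_id`, `direction` / per-side directions).
#' @export
venn_compare <- function(res_a, res_b, name_a = "A", name_b = "B") {
  common <- intersect(res_a$analyte_id, res_b$analyte_id)
  if (length(common) == 0) stopf("the two results share no analytes")
  sig_a <- res_a[res_a$significant & res_a$analyte_id %in% common, ]
  sig_b <- res_b[res_b$significant & res_b$analyte_id %in% common, ]
  shared_ids <- intersect(sig_a$analyte_id, sig_b$analyte_id)
  dir_a <- sig_a$direction[match(shared_ids, sig_a$analyte_id)]
  dir_b <- sig_b$direction[match(shared_ids, sig_b$analyte_id)]
  concord <- dir_a == dir_b
  mk <- function(ids, dirs) data.frame(analyte_id = ids, direction = dirs,
                                       stringsAsFactors = FALSE)
  structure(list(
    only_A = mk(setdiff(sig_a$analyte_id, shared_ids),
                sig_a$direction[match(setdiff(sig_a$analyte_id, shared_ids),
                                      sig_a$analyte_id)]),
    only_B = mk(setdiff(sig_b$analyte_id, shared_ids),
                sig_b$direction[match(setdiff(sig_b$analyte_id, shared_ids),
                                      sig_b$analyte_id)]),
    shared_concordant = mk(shared_ids[concord], dir_a[concord]),
    shared_discordant = data.frame(analyte_id = shared_ids[!concord],
                                   direction_A = dir_a[!concord],
                                   direction_B = dir_b[!concord],
                                   stringsAsFactors = FALSE),
    names = c(name_a, name_b)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition (%s vs %s): only %s = %d; only %s = %d; shared concordant = %d; shared discordant = %d\n",
              x$names[1], x$names[2],
              x$names[1], nrow(x$only_A), x$names[2], nrow(x$only_B),
              nrow(x$shared_concordant), nrow(x$shared_discordant)))
  invisible(x)
}
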