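#' Filter analytes by quantitation coverage
#'
#' Excludes analytes having strictly more than `threshold` (default 20%) of
#' their values out of quantitation range (below LLOQ, above ULOQ, or
#' missing). An analyte with exactly 20% out-of-range values is retained.
#' When the dataset mixes strata (e.g. both tissues), fractions are computed
#' within each stratum and an analyte is excluded only if it exceeds the
#' threshold in every stratum, so that heavy censoring in one tissue cannot
#' delete an analyte that is well quantified in the other; per-tissue
#' analyses should subset first ([subset_samples()]), which reduces this to
#' the plain rule.
#'
#' @param dataset a [study_dataset()].
#' @param threshold proportion in (0, 1]; exclusion is strict (`>`).
#' @param stratify_by metadata column defining strata (default `"tissue"`);
#'   `NULL` for a single stratum.
#' @return A list with elements `dataset` (filtered) and `report`
#'   (class `filter_report`: `excluded` data.frame with per-analyte
#'   out-of-range fractions, `retained_count`, `threshold`).
#' @export
filter_quantitation <- function(dataset, threshold = 0.20, stratify_by = "tissue") {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stopf("threshold must be a proportion in (0, 1], got %s", format(threshold))
  if (ncol(dataset$concentrations) == 0) stopf("dataset has no analytes")

  strata <- if (is.null(stratify_by)) rep("all", nrow(dataset$samples))
            else dataset$samples[[stratify_by]]
  frac <- sapply(unique(strata), function(s) {
    colMeans(dataset$flags[strata == s, , drop = FALSE] != "OK")
  })
  frac <- matrix(frac, ncol = length(unique(strata)),
                 dimnames = list(dataset$analytes$analyte_id, unique(strata)))
  # binding fraction: the smallest stratum fraction must itself exceed the
  # threshold for exclusion (single-stratum data: the plain fraction)
  binding <- apply(frac, 1, min)
  drop <- binding > threshold

  report <- structure(list(
    excluded = data.frame(analyte_id = dataset$analytes$analyte_id[drop],
                          fraction_out_of_range = unname(binding[drop]),
                          stringsAsFactors = FALSE),
    per_stratum_fraction = frac,
    retained_count = sum(!drop),
    threshold = threshold
  ), class = "filter_report")

  keep_ids <- dataset$analytes$analyte_id[!drop]
  filtered <- if (all(!drop)) dataset else
    subset_samples(dataset, analytes = keep_ids)
  list(dataset = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Quantitation filter (> %.0f%% out of range): %d excluded, %d retained\n",
              100 * x$threshold, nrow(x$excluded), x$retained_count))
  if (nrow(x$excluded)) print(utils::head(x$excluded, 10))
  invisible(x)
}

#' Impute residual out-of-range values
#'
#' After filtering, retained analytes may still carry a few below-LLOQ or
#' missing entries. The default policy replaces each with half the minimum
#' quantified (OK) value of that analyte. Above-ULOQ entries keep their
#' reported value when one is present; when the export carried no number
#' (token dialect) they are set to twice the maximum quantified value.
#'
#' @param dataset a filtered [study_dataset()].
#' @param policy `"halfmin"` (half the per-analyte minimum OK value).
#' @return A `study_dataset` with complete positive concentrations; flags are
#'   preserved as a record of which entries were imputed.
#' @export
impute_quantitation <- function(dataset, policy = c("halfmin")) {
  policy <- match.arg(policy)
  conc <- dataset$concentrations
  flags <- dataset$flags
  for (j in seq_len(ncol(conc))) {
    ok <- flags[, j] == "OK"
    fill <- flags[, j] %in% c("BELOW_LLOQ", "MISSING")
    high <- flags[, j] == "ABOVE_ULOQ" & is.na(conc[, j])
    if (!any(fill | high)) next
    if (!any(ok))
      stopf("analyte '%s' has no quantified values to impute from (should have been filtered)",
            dataset$analytes$analyte_id[j])
    if (any(fill)) conc[fill, j] <- min(conc[ok, j]) / 2
    if (any(high)) conc[high, j] <- max(conc[ok, j]) * 2
  }
  out <- dataset
  out$concentrations <- conc
  out
}

#' Element-wise log transform
#'
#' @param x numeric matrix of strictly positive values.
#' @param base 10 (default) or `exp(1)`.
#' @return The transformed matrix.
#' @export
log_transform <- function(x, base = 10) {
  x <- as.matrix(x)
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-positive or non-finite value at row %d, column %d (%s)",
          bad[1, 1], bad[1, 2],
          if (!is.null(colnames(x))) colnames(x)[bad[1, 2]] else "unnamed")
  log(x, base = base)
}

#' Column scaling with a recorded, invertible specification
#'
#' Centers each column and optionally divides by its sample standard
#' deviation (`"unit_variance"`, the default for the multivariate models) or
#' by the square root of the standard deviation (`"pareto"`).
#'
#' @param x numeric matrix with at least 2 rows.
#' @param scaling `"unit_variance"`, `"center"`, or `"pareto"`.
#' @return The scaled matrix with attributes `center`, `scale` and `scaling`
#'   (class `scaled_matrix`); see [apply_scaling()] and [unscale()].
#' @export
scale_columns <- function(x, scaling = c("unit_variance", "center", "pareto")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("scaling requires at least 2 rows")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (scaling != "center" && any(sds < .Machine$double.eps^0.5)) {
    const <- which(sds < .Machine$double.eps^0.5)
    stopf("constant column(s) cannot be %s scaled: %s", scaling,
          paste(if (!is.null(colnames(x))) colnames(x)[const] else const, collapse = ", "))
  }
  scl <- switch(scaling, center = rep(1, ncol(x)), unit_variance = sds,
                pareto = sqrt(sds))
  out <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(out, center = ctr, scale = scl, scaling = scaling,
            class = c("scaled_matrix", class(out)))
}

#' Apply a fitted scaling to new data
#'
#' @param scaled a `scaled_matrix` from [scale_columns()] (the training fit).
#' @param newx matrix with the same columns as the training matrix.
#' @return `newx` transformed with the training center and scale.
#' @export
apply_scaling <- function(scaled, newx) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(attr(scaled, "center")))
    stopf("new data has %d columns, scaling was fitted on %d",
          ncol(newx), length(attr(scaled, "center")))
  sweep(sweep(newx, 2, attr(scaled, "center")), 2, attr(scaled, "scale"), "/")
}

#' Invert a column scaling
#'
#' @param scaled a `scaled_matrix`.
#' @return The original matrix (center and scale undone).
#' @export
unscale <- function(scaled) {
  out <- sweep(sweep(unclass(scaled), 2, attr(scaled, "scale"), "*"),
               2, attr(scaled, "center"), "+")
  attr(out, "center") <- NULL; attr(out, "scale") <- NULL
  attr(out, "scaling") <- NULL
  out
}

#' Filter, impute and log-transform in one step
#'
#' The common entry into the multivariate and univariate analyses: applies
#' [filter_quantitation()], [impute_quantitation()] and [log_transform()] in
#' order.
#'
#' @param dataset a [study_dataset()], typically already subset to one
#'   tissue.
#' @param threshold quantitation filter threshold.
#' @param log_base log base (default 10).
#' @param stratify_by stratification column for the filter (default `NULL`:
#'   single stratum).
#' @return list with `logx` (log-concentration matrix), `dataset` (filtered,
#'   imputed) and `report` (the [filter_quantitation()] report).
#' @export
prepare_log_matrix <- function(dataset, threshold = 0.20, log_base = 10,
                               stratify_by = NULL) {
  filt <- filter_quantitation(dataset, threshold, stratify_by = stratify_by)
  imp <- impute_quantitation(filt$dataset)
  list(logx = log_transform(imp$concentrations, base = log_base),
       dataset = imp, report = filt$report)
}
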