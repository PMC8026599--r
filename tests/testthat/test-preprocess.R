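make_flagged_dataset <- function(n_below, n_total = 10) {
  meta <- paired_meta(n_total / 2)
  conc <- matrix(seq_len(n_total) + 1, n_total, 2)
  flags <- matrix("OK", n_total, 2)
  if (n_below > 0) {
    flags[seq_len(n_below), 1] <- "BELOW_LLOQ"
    conc[seq_len(n_below), 1] <- NA
  }
  tiny_dataset(conc, meta, flags)
}

test_that("quantitation filter excludes strictly above the threshold", {
  # 3/10 out of range (0.30) -> excluded
  res <- filter_quantitation(make_flagged_dataset(3), stratify_by = NULL)
  expect_equal(res$report$excluded$analyte_id, "A1")
  expect_equal(res$report$excluded$fraction_out_of_range, 0.3)
  expect_equal(res$report$retained_count, 1)
  expect_equal(ncol(res$dataset$concentrations), 1)

  # exactly 20% -> retained ("more than 20%" is strict)
  res <- filter_quantitation(make_flagged_dataset(2), stratify_by = NULL)
  expect_equal(nrow(res$report$excluded), 0)
  expect_equal(res$report$retained_count, 2)

  # all OK -> nothing excluded
  res <- filter_quantitation(make_flagged_dataset(0), stratify_by = NULL)
  expect_equal(nrow(res$report$excluded), 0)
})

test_that("filter threshold must be a proportion in (0, 1]", {
  d <- make_flagged_dataset(0)
  expect_error(filter_quantitation(d, threshold = 0), "proportion")
  expect_error(filter_quantitation(d, threshold = 1.2), "proportion")
  expect_no_error(filter_quantitation(d, threshold = 1))
})

test_that("filtering is idempotent and fractions match brute-force counts", {
  sim <- generate_study(scenario_presets(seed = 3)$null)
  d <- subset_samples(sim$dataset, tissue = "retina")
  res1 <- filter_quantitation(d, stratify_by = NULL)
  # brute-force per-analyte fraction on the raw flags
  frac <- colMeans(d$flags != "OK")
  expect_equal(sort(res1$report$excluded$analyte_id),
               sort(names(frac)[frac > 0.2]))
  expect_equal(res1$report$excluded$fraction_out_of_range,
               unname(frac[res1$report$excluded$analyte_id]))
  res2 <- filter_quantitation(res1$dataset, stratify_by = NULL)
  expect_equal(nrow(res2$report$excluded), 0)
  expect_equal(res2$dataset$concentrations, res1$dataset$concentrations)
})

test_that("per-stratum filtering retains analytes quantifiable in one tissue", {
  meta <- rbind(paired_meta(5, tissue = "vitreous"),
                paired_meta(5, tissue = "retina"))
  conc <- matrix(5, 20, 1)
  flags <- matrix("OK", 20, 1)
  flags[meta$tissue == "retina", 1] <- "BELOW_LLOQ"  # censored in retina only
  conc[flags == "BELOW_LLOQ"] <- NA
  d <- tiny_dataset(conc, meta, flags)
  strat <- filter_quantitation(d, stratify_by = "tissue")
  expect_equal(strat$report$retained_count, 1)   # usable in vitreous
  flat <- filter_quantitation(d, stratify_by = NULL)
  expect_equal(flat$report$retained_count, 0)    # 50% overall: gone
})

test_that("half-minimum imputation fills residual censored values", {
  meta <- paired_meta(2)[1:3, ]
  meta$tissue[3] <- "retina"  # keep (subject, eye, tissue) unique
  conc <- matrix(c(4, 2, NA), 3, 1)
  flags <- matrix(c("OK", "OK", "BELOW_LLOQ"), 3, 1)
  d <- tiny_dataset(conc, meta, flags)
  imp <- impute_quantitation(d)
  expect_equal(unname(imp$concentrations[3, 1]), 1.0)  # min(4,2)/2

  # no out-of-range values: identity
  d0 <- tiny_dataset(matrix(c(4, 2, 3), 3, 1), meta)
  expect_equal(impute_quantitation(d0)$concentrations, d0$concentrations)

  # analyte with zero quantified values: error
  dbad <- tiny_dataset(matrix(NA_real_, 3, 1), meta,
                       matrix("BELOW_LLOQ", 3, 1))
  expect_error(impute_quantitation(dbad), "no quantified values")
})

test_that("log transform is exact and rejects non-positive cells", {
  expect_equal(log_transform(matrix(c(1, 100), 1, 2))[1, ], c(0, 2))
  expect_equal(log_transform(matrix(exp(2)), base = exp(1))[1, 1], 2)
  expect_error(log_transform(matrix(c(1, -1), 1, 2)), "row 1, column 2")
})

test_that("column scaling matches its definition and inverts exactly", {
  x <- matrix(c(1, 2, 3, 10, 20, 40), 3, 2)
  ctr <- scale_columns(x, "center")
  expect_equal(unname(ctr[, 1]), c(-1, 0, 1))
  uv <- scale_columns(x, "unit_variance")
  expect_equal(unname(colMeans(uv)), c(0, 0))
  expect_equal(unname(apply(uv, 2, sd)), c(1, 1))
  par <- scale_columns(x, "pareto")
  expect_equal(unname(apply(par, 2, sd)), sqrt(apply(x, 2, sd)))
  for (s in c("center", "unit_variance", "pareto"))
    expect_equal(unscale(scale_columns(x, s)), x, ignore_attr = TRUE)
  xc <- cbind(x, 5)
  expect_error(scale_columns(xc, "unit_variance"), "constant column")
  expect_error(scale_columns(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("unit-variance scaling absorbs the log base", {
  set.seed(4)
  x <- matrix(rlnorm(60), 12, 5)
  s10 <- scale_columns(log_transform(x, 10), "unit_variance")
  se <- scale_columns(log_transform(x, exp(1)), "unit_variance")
  expect_lt(max(abs(s10 - se)), 1e-10)
})

test_that("training scaling applies unchanged to new data", {
  set.seed(5)
  x <- matrix(rnorm(40), 8, 5)
  s <- scale_columns(x)
  expect_equal(apply_scaling(s, x), unclass(s), ignore_attr = TRUE)
  xnew <- matrix(rnorm(10), 2, 5)
  manual <- sweep(sweep(xnew, 2, attr(s, "center")), 2, attr(s, "scale"), "/")
  expect_equal(apply_scaling(s, xnew), manual)
})
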