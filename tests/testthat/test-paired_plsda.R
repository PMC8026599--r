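test_that("within-subject decomposition splits and reconstructs the matrix", {
  # one analyte, one subject with values 1 and 3
  x <- matrix(c(1, 3), 2, 1)
  dec <- within_subject_split(x, c("s1", "s1"))
  expect_equal(unname(dec$within[, 1]), c(-1, 1))

  set.seed(51)
  rp <- random_paired(6, 4)
  dec <- within_subject_split(rp$x, rp$subject)
  # per-subject within rows sum to zero
  sums <- rowsum(dec$within, rp$subject)
  expect_lt(max(abs(sums)), 1e-12)
  # between + within + grand mean reconstructs X
  rec <- dec$between + dec$within +
    matrix(dec$grand_mean, nrow(rp$x), ncol(rp$x), byrow = TRUE)
  expect_equal(rec, rp$x, ignore_attr = TRUE)

  expect_error(within_subject_split(rp$x[-1, ], rp$subject[-1]),
               "exactly 2 samples")
})

test_that("within matrix agrees with the mixOmics multilevel decomposition", {
  skip_if_not_installed("mixOmics")
  set.seed(52)
  rp <- random_paired(8, 6)
  dec <- within_subject_split(rp$x, rp$subject)
  mo <- mixOmics::withinVariation(rp$x, design = data.frame(
    sample = as.integer(factor(rp$subject))))
  expect_equal(unname(dec$within), unname(as.matrix(mo)), tolerance = 1e-10)
})

test_that("multilevel PLS-DA learns a within-pair effect and not its absence", {
  set.seed(53)
  rp <- random_paired(14, 150, delta = 2, n_affected = 10)
  fit <- mlplsda(rp$x, rp$y, rp$subject)
  expect_gt(fit$fit$R2Y, 0.5)

  # exactly orthogonal construction: no within-pair signal for one LV
  x0 <- random_paired(10, 8)$x
  y0 <- rep(c("FDEP", "control"), 10)
  subj0 <- rep(sprintf("S%02d", 1:10), each = 2)
  dec <- within_subject_split(x0, subj0)
  yc <- ifelse(y0 == "FDEP", 1, -1)
  w0 <- dec$within - yc %*% crossprod(yc, dec$within) / sum(yc^2)
  w0 <- w0 + matrix(rnorm(length(w0), sd = 1e-8), nrow(w0))
  xr <- w0 + (x0 - dec$within)   # rebuild full matrix with null within part
  fit0 <- mlplsda(xr, y0, subj0, ncomp = 1, scaling = "center")
  expect_lt(fit0$fit$R2Y, 1e-5)

  expect_error(mlplsda(rp$x[-1, ], rp$y[-1], rp$subject[-1]), "exactly 2")
})

test_that("AUROC equals the Mann-Whitney pair count with ties at one half", {
  expect_equal(auroc(c(1, 2, 10, 11), c("n", "n", "p", "p"), positive = "p"), 1)
  # class0 {1,2,3} vs class1 {2.5,3.5}: 5 of 6 pairs ordered
  expect_equal(auroc(c(1, 2, 3, 2.5, 3.5), c(0, 0, 0, 1, 1), positive = "1"),
               5 / 6)
  # tie counted one half
  expect_equal(auroc(c(1, 1), c("n", "p"), positive = "p"), 0.5)
  expect_error(auroc(1:3, c("p", "p", "p")), "two levels")

  set.seed(54)
  scores <- rnorm(2000)
  labels <- rep(c("x", "y"), 1000)
  expect_equal(auroc(scores, labels, positive = "y"), 0.5, tolerance = 0.05)
})

test_that("paired p-value matches the direct t formula and handles degeneracy", {
  scores <- c(0.8, 0.1, -0.2, 0.3, 0.6, 0.5, -0.1, 0.0, 0.25, 0.2)
  labels <- rep(c("FDEP", "control"), 5)
  subj <- rep(sprintf("S%d", 1:5), each = 2)
  d <- scores[labels == "FDEP"] - scores[labels == "control"]
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(auroc_pvalue(scores, labels, subj, positive = "FDEP"),
               2 * pt(abs(tstat), 4, lower.tail = FALSE), tolerance = 1e-12)
  # constant nonzero differences: p = 0 with a warning
  expect_warning(
    p0 <- auroc_pvalue(c(1, 0, 2, 1, 3, 2), rep(c("FDEP", "control"), 3),
                       rep(c("a", "b", "c"), each = 2), positive = "FDEP"),
    "constant")
  expect_equal(p0, 0)
  expect_error(auroc_pvalue(c(1, 0), c("FDEP", "control"), c("a", "a"),
                            positive = "FDEP"), "2 pairs")
})

test_that("test scores from mlplsda give the same AUROC as pROC", {
  skip_if_not_installed("pROC")
  set.seed(55)
  rp <- random_paired(14, 30, delta = 1, n_affected = 5)
  tr <- rp$subject %in% sprintf("S%02d", 1:9)
  fit <- mlplsda(rp$x[tr, ], rp$y[tr], rp$subject[tr])
  sc <- predict(fit, rp$x[!tr, ], rp$subject[!tr])
  ours <- auroc(sc, rp$y[!tr], positive = "FDEP")
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(rp$y[!tr], sc, levels = c("control", "FDEP"),
              direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("resampling validation is deterministic and never splits a pair", {
  set.seed(56)
  rp <- random_paired(14, 40, delta = 1.5, n_affected = 8)
  v1 <- validate_paired(rp$x, rp$y, rp$subject, n_models = 60, seed = 4,
                        positive = "FDEP")
  v2 <- validate_paired(rp$x, rp$y, rp$subject, n_models = 60, seed = 4,
                        positive = "FDEP")
  expect_identical(v1$aurocs, v2$aurocs)
  expect_identical(v1$pvalues, v2$pvalues)
  # pair integrity: both eyes of every training subject stay together,
  # so the 9 allocated subjects account for all 18 training samples
  expect_true(all(!is.na(v1$allocations)))
  expect_true(all(apply(v1$allocations, 1,
                        function(s) length(unique(s)) == 9)))
})

test_that("a strong within-pair effect validates; its absence does not", {
  set.seed(57)
  rp <- random_paired(14, 100, delta = 3, n_affected = 15)
  v <- validate_paired(rp$x, rp$y, rp$subject, n_models = 120, seed = 8,
                       positive = "FDEP")
  expect_true(v$satisfactory)
  expect_gte(v$median_auroc, 0.8)

  # per-resample label exchange (coin flip per subject) recenters the
  # median AUROC at one half even for a fixed dataset
  set.seed(58)
  au <- replicate(250, {
    flip <- sample(c(TRUE, FALSE), 14, replace = TRUE)
    y <- rp$y
    for (s in which(flip)) {
      i <- which(rp$subject == sprintf("S%02d", s))
      y[i] <- rev(y[i])
    }
    tr <- rp$subject %in% sprintf("S%02d", sample(14, 9))
    fit <- mlplsda(rp$x[tr, ], y[tr], rp$subject[tr])
    auroc(predict(fit, rp$x[!tr, ], rp$subject[!tr]), y[!tr],
          positive = "FDEP")
  })
  expect_equal(median(au), 0.5, tolerance = 0.05)
})
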