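# Direct re-derivation of the one-component PLS weight/score/prediction,
# used as an independent oracle against the package's NIPALS path.
oracle_pls1 <- function(xtr, ytr, xte) {
  ctr <- colMeans(xtr)
  xs <- sweep(xtr, 2, ctr)
  ym <- mean(ytr)
  yc <- ytr - ym
  w <- drop(crossprod(xs, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(xs %*% w)
  cc <- sum(yc * t) / sum(t^2)
  drop(sweep(xte, 2, ctr) %*% (w * cc)) + ym
}

test_that("first PLS weight is proportional to X'y", {
  set.seed(31)
  x <- matrix(rnorm(18), 6, 3)
  y <- c("a", "a", "a", "b", "b", "b")
  fit <- plsda(x, y, ncomp = 1, scaling = "center")
  xs <- sweep(x, 2, colMeans(x))
  yc <- ifelse(y == "b", 1, -1); yc <- yc - mean(yc)
  w_direct <- drop(crossprod(xs, yc))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_equal(abs(drop(fit$W[, 1])), abs(w_direct), tolerance = 1e-10)
})

test_that("a single y-aligned column dominates the weight vector", {
  set.seed(32)
  y <- rep(c(-1, 1), each = 8)
  x <- matrix(rnorm(16 * 5), 16, 5)
  x[, 3] <- y * 3 + rnorm(16, sd = 0.1)
  fit <- plsda(x, y, ncomp = 1)
  expect_equal(which.max(abs(fit$W[, 1])), 3L)
})

test_that("degenerate responses are rejected", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(plsda(x, rep("a", 5)), "two levels")
  expect_error(oplsda(x, rep(1, 5), validate = FALSE), "two levels")
})

test_that("OPLS with 1+1 components reproduces the 2-component PLS fit", {
  set.seed(33)
  for (r in 1:25) {
    n <- sample(8:16, 1); p <- sample(4:12, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- sample(rep(c("g1", "g2"), length.out = n))
    if (length(unique(y)) < 2) next
    o <- oplsda(x, y, n_ortho = 1, validate = FALSE)
    p2 <- plsda(x, y, ncomp = 2)
    expect_lt(max(abs(o$fitted - fitted(p2))), 1e-8)
  }
})

test_that("the orthogonal score carries no class information", {
  set.seed(34)
  x <- matrix(rnorm(20 * 8), 20, 8)
  y <- rep(c("a", "b"), 10)
  o <- oplsda(x, y, validate = FALSE)
  yc <- o$y - mean(o$y)
  expect_lt(abs(cor(o$t_o[, 1], yc)), 1e-8)
})

test_that("a response-orthogonal matrix yields near-zero R2Y", {
  set.seed(35)
  n <- 12
  y <- rep(c(-1, 1), n / 2)
  yc <- y - mean(y)
  x <- matrix(rnorm(n * 6), n, 6)
  x <- sweep(x, 2, colMeans(x))
  x <- x - yc %*% crossprod(yc, x) / sum(yc^2)  # exact orthogonal part
  x <- x + matrix(rnorm(n * 6, sd = 1e-8), n, 6)  # break exact degeneracy
  fit <- plsda(x, y, ncomp = 1, scaling = "center")
  expect_lt(fit$R2Y, 1e-6)
})

test_that("leave-one-out PRESS matches an explicit refit loop", {
  set.seed(36)
  x <- matrix(rnorm(18), 6, 3)
  y <- c("a", "b", "a", "b", "a", "b")
  cv <- cv_q2(x, y, n_ortho = 0, K = 6, seed = 9, scaling = "center")
  yn <- ifelse(y == "b", 1, -1)
  press <- 0
  for (i in 1:6) {
    yhat <- oracle_pls1(x[-i, ], yn[-i], x[i, , drop = FALSE])
    press <- press + (yn[i] - yhat)^2
  }
  expect_equal(cv$PRESS, press, tolerance = 1e-10)
  expect_equal(cv$Q2, 1 - press / sum((yn - mean(yn))^2), tolerance = 1e-10)
})

test_that("separated classes give Q2 above 0.5 and significant CV-ANOVA", {
  set.seed(37)
  n <- 28; p <- 150
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c("SW", "BEW"), each = 14)
  x[y == "BEW", 1:10] <- x[y == "BEW", 1:10] + 3
  cv <- cv_q2(x, y, n_ortho = 1, K = 7, seed = 2)
  expect_gt(cv$Q2, 0.5)
  expect_lt(cv$cv_anova_p, 0.05)
  # permutations on the same data: median Q2p negative, below Q2c
  pm <- permutation_q2(x, y, n_perm = 50, seed = 2)
  expect_lt(pm$median, 0)
  expect_lt(pm$median, cv$Q2)
})

test_that("CV-ANOVA reduces to the null when PRESS reaches SS", {
  an <- cv_anova(press = 10, ss = 10, n = 20, ncomp = 2)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  an2 <- cv_anova(press = 12, ss = 10, n = 20, ncomp = 2)
  expect_equal(an2$p, 1)
  expect_error(cv_anova(5, 10, n = 3, ncomp = 2), "degrees of freedom")
})

test_that("permutation Q2 is seed-reproducible and guards n_perm", {
  set.seed(38)
  x <- matrix(rnorm(16 * 6), 16, 6)
  y <- rep(c("a", "b"), 8)
  p1 <- permutation_q2(x, y, n_perm = 20, seed = 5)
  p2 <- permutation_q2(x, y, n_perm = 20, seed = 5)
  expect_identical(p1$q2p, p2$q2p)
  expect_error(permutation_q2(x, y, n_perm = 5), "at least 20")
})

test_that("cross-validation re-estimates scaling inside folds", {
  # one column whose variance is carried by two extreme samples: global
  # scaling leaks their spread into folds that exclude them
  set.seed(39)
  n <- 14
  x <- matrix(rnorm(n * 4), n, 4)
  x[1:2, 2] <- c(40, -40)
  y <- rep(c("a", "b"), 7)
  cv <- cv_q2(x, y, n_ortho = 0, K = 7, seed = 3)
  xg <- scale_columns(x)
  # naive CV with the globally scaled matrix, same folds
  press_naive <- 0
  for (k in sort(unique(cv$fold_assignment))) {
    tr <- cv$fold_assignment != k
    yn <- ifelse(y == "b", 1, -1)
    yhat <- oracle_pls1(unclass(xg)[tr, ], yn[tr],
                        unclass(xg)[!tr, , drop = FALSE])
    press_naive <- press_naive + sum((yn[!tr] - yhat)^2)
  }
  expect_gt(abs(press_naive - cv$PRESS) / cv$PRESS, 1e-4)
})

test_that("cross-validated Q2 does not beat the training fit on average", {
  set.seed(40)
  gaps <- replicate(40, {
    x <- matrix(rnorm(20 * 10), 20, 10)
    y <- rep(c("a", "b"), 10)
    m <- plsda(x, y, ncomp = 2)
    cv <- cv_q2(x, y, n_ortho = 1, K = 5, seed = 1)
    m$R2Y - cv$Q2
  })
  expect_gt(mean(gaps), 0)
})

test_that("the overfitting verdict applies the three printed criteria", {
  v <- assess_overfitting(q2 = 0.56, q2p_median = -0.2, cv_p = 5e-4)
  expect_true(v$overall)
  expect_false(assess_overfitting(q2 = 0.4, q2p_median = -0.2, cv_p = 1e-3)$overall)
  expect_false(assess_overfitting(q2 = 0.7, q2p_median = 0.1, cv_p = 1e-3)$q2p_pass)
  expect_false(assess_overfitting(q2 = 0.7, q2p_median = -0.1, cv_p = 0.2)$overall)
  # populated from a validated model
  set.seed(41)
  x <- matrix(rnorm(20 * 8), 20, 8)
  y <- rep(c("a", "b"), 10)
  m <- oplsda(x, y, n_perm = 20, seed = 1)
  expect_s3_class(m$verdict, "overfit_verdict")
  expect_equal(m$verdict$overall,
               m$verdict$q2c_pass && m$verdict$q2p_pass && m$verdict$cvanova_pass)
  expect_error(assess_overfitting(oplsda(x, y, validate = FALSE)), "diagnostics")
})
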