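# Cross-validation, CV-ANOVA and permutation diagnostics for the
# discriminant models.

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin over K folds, so no training fold can lose a class as
# long as each class has at least 2 members.
make_folds <- function(y, K) {
  fold <- integer(length(y))
  nxt <- 0L
  for (lev in unique(y)) {
    idx <- which(y == lev)
    if (length(idx) < 2)
      stopf("class '%s' has fewer than 2 samples; cannot stratify folds", lev)
    ord <- idx[sample.int(length(idx))]
    fold[ord] <- ((nxt + seq_along(ord) - 1L) %% K) + 1L
    nxt <- nxt + length(ord)
  }
  fold
}

#' Cross-validated Q2 for a (O)PLS-DA model
#'
#' K-fold cross-validation of the full modelling pipeline: inside each
#' training fold the column scaling is re-estimated, the model refitted, and
#' the held-out samples predicted with the training transform. Q2 is
#' `1 - PRESS/SS` where PRESS accumulates squared held-out prediction errors
#' of the -1/+1 class code and SS is the total (mean-centered) response sum
#' of squares. The CV-ANOVA F test of the improvement over the null
#' (mean-only) model is attached.
#'
#' @param x raw (unscaled, typically log) matrix.
#' @param y two-level class vector.
#' @param n_ortho orthogonal components (0 for plain PLS-DA with one LV).
#' @param K number of folds (default 7), `2 <= K <= n`.
#' @param seed seed for the stratified fold shuffle.
#' @param scaling column scaling re-estimated per fold.
#' @return Object of class `cv_result`: `Q2`, `PRESS`, `SS`, `folds`,
#'   `cv_anova_F`, `cv_anova_p`, `fold_assignment`, `ncomp_total`.
#' @export
cv_q2 <- function(x, y, n_ortho = 1, K = 7, seed = 1,
                  scaling = c("unit_variance", "center", "pareto")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  cls <- code_classes(y)
  n <- nrow(x)
  if (!is_count(K) || K < 2 || K > n)
    stopf("K must be an integer in [2, %d]", n)
  fold <- with_seed(seed, make_folds(cls$y, K))
  press <- 0
  for (k in sort(unique(fold))) {
    tr <- fold != k; te <- !tr
    if (length(unique(cls$y[tr])) < 2)
      stopf("training fold %d lost a class; use fewer folds", k)
    xs <- scale_columns(x[tr, , drop = FALSE], scaling)
    ym <- mean(cls$y[tr])
    if (n_ortho > 0) {
      core <- fit_opls_core(unclass(xs), cls$y[tr] - ym, n_ortho)
      xte <- apply_scaling(xs, x[te, , drop = FALSE])
      for (j in seq_len(n_ortho)) {
        to <- xte %*% core$Wo[, j]
        xte <- xte - tcrossprod(to, core$Po[, j])
      }
      yhat <- drop(xte %*% core$pls$b) + ym
    } else {
      core <- fit_pls1_core(unclass(xs), cls$y[tr] - ym, 1)
      xte <- apply_scaling(xs, x[te, , drop = FALSE])
      yhat <- drop(xte %*% core$b) + ym
    }
    press <- press + sum((cls$y[te] - yhat)^2)
  }
  ss <- sum((cls$y - mean(cls$y))^2)
  ncomp_total <- max(1, n_ortho + 1)
  an <- cv_anova(press, ss, n, ncomp_total)
  structure(list(Q2 = 1 - press / ss, PRESS = press, SS = ss, folds = K,
                 cv_anova_F = an$F, cv_anova_p = an$p,
                 fold_assignment = fold, ncomp_total = ncomp_total),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: Q2 = %.3f (PRESS = %.2f, SS = %.2f); CV-ANOVA F = %.2f, p = %.3g\n",
              x$folds, x$Q2, x$PRESS, x$SS, x$cv_anova_F, x$cv_anova_p))
  invisible(x)
}

#' CV-ANOVA significance test
#'
#' F test of the cross-validated predictive residuals against the total
#' response variation: `F = ((SS - PRESS)/d1) / (PRESS/d2)` with `d1 = A`
#' (total latent variables) and `d2 = n - 1 - A`; the p-value is the upper
#' tail of `F(d1, d2)`. A model no better than the mean (`PRESS >= SS`) is
#' reported as `F = 0, p = 1`.
#'
#' @param press cross-validated predictive residual sum of squares.
#' @param ss total response sum of squares.
#' @param n number of samples.
#' @param ncomp total number of latent variables (predictive + orthogonal).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
cv_anova <- function(press, ss, n, ncomp) {
  d1 <- ncomp
  d2 <- n - 1 - ncomp
  if (d2 <= 0) stopf("CV-ANOVA degrees of freedom d2 = %d <= 0", d2)
  if (ss <= press) return(list(F = 0, p = 1, df1 = d1, df2 = d2))
  f <- ((ss - press) / d1) / (press / d2)
  list(F = f, p = stats::pf(f, d1, d2, lower.tail = FALSE), df1 = d1, df2 = d2)
}

#' Q2 distribution under response permutation
#'
#' Recomputes the cross-validated Q2 after permuting the class labels while
#' keeping the data matrix fixed, `n_perm` times. A well-behaved model has a
#' clearly negative median permuted Q2: permuted labels should predict worse
#' than the mean.
#'
#' @inheritParams cv_q2
#' @param n_perm number of permutations (minimum 20).
#' @return Object of class `perm_result`: `q2p` (length `n_perm`),
#'   `n_perm`, `median`, `max`.
#' @export
permutation_q2 <- function(x, y, n_ortho = 1, K = 7, n_perm = 100, seed = 1,
                           scaling = c("unit_variance", "center", "pareto")) {
  scaling <- match.arg(scaling)
  if (!is_count(n_perm) || n_perm < 20)
    stopf("n_perm must be at least 20 for a usable permutation distribution")
  y <- as.character(y)
  q2p <- vapply(seq_len(n_perm), function(k) {
    yp <- with_seed(substream(seed, k), sample(y))
    cv_q2(x, yp, n_ortho = n_ortho, K = K,
          seed = substream(seed, n_perm + k), scaling = scaling)$Q2
  }, numeric(1))
  structure(list(q2p = q2p, n_perm = n_perm,
                 median = stats::median(q2p), max = max(q2p)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation Q2 (n = %d): median %.3f, max %.3f\n",
              x$n_perm, x$median, x$max))
  invisible(x)
}

#' Overfitting verdict for a validated OPLS-DA model
#'
#' Applies the three-way rule for a trustworthy discriminant model:
#' cross-validated Q2 above 0.5, negative median permuted Q2, and CV-ANOVA
#' p below 0.05; the overall verdict is their conjunction.
#'
#' @param model a validated [oplsda()] object, or `NULL` when the individual
#'   quantities are supplied directly.
#' @param q2,q2p_median,cv_p the diagnostics, taken from `model` when given.
#' @return Object of class `overfit_verdict` with logical fields `q2c_pass`,
#'   `q2p_pass`, `cvanova_pass`, `overall`.
#' @export
assess_overfitting <- function(model = NULL, q2 = NULL, q2p_median = NULL,
                               cv_p = NULL) {
  if (!is.null(model)) {
    if (is.null(model$cv) || is.null(model$permutation))
      stopf("model has no cross-validation/permutation diagnostics; refit with validate = TRUE")
    q2 <- model$cv$Q2
    q2p_median <- stats::median(model$permutation$q2p)
    cv_p <- model$cv$cv_anova_p
  }
  if (is.null(q2) || is.null(q2p_median) || is.null(cv_p))
    stopf("supply a validated model or all of q2, q2p_median, cv_p")
  v <- list(q2c_pass = q2 > 0.5,
            q2p_pass = q2p_median < 0,
            cvanova_pass = cv_p < 0.05)
  v$overall <- v$q2c_pass && v$q2p_pass && v$cvanova_pass
  structure(v, class = "overfit_verdict")
}

#' @export
print.overfit_verdict <- function(x, ...) {
  cat(sprintf("Q2 > 0.5: %s | median permuted Q2 < 0: %s | CV-ANOVA p < 0.05: %s => %s\n",
              x$q2c_pass, x$q2p_pass, x$cvanova_pass,
              if (x$overall) "PASS" else "FAIL"))
  invisible(x)
}
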