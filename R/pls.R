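# Single-response PLS and OPLS cores. Matrices arriving here are already
# column-centered/scaled and the response is centered; the exported fitting
# functions own the preprocessing and keep its parameters for prediction.

# NIPALS recursion for one response: w = X'y/||X'y||; t = Xw; p = X't/(t't);
# c = y't/(t't); deflate X <- X - t p'. Weight signs fixed so the
# largest-magnitude element is positive.
fit_pls1_core <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); cvec <- numeric(ncomp)
  Xd <- X
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stopf("no residual X-y covariance at component %d; ncomp exceeds the predictive rank", a)
    w <- w / nw
    piv <- which.max(abs(w))
    if (w[piv] < 0) w <- -w
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12)
      stopf("degenerate score at component %d (rank deficiency)", a)
    pv <- crossprod(Xd, t) / tt
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t
    cvec[a] <- sum(y * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
  }
  b <- W %*% solve(crossprod(P, W), cvec)
  fitted <- drop(X %*% b)
  list(W = W, P = P, C = cvec, scores = Tm, b = drop(b), fitted = fitted,
       R2Y = 1 - sum((y - fitted)^2) / sum(y^2))
}

# Orthogonal-signal-correction step(s) followed by a 1-component PLS fit.
# Per orthogonal component: from the PLS weight w of the current matrix,
# p = X't/(t't); w_o = p - (w'p)w normalized; t_o = X w_o;
# p_o = X't_o/(t_o't_o); deflate X <- X - t_o p_o'.
fit_opls_core <- function(X, y, n_ortho) {
  p <- ncol(X); n <- nrow(X)
  Wo <- matrix(0, p, n_ortho); Po <- matrix(0, p, n_ortho)
  To <- matrix(0, n, n_ortho)
  Xd <- X
  for (j in seq_len(n_ortho)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stopf("no X-y covariance; cannot extract orthogonal component %d", j)
    w <- w / nw
    t <- Xd %*% w
    pv <- crossprod(Xd, t) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stopf("no orthogonal variation left at component %d", j)
    wo <- wo / nwo
    piv <- which.max(abs(wo))
    if (wo[piv] < 0) wo <- -wo
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    Wo[, j] <- wo; Po[, j] <- po; To[, j] <- to
    Xd <- Xd - tcrossprod(to, po)
  }
  pls <- fit_pls1_core(Xd, y, 1)
  list(Wo = Wo, Po = Po, To = To, pls = pls, Xd = Xd)
}

# Map a two-level class vector to {-1, +1} with recorded levels
# (first sorted level -> -1, second -> +1).
code_classes <- function(y, levels = NULL) {
  yc <- as.character(y)
  lev <- levels %||% sort(unique(yc), method = "radix")
  if (length(lev) != 2 || !all(yc %in% lev))
    stopf("response must take exactly two levels, got: %s",
          paste(unique(yc), collapse = ", "))
  if (length(unique(yc)) != 2) stopf("both classes must be present")
  list(y = ifelse(yc == lev[2], 1, -1), levels = lev)
}

#' PLS discriminant analysis (single response)
#'
#' Fits a PLS-DA model by the NIPALS recursion on a class indicator coded
#' -1/+1. Columns are centered and scaled internally (the scaling is stored
#' and re-applied by `predict`).
#'
#' @param x numeric matrix, samples x analytes (typically log
#'   concentrations).
#' @param y two-level class vector (factor, character, or -1/+1).
#' @param ncomp number of latent variables.
#' @param scaling column scaling passed to [scale_columns()].
#' @return Object of class `plsda` with weights `W`, loadings `P`,
#'   y-loadings `C`, `scores`, regression vector `b`, `R2Y`, class coding.
#' @seealso [oplsda()] for the orthogonalized variant and its overfitting
#'   diagnostics; [mlplsda()] for paired samples.
#' @export
plsda <- function(x, y, ncomp = 2,
                  scaling = c("unit_variance", "center", "pareto")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  cls <- code_classes(y)
  if (!is_count(ncomp) || ncomp < 1) stopf("ncomp must be a positive integer")
  xs <- scale_columns(x, scaling)
  ym <- mean(cls$y)
  fit <- fit_pls1_core(unclass(xs), cls$y - ym, ncomp)
  structure(c(fit, list(scaling = xs, y_mean = ym, levels = cls$levels,
                        y = cls$y, ncomp = ncomp)),
            class = "plsda")
}

#' @export
predict.plsda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  xs <- apply_scaling(object$scaling, newdata)
  yhat <- drop(xs %*% object$b) + object$y_mean
  if (type == "score") yhat
  else object$levels[(yhat > 0) + 1L]
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d latent variable(s), %d samples x %d variables\n",
              x$ncomp, nrow(x$scores), length(x$b)))
  cat(sprintf("  classes: %s (-1) vs %s (+1); R2Y = %.3f\n",
              x$levels[1], x$levels[2], x$R2Y))
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$b

#' @export
fitted.plsda <- function(object, ...) object$fitted + object$y_mean

#' @export
residuals.plsda <- function(object, ...) object$y - fitted(object)

#' Orthogonal PLS discriminant analysis with overfitting diagnostics
#'
#' Fits an OPLS-DA model for independent samples: one predictive latent
#' variable plus `n_ortho` (default 1, i.e. a two-LV model) orthogonal
#' components that capture class-uncorrelated variation. By default the fit
#' is accompanied by the full overfitting-control stack: K-fold
#' cross-validated Q2 with scaling re-estimated inside each training fold,
#' the CV-ANOVA F test against the null model, and the distribution of Q2
#' under response permutation. A model is considered trustworthy when
#' Q2 > 0.5, the median permuted Q2 is negative, and CV-ANOVA p < 0.05
#' (see [assess_overfitting()]).
#'
#' @param x numeric matrix (samples x analytes), typically log
#'   concentrations; scaling is performed internally.
#' @param y two-level class vector.
#' @param n_ortho number of orthogonal latent variables (default 1).
#' @param scaling column scaling (default unit variance).
#' @param validate run cross-validation, CV-ANOVA and permutation testing.
#' @param folds number of CV folds (default 7, stratified by class).
#' @param n_perm number of response permutations (default 100; minimum 20).
#' @param seed seed for fold assignment and permutations.
#' @return Object of class `oplsda`: predictive block (`w_p`, `p_p`, `t_p`,
#'   `c_p`), orthogonal block (`w_o`, `p_o`, `t_o`), regression vector `b`,
#'   `R2Y`, and (when validated) `cv` ([cv_q2()] result), `permutation`
#'   ([permutation_q2()] result) and `verdict` ([assess_overfitting()]).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(28 * 40), 28, 40)
#' grp <- rep(c("SW", "BEW"), each = 14)
#' x[grp == "BEW", 1:5] <- x[grp == "BEW", 1:5] + 2
#' m <- oplsda(x, grp, n_perm = 20)
#' m$verdict$overall
#' @export
oplsda <- function(x, y, n_ortho = 1,
                   scaling = c("unit_variance", "center", "pareto"),
                   validate = TRUE, folds = 7, n_perm = 100, seed = 1) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  cls <- code_classes(y)
  if (!is_count(n_ortho) || n_ortho < 1) stopf("n_ortho must be a positive integer")
  xs <- scale_columns(x, scaling)
  ym <- mean(cls$y)
  core <- fit_opls_core(unclass(xs), cls$y - ym, n_ortho)
  fitted <- core$pls$fitted + ym
  obj <- structure(list(
    w_p = core$pls$W[, 1], p_p = core$pls$P[, 1], t_p = core$pls$scores[, 1],
    c_p = core$pls$C[1], w_o = core$Wo, p_o = core$Po, t_o = core$To,
    b = core$pls$b, R2Y = core$pls$R2Y, fitted = fitted,
    n_ortho = n_ortho, scaling = xs, scaling_type = scaling,
    y_mean = ym, levels = cls$levels, y = cls$y,
    cv = NULL, permutation = NULL, verdict = NULL
  ), class = "oplsda")
  if (validate) {
    obj$cv <- cv_q2(x, y, n_ortho = n_ortho, K = folds, seed = seed,
                    scaling = scaling)
    obj$permutation <- permutation_q2(x, y, n_ortho = n_ortho, K = folds,
                                      n_perm = n_perm, seed = seed,
                                      scaling = scaling)
    obj$verdict <- assess_overfitting(obj)
  }
  obj
}

#' @export
predict.oplsda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  xs <- apply_scaling(object$scaling, newdata)
  for (j in seq_len(object$n_ortho)) {
    to <- xs %*% object$w_o[, j]
    xs <- xs - tcrossprod(to, object$p_o[, j])
  }
  yhat <- drop(xs %*% object$b) + object$y_mean
  if (type == "score") yhat else object$levels[(yhat > 0) + 1L]
}

#' @export
coef.oplsda <- function(object, ...) object$b

#' @export
fitted.oplsda <- function(object, ...) object$fitted

#' @export
residuals.oplsda <- function(object, ...) object$y - object$fitted

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal LV, %d samples x %d variables\n",
              x$n_ortho, length(x$t_p), length(x$b)))
  cat(sprintf("  classes: %s (-1) vs %s (+1); R2Y = %.3f\n",
              x$levels[1], x$levels[2], x$R2Y))
  if (!is.null(x$cv))
    cat(sprintf("  Q2 = %.3f (K = %d); CV-ANOVA F = %.2f, p = %.3g\n",
                x$cv$Q2, x$cv$folds, x$cv$cv_anova_F, x$cv$cv_anova_p))
  if (!is.null(x$permutation))
    cat(sprintf("  permuted Q2: median %.3f, max %.3f (n = %d)\n",
                stats::median(x$permutation$q2p), max(x$permutation$q2p),
                x$permutation$n_perm))
  if (!is.null(x$verdict))
    cat(sprintf("  overfitting verdict: %s\n",
                if (x$verdict$overall) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  out <- list(R2Y = object$R2Y,
              Q2 = object$cv$Q2 %||% NA_real_,
              cv_anova_p = object$cv$cv_anova_p %||% NA_real_,
              q2p_median = if (is.null(object$permutation)) NA_real_
                           else stats::median(object$permutation$q2p),
              verdict = object$verdict)
  class(out) <- "summary.oplsda"
  out
}

#' @export
print.summary.oplsda <- function(x, ...) {
  cat(sprintf("R2Y = %.3f; Q2 = %.3f; CV-ANOVA p = %.3g; median permuted Q2 = %.3f\n",
              x$R2Y, x$Q2, x$cv_anova_p, x$q2p_median))
  if (!is.null(x$verdict))
    cat(sprintf("verdict: Q2 > 0.5 %s; median Q2p < 0 %s; CV-ANOVA p < 0.05 %s -> %s\n",
                x$verdict$q2c_pass, x$verdict$q2p_pass, x$verdict$cvanova_pass,
                if (x$verdict$overall) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
plot.oplsda <- function(x, ...) {
  plot(x$t_p, x$t_o[, 1], col = ifelse(x$y > 0, 2, 4),
       xlab = "predictive score t[1]", ylab = "orthogonal score to[1]", ...)
  invisible(x)
}
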