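#' Principal component analysis for sample screening
#'
#' Unsupervised PCA of a column-centered (typically unit-variance scaled)
#' concentration matrix, computed by singular value decomposition. Used
#' together with [hotelling_t2()] to spot atypical samples before any
#' supervised modelling; flagged samples are reported, never removed
#' automatically.
#'
#' @param x centered numeric matrix (samples x analytes); column means must
#'   be within 1e-6 of zero.
#' @param ncomp number of components, `1 <= ncomp <= min(n - 1, p)`.
#' @return Object of class `pcaqc` with elements `scores` (n x A),
#'   `loadings` (p x A, unit-norm columns), `explained_variance`
#'   (per-component score variance), `explained_proportion`, `ncomp`,
#'   `total_variance`.
#' @examples
#' x <- scale_columns(matrix(rnorm(60), 12, 5))
#' fit <- pcaqc(x, ncomp = 2)
#' summary(fit)
#' @export
pcaqc <- function(x, ncomp = 2) {
  x <- unclass(as.matrix(x))
  n <- nrow(x); p <- ncol(x)
  if (!is_count(ncomp) || ncomp < 1 || ncomp > min(n - 1, p))
    stopf("ncomp must be an integer in [1, %d], got %s", min(n - 1, p), format(ncomp))
  cm <- colMeans(x)
  if (any(abs(cm) > 1e-6))
    stopf("x is not column-centered (max |column mean| = %.3g); scale first",
          max(abs(cm)))
  sv <- svd(x, nu = ncomp, nv = ncomp)
  scores <- sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v
  # deterministic sign: largest-magnitude loading element positive
  for (a in seq_len(ncomp)) {
    piv <- which.max(abs(loadings[, a]))
    if (loadings[piv, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncomp))
  ev <- sv$d^2 / (n - 1)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(ncomp)],
                 explained_proportion = (ev / sum(ev))[seq_len(ncomp)],
                 all_variances = ev,
                 total_variance = sum(apply(x, 2, stats::var)),
                 ncomp = ncomp, n = n),
            class = "pcaqc")
}

#' @export
print.pcaqc <- function(x, ...) {
  cat(sprintf("PCA: %d components on %d samples\n", x$ncomp, x$n))
  cat(sprintf("  explained: %s\n",
              paste(sprintf("%s %.1f%%", colnames(x$scores),
                            100 * x$explained_proportion), collapse = ", ")))
  invisible(x)
}

#' @export
summary.pcaqc <- function(object, ...) {
  out <- data.frame(component = colnames(object$scores),
                    variance = object$explained_variance,
                    proportion = object$explained_proportion)
  class(out) <- c("summary.pcaqc", "data.frame")
  out
}

#' @export
plot.pcaqc <- function(x, comps = c(1, 2), ...) {
  if (x$ncomp < 2) stopf("score plot needs at least 2 components")
  plot(x$scores[, comps[1]], x$scores[, comps[2]],
       xlab = sprintf("%s (%.1f%%)", colnames(x$scores)[comps[1]],
                      100 * x$explained_proportion[comps[1]]),
       ylab = sprintf("%s (%.1f%%)", colnames(x$scores)[comps[2]],
                      100 * x$explained_proportion[comps[2]]), ...)
  invisible(x)
}

#' Hotelling T2 screening of PCA scores
#'
#' Computes the per-sample Hotelling T2 statistic over the model's score
#' space, `T2_i = sum_a t_ia^2 / var(t_a)`, and the critical limit
#' `A(n-1)/(n-A) * F(A, n-A; 1-alpha)`. Samples exceeding the limit are
#' reported as atypical candidates for data and metadata review; exclusion
#' is left to the analyst.
#'
#' @param model a [pcaqc()] fit on at least 3 samples.
#' @param alpha significance level of the limit (default 0.05).
#' @return Object of class `t2_report`: `t2` per sample, `limit`, `flagged`
#'   (sample ids or indices above the limit), `alpha`.
#' @export
hotelling_t2 <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pcaqc"))
  n <- model$n; A <- model$ncomp
  if (n < 3) stopf("T2 screening needs at least 3 samples")
  if (n <= A) stopf("T2 limit undefined for n = %d <= A = %d", n, A)
  v <- apply(model$scores, 2, stats::var)
  if (any(v < .Machine$double.eps))
    stopf("degenerate score variance (all samples identical after centering?)")
  t2 <- rowSums(sweep(model$scores^2, 2, v, "/"))
  limit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  ids <- rownames(model$scores) %||% as.character(seq_len(n))
  structure(list(t2 = stats::setNames(t2, ids), limit = limit,
                 flagged = ids[t2 > limit], alpha = alpha),
            class = "t2_report")
}

#' @export
print.t2_report <- function(x, ...) {
  cat(sprintf("Hotelling T2: limit %.3f (alpha = %.3g); %d/%d sample(s) flagged\n",
              x$limit, x$alpha, length(x$flagged), length(x$t2)))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
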