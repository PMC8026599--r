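#' Within-/between-subject decomposition of a paired matrix
#'
#' Splits a matrix of paired observations (two samples per subject, one per
#' eye) into the between-subject part (subject means, as deviations from the
#' grand mean) and the within-subject part (deviations from the subject
#' mean). Supervised models on the within part isolate the paired treatment
#' effect from between-subject variation.
#'
#' @param x numeric matrix, one row per sample.
#' @param subject subject identifier per row; every subject must appear
#'   exactly twice.
#' @return List with `within` and `between` matrices (same shape as `x`),
#'   `grand_mean`, and `subject`.
#' @export
within_subject_split <- function(x, subject) {
  x <- as.matrix(x)
  subject <- as.character(subject)
  counts <- table(subject)
  bad <- names(counts)[counts != 2]
  if (length(bad))
    stopf("subjects without exactly 2 samples: %s", paste(bad, collapse = ", "))
  gm <- colMeans(x)
  subj_means <- rowsum(x, subject) / 2
  sm <- subj_means[subject, , drop = FALSE]
  within <- x - sm
  between <- sweep(sm, 2, gm)
  rownames(within) <- rownames(between) <- rownames(x)
  list(within = within, between = between, grand_mean = gm, subject = subject)
}

#' Multilevel PLS-DA for paired samples
#'
#' PLS-DA on the within-subject part of a paired data matrix: each subject's
#' two eyes are reduced to their deviations from the subject mean before the
#' supervised fit, so the model sees only the paired (eye) contrast. New
#' paired samples are predicted by applying the same within-subject
#' reduction and the training scaling, then the regression vector.
#'
#' @param x numeric matrix (samples x analytes), log concentrations.
#' @param y two-level class vector (e.g. eye: FDEP vs control), one level
#'   per sample; each subject must carry both levels.
#' @param subject subject identifier per row (exactly 2 rows each).
#' @param ncomp number of latent variables (default 2).
#' @param scaling column scaling of the within matrix.
#' @return Object of class `mlplsda` wrapping the [plsda()] fit on the
#'   within matrix.
#' @export
mlplsda <- function(x, y, subject, ncomp = 2,
                    scaling = c("unit_variance", "center", "pareto")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  dec <- within_subject_split(x, subject)
  cls <- code_classes(y)
  per_subj <- tapply(cls$y, dec$subject, function(v) length(unique(v)))
  if (any(per_subj != 2))
    stopf("each subject must carry both class levels; offending: %s",
          paste(names(per_subj)[per_subj != 2], collapse = ", "))
  fit <- plsda(dec$within, y, ncomp = ncomp, scaling = scaling)
  structure(list(fit = fit, decomposition = dec, ncomp = ncomp,
                 levels = fit$levels, y = fit$y), class = "mlplsda")
}

#' @export
predict.mlplsda <- function(object, newdata, subject,
                            type = c("score", "class"), ...) {
  type <- match.arg(type)
  dec <- within_subject_split(as.matrix(newdata), subject)
  predict(object$fit, dec$within, type = type)
}

#' @export
print.mlplsda <- function(x, ...) {
  cat(sprintf("Multilevel PLS-DA: %d LV on within-subject matrix (%d pairs)\n",
              x$ncomp, nrow(x$fit$scores) / 2))
  cat(sprintf("  classes: %s (-1) vs %s (+1); R2Y = %.3f\n",
              x$levels[1], x$levels[2], x$fit$R2Y))
  invisible(x)
}

#' @export
coef.mlplsda <- function(object, ...) coef(object$fit)

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) score pairs
#' ordered correctly, ties counted one half. Computed from mid-ranks, which
#' is exactly the all-pairs count.
#'
#' @param scores numeric predicted scores.
#' @param labels two-level class vector.
#' @param positive level treated as positive; default the +1 level of the
#'   sorted coding (see [plsda()]).
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(1, 2, 3, 2.5, 3.5), c(0, 0, 0, 1, 1))  # 5/6
#' @export
auroc <- function(scores, labels, positive = NULL) {
  cls <- code_classes(labels, levels = if (is.null(positive)) NULL
                      else c(setdiff(unique(as.character(labels)), positive), positive))
  pos <- cls$y > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired-design p-value for a model's test-set scores
#'
#' Two-sided paired t test of the within-pair difference of predicted scores
#' (positive minus negative class member of each subject) against zero:
#' under the null of no discrimination the paired score differences are
#' centered at zero. A degenerate case where all differences are identical
#' and nonzero returns p = 0 with a warning.
#'
#' @param scores predicted numeric scores.
#' @param labels two-level class vector.
#' @param subject subject id per sample; pairs must be complete.
#' @param positive positive class level (default: +1 coding level).
#' @return Two-sided p-value.
#' @export
auroc_pvalue <- function(scores, labels, subject, positive = NULL) {
  cls <- code_classes(labels, levels = if (is.null(positive)) NULL
                      else c(setdiff(unique(as.character(labels)), positive), positive))
  subject <- as.character(subject)
  counts <- table(subject)
  if (any(counts != 2)) stopf("test set must contain complete pairs")
  subj <- unique(subject)
  if (length(subj) < 2) stopf("at least 2 pairs required for the paired t test")
  d <- vapply(subj, function(s) {
    i <- which(subject == s)
    scores[i[cls$y[i] > 0]] - scores[i[cls$y[i] < 0]]
  }, numeric(1))
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    if (all(abs(d) < .Machine$double.eps^0.5)) return(1)
    warning("within-pair score differences are constant; returning p = 0",
            call. = FALSE)
    return(0)
  }
  stats::t.test(d)$p.value
}

#' Train/test resampling validation of the paired PLS-DA
#'
#' Repeatedly splits the paired dataset into training and test sets (by
#' default 9 subject pairs / 18 samples for training and 5 pairs /
#' 10 samples for testing), refits the multilevel PLS-DA on each training
#' set (scaling re-estimated on training data only), predicts the held-out
#' pairs, and records the test AUROC and its paired-t p-value. The model
#' family is judged satisfactory when the median AUROC is at least 0.8 and
#' the median p-value is below 0.05.
#'
#' Allocation keeps both eyes of a subject on the same side of the split
#' (`unit = "pair"`); `unit = "sample"` reproduces the naive sample-level
#' allocation, in which subjects split across the sets contribute no usable
#' within-pair information to training.
#'
#' @param x numeric matrix (samples x analytes), log concentrations.
#' @param y two-level class vector per sample.
#' @param subject subject id per sample.
#' @param n_models number of resampled models (default 1000).
#' @param train_pairs subjects allocated to training (default 9 of 14).
#' @param ncomp,scaling passed to [mlplsda()].
#' @param seed base seed; resample k draws its substream from (seed, k).
#' @param unit `"pair"` (default) or `"sample"`.
#' @param positive positive class level for the AUROC.
#' @return Object of class `validation_summary`: `aurocs`, `pvalues`
#'   (length `n_models`), `median_auroc`, `median_p`, `satisfactory`,
#'   `allocations` (train-subject matrix), `scheme`.
#' @export
validate_paired <- function(x, y, subject, n_models = 1000, train_pairs = 9,
                            ncomp = 2,
                            scaling = c("unit_variance", "center", "pareto"),
                            seed = 1, unit = c("pair", "sample"),
                            positive = NULL) {
  scaling <- match.arg(scaling)
  unit <- match.arg(unit)
  x <- as.matrix(x)
  subject <- as.character(subject)
  subjects <- unique(subject)
  n_pairs <- length(subjects)
  if (any(table(subject) != 2)) stopf("every subject needs exactly 2 samples")
  if (!is_count(train_pairs) || train_pairs < 2 || train_pairs >= n_pairs)
    stopf("train_pairs must be in [2, %d)", n_pairs)
  aurocs <- numeric(n_models); pvals <- numeric(n_models)
  alloc <- matrix(NA_character_, n_models, train_pairs)
  for (k in seq_len(n_models)) {
    sk <- substream(seed, k)
    if (unit == "pair") {
      tr_subj <- with_seed(sk, sample(subjects, train_pairs))
      tr <- subject %in% tr_subj
    } else {
      tr_idx <- with_seed(sk, sample(length(subject), 2 * train_pairs))
      tr <- seq_along(subject) %in% tr_idx
      tr_subj <- unique(subject[tr])
    }
    te <- !tr
    fit <- if (unit == "pair") {
      mlplsda(x[tr, , drop = FALSE], y[tr], subject[tr],
              ncomp = ncomp, scaling = scaling)
    } else {
      # naive allocation: within deviations computed from whatever samples a
      # subject contributed; singleton subjects yield zero rows
      dec_tr <- naive_within(x[tr, , drop = FALSE], subject[tr])
      structure(list(fit = plsda(dec_tr, y[tr], ncomp = ncomp, scaling = scaling)),
                class = "mlplsda")
    }
    sc <- if (unit == "pair") predict(fit, x[te, , drop = FALSE], subject[te])
          else predict(fit$fit, naive_within(x[te, , drop = FALSE], subject[te]))
    # orient scores to the requested positive class (the model's internal
    # +1 level is a coding convention, not a direction of interest)
    pos <- positive %||% fit$fit$levels[2]
    if (fit$fit$levels[2] != pos) sc <- -sc
    aurocs[k] <- auroc(sc, y[te], positive = pos)
    pvals[k] <- suppressWarnings(
      auroc_pvalue(sc, y[te], subject[te], positive = pos))
    alloc[k, seq_along(tr_subj)[seq_len(min(train_pairs, length(tr_subj)))]] <-
      tr_subj[seq_len(min(train_pairs, length(tr_subj)))]
  }
  structure(list(aurocs = aurocs, pvalues = pvals,
                 median_auroc = stats::median(aurocs),
                 median_p = stats::median(pvals),
                 satisfactory = stats::median(aurocs) >= 0.8 &&
                   stats::median(pvals) < 0.05,
                 allocations = alloc,
                 scheme = list(n_models = n_models, train_pairs = train_pairs,
                               test_pairs = n_pairs - train_pairs,
                               unit = unit, seed = seed, ncomp = ncomp,
                               scaling = scaling)),
            class = "validation_summary")
}

# Subject-mean deviations without requiring complete pairs (naive
# sample-level allocation); singleton subjects give zero rows.
naive_within <- function(x, subject) {
  sums <- rowsum(x, subject)
  sm <- sums / as.vector(table(subject)[rownames(sums)])
  x - sm[as.character(subject), , drop = FALSE]
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Paired validation: %d models, %d train / %d test pairs (%s allocation)\n",
              x$scheme$n_models, x$scheme$train_pairs, x$scheme$test_pairs,
              x$scheme$unit))
  cat(sprintf("  median AUROC = %.3f; median p = %.3g; satisfactory (AUROC >= 0.8 & p < 0.05): %s\n",
              x$median_auroc, x$median_p, x$satisfactory))
  invisible(x)
}
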