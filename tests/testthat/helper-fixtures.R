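# Shared fixtures and independent oracles, all built in code.

# Paired-design metadata: n_subj subjects, two eyes each, one tissue/group.
paired_meta <- function(n_subj, group = "SW", tissue = "vitreous") {
  subj <- sprintf("%s_S%02d", group, seq_len(n_subj))
  data.frame(
    sample_id = paste0(rep(subj, each = 2), "_", c("FDEP", "control"), "_",
                       substr(tissue, 1, 3)),
    subject_id = rep(subj, each = 2),
    eye = rep(c("FDEP", "control"), n_subj),
    group = group, tissue = tissue,
    stringsAsFactors = FALSE
  )
}

# Two-group independent metadata: one eye per subject.
grouped_meta <- function(n_per_group, eye = "FDEP", tissue = "vitreous") {
  subj <- c(sprintf("SW_S%02d", seq_len(n_per_group)),
            sprintf("BEW_S%02d", seq_len(n_per_group)))
  data.frame(
    sample_id = paste0(subj, "_", eye),
    subject_id = subj,
    eye = eye,
    group = rep(c("SW", "BEW"), each = n_per_group),
    tissue = tissue,
    stringsAsFactors = FALSE
  )
}

# Small complete dataset with analytes A1..Ap.
tiny_dataset <- function(conc, meta, flags = NULL) {
  p <- ncol(conc)
  study_dataset(conc, flags, meta,
                data.frame(analyte_id = paste0("A", seq_len(p)),
                           class = "unknown", stringsAsFactors = FALSE))
}

# Brute-force AUROC: count over all (positive, negative) pairs, ties 1/2.
brute_auroc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Exhaustive BH step-up: reject the i smallest p-values for the largest i
# with p_(i) <= i*q/m.
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  i <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  if (!is.finite(i)) return(integer(0))
  sort(o[seq_len(i)])
}

# Random paired (two eyes per subject) log-scale matrix with an optional
# within-pair effect on the first n_affected columns.
random_paired <- function(n_pairs, p, delta = 0, n_affected = 0) {
  meta_y <- rep(c("FDEP", "control"), n_pairs)
  subject <- rep(sprintf("S%02d", seq_len(n_pairs)), each = 2)
  x <- matrix(rnorm(2 * n_pairs * p), 2 * n_pairs, p)
  if (n_affected > 0)
    x[meta_y == "FDEP", seq_len(n_affected)] <-
      x[meta_y == "FDEP", seq_len(n_affected)] + delta
  list(x = x, y = meta_y, subject = subject)
}
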