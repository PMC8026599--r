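QUANT_FLAGS <- c("OK", "BELOW_LLOQ", "ABOVE_ULOQ", "MISSING")
EYE_LEVELS <- c("FDEP", "control")
GROUP_LEVELS <- c("SW", "BEW")
TISSUE_LEVELS <- c("vitreous", "retina")

#' Construct a study dataset
#'
#' Bundles a samples-by-analytes concentration matrix with per-value
#' quantitation flags and per-sample design metadata for the paired ocular
#' design (one form-deprived and one control eye per subject, subjects split
#' across two lighting groups, samples taken per tissue).
#'
#' @param concentrations numeric matrix, samples in rows, analytes in columns
#'   (concentration units are irrelevant to the statistics).
#' @param flags character matrix of the same shape with entries `"OK"`,
#'   `"BELOW_LLOQ"`, `"ABOVE_ULOQ"` or `"MISSING"`. If `NULL`, all finite
#'   positive values are `OK` and the rest `MISSING`.
#' @param samples data.frame with columns `sample_id`, `subject_id`, `eye`
#'   (`FDEP`/`control`), `group` (`SW`/`BEW`), `tissue` (`vitreous`/`retina`).
#' @param analytes data.frame with columns `analyte_id` and `class`
#'   (a [panel_registry()] works).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(concentrations, flags = NULL, samples, analytes) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  if (is.null(flags)) {
    flags <- matrix(ifelse(is.finite(concentrations) & concentrations > 0,
                           "OK", "MISSING"),
                    nrow = nrow(concentrations))
  }
  flags <- as.matrix(flags)
  if (!identical(dim(flags), dim(concentrations)))
    stopf("flag matrix dimensions %s do not match concentrations %s",
          paste(dim(flags), collapse = "x"), paste(dim(concentrations), collapse = "x"))
  bad <- setdiff(unique(as.vector(flags)), QUANT_FLAGS)
  if (length(bad))
    stopf("unknown quantitation flag(s): %s", paste(bad, collapse = ", "))

  samples <- validate_sample_meta(samples)
  if (nrow(samples) != nrow(concentrations))
    stopf("%d metadata rows for %d samples", nrow(samples), nrow(concentrations))
  if (!is.data.frame(analytes) || !all(c("analyte_id", "class") %in% names(analytes)))
    stopf("analytes must have columns 'analyte_id' and 'class'")
  analytes <- as.data.frame(analytes)[, c("analyte_id", "class")]
  if (nrow(analytes) != ncol(concentrations))
    stopf("%d analyte rows for %d columns", nrow(analytes), ncol(concentrations))

  # OK values must be usable downstream (log transform): finite and > 0.
  ok <- flags == "OK"
  zero_ok <- ok & (!is.finite(concentrations) | concentrations <= 0)
  if (any(zero_ok)) {
    warning(sprintf("%d non-positive value(s) flagged OK coerced to MISSING",
                    sum(zero_ok)), call. = FALSE)
    flags[zero_ok] <- "MISSING"
    concentrations[zero_ok] <- NA_real_
  }

  dimnames(concentrations) <- list(samples$sample_id, analytes$analyte_id)
  dimnames(flags) <- dimnames(concentrations)
  structure(list(concentrations = concentrations, flags = flags,
                 samples = samples, analytes = analytes),
            class = "study_dataset")
}

validate_sample_meta <- function(samples) {
  req <- c("sample_id", "subject_id", "eye", "group", "tissue")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stopf("sample metadata must have columns %s", paste(req, collapse = ", "))
  samples <- as.data.frame(samples)[, req]
  for (col in req) samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample_id: %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(samples[[col]]), levels)
    if (length(bad))
      stopf("unrecognized %s level(s): %s (expected %s)", col,
            paste(bad, collapse = ", "), paste(levels, collapse = "/"))
  }
  check_levels("eye", EYE_LEVELS)
  check_levels("group", GROUP_LEVELS)
  check_levels("tissue", TISSUE_LEVELS)
  key <- paste(samples$subject_id, samples$eye, samples$tissue)
  if (anyDuplicated(key))
    stopf("duplicate (subject_id, eye, tissue) combination: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(samples) <- NULL
  samples
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d samples x %d analytes\n",
              nrow(x$concentrations), ncol(x$concentrations)))
  cat("  tissues:", paste(names(table(x$samples$tissue)),
                          table(x$samples$tissue), collapse = ", "), "\n")
  cat("  groups: ", paste(names(table(x$samples$group)),
                          table(x$samples$group), collapse = ", "), "\n")
  fl <- table(factor(x$flags, levels = QUANT_FLAGS))
  cat("  flags:  ", paste(names(fl), fl, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.study_dataset <- function(x) dim(x$concentrations)

#' Subset a study dataset by sample metadata
#'
#' @param dataset a `study_dataset`.
#' @param ... named filters on metadata columns, e.g. `tissue = "vitreous"`,
#'   `group = "BEW"`, `eye = c("FDEP", "control")`.
#' @param analytes optional character vector of analyte ids to keep.
#' @return The filtered `study_dataset`.
#' @export
subset_samples <- function(dataset, ..., analytes = NULL) {
  filters <- list(...)
  keep <- rep(TRUE, nrow(dataset$samples))
  for (nm in names(filters)) {
    if (!nm %in% names(dataset$samples)) stopf("unknown metadata column '%s'", nm)
    keep <- keep & dataset$samples[[nm]] %in% filters[[nm]]
  }
  if (!any(keep)) stopf("no samples match the filter")
  cols <- if (is.null(analytes)) seq_len(ncol(dataset$concentrations))
          else match(analytes, dataset$analytes$analyte_id)
  if (anyNA(cols)) stopf("unknown analyte id(s) in subset")
  study_dataset(dataset$concentrations[keep, cols, drop = FALSE],
                dataset$flags[keep, cols, drop = FALSE],
                dataset$samples[keep, , drop = FALSE],
                dataset$analytes[cols, , drop = FALSE])
}

LLOQ_TOKEN <- "<LLOQ"
ULOQ_TOKEN <- ">ULOQ"
META_COLUMNS <- c("sample_id", "subject_id", "eye", "group", "tissue")

#' Read a concentration table
#'
#' Reads a wide CSV/TSV table (delimiter auto-detected): one metadata block
#' (`sample_id`, `subject_id`, `eye`, `group`, `tissue`) followed by one
#' column per analyte. Cells are decimal numbers or the tokens `"<LLOQ"`,
#' `">ULOQ"`, or empty (missing). Alternatively, a numeric column may be
#' paired with a `<analyte>_flag` column carrying the flag, which overrides
#' the token convention (both dialects occur in kit exports); see
#' [write_concentration_table()].
#'
#' @param path file path.
#' @param registry a [panel_registry()]; analyte columns not present in the
#'   registry are accepted with class `"unknown"` and a warning.
#' @return A [study_dataset()].
#' @export
read_concentration_table <- function(path, registry = p180_registry()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stopf("empty table: %s", path)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = NULL, quote = "\"")
  if (nrow(raw) == 0) stopf("empty table (no sample rows): %s", path)
  missing_meta <- setdiff(META_COLUMNS, names(raw))
  if (length(missing_meta))
    stopf("missing metadata column(s): %s", paste(missing_meta, collapse = ", "))

  value_cols <- setdiff(names(raw), META_COLUMNS)
  flag_cols <- grep("_flag$", value_cols, value = TRUE)
  analyte_cols <- setdiff(value_cols, flag_cols)
  orphan <- setdiff(sub("_flag$", "", flag_cols), analyte_cols)
  if (length(orphan))
    stopf("flag column(s) without a value column: %s",
          paste(paste0(orphan, "_flag"), collapse = ", "))

  n <- nrow(raw)
  p <- length(analyte_cols)
  conc <- matrix(NA_real_, n, p)
  flags <- matrix("OK", n, p)
  for (j in seq_len(p)) {
    cells <- trimws(raw[[analyte_cols[j]]])
    is_lloq <- cells == LLOQ_TOKEN
    is_uloq <- cells == ULOQ_TOKEN
    is_missing <- cells == "" | toupper(cells) == "NA"
    numeric_cells <- !(is_lloq | is_uloq | is_missing)
    vals <- suppressWarnings(as.numeric(cells[numeric_cells]))
    if (anyNA(vals)) {
      bad_row <- which(numeric_cells)[which(is.na(vals))[1]]
      stopf("non-numeric value '%s' at row %d, column '%s'",
            cells[bad_row], bad_row, analyte_cols[j])
    }
    conc[numeric_cells, j] <- vals
    flags[is_lloq, j] <- "BELOW_LLOQ"
    flags[is_uloq, j] <- "ABOVE_ULOQ"
    flags[is_missing, j] <- "MISSING"
    fc <- paste0(analyte_cols[j], "_flag")
    if (fc %in% flag_cols) {
      fv <- trimws(raw[[fc]])
      fv[fv == ""] <- "OK"
      bad <- setdiff(unique(fv), QUANT_FLAGS)
      if (length(bad))
        stopf("unknown flag value(s) in column '%s': %s", fc, paste(bad, collapse = ", "))
      flags[, j] <- fv
      flags[is.na(conc[, j]) & fv == "OK", j] <- "MISSING"
    }
  }
  cls <- rep("unknown", p)
  known <- analyte_cols %in% registry$analyte_id
  cls[known] <- registry$class[match(analyte_cols[known], registry$analyte_id)]
  if (any(!known))
    warning(sprintf("%d analyte(s) not in registry tagged class 'unknown': %s",
                    sum(!known), paste(utils::head(analyte_cols[!known], 5), collapse = ", ")),
            call. = FALSE)

  study_dataset(conc, flags,
                samples = raw[, META_COLUMNS],
                analytes = data.frame(analyte_id = analyte_cols, class = cls,
                                      stringsAsFactors = FALSE))
}

#' Write a concentration table
#'
#' Serializes a [study_dataset()] so that [read_concentration_table()]
#' reproduces it. The `"token"` dialect writes `"<LLOQ"` / `">ULOQ"` / empty
#' cells for out-of-range values (numeric values carried by non-OK cells are
#' not representable and are dropped); the `"flag_columns"` dialect keeps all
#' numeric values and writes a `<analyte>_flag` column per analyte.
#'
#' @param dataset a `study_dataset`.
#' @param path output file path; `.tsv` extension selects tab delimiting.
#' @param dialect `"token"` (default) or `"flag_columns"`.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(dataset, path, dialect = c("token", "flag_columns")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- dataset$samples
  ids <- dataset$analytes$analyte_id
  for (j in seq_along(ids)) {
    vals <- format_concentration(dataset$concentrations[, j])
    if (dialect == "token") {
      fl <- dataset$flags[, j]
      vals[fl == "BELOW_LLOQ"] <- LLOQ_TOKEN
      vals[fl == "ABOVE_ULOQ"] <- ULOQ_TOKEN
      vals[fl == "MISSING"] <- ""
      out[[ids[j]]] <- vals
    } else {
      out[[ids[j]]] <- vals
      out[[paste0(ids[j], "_flag")]] <- dataset$flags[, j]
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_concentration <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
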