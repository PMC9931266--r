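#' Patient cohort container
#'
#' A `cohort` bundles a predictor table (binary 0/1 and ordinal integer
#' columns, `NA` marking missing values), a complete binary outcome vector,
#' a site label, and optionally a duplicate-rating table from a second
#' rater used by the inter-rater reliability screen.
#'
#' @param predictors data.frame of numeric predictor columns; `NA` = missing.
#' @param outcome integer/numeric 0/1 vector, one entry per row, no missing.
#' @param kinds optional named character vector (`"binary"` or `"ordinal"`)
#'   per predictor; inferred from the data when omitted (a column whose
#'   non-missing values all lie in `{0, 1}` is binary).
#' @param site site label recorded with the cohort.
#' @param rater_b optional data.frame of second-rater duplicates for a
#'   subset of the binary predictors (same row count).
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(predictors, outcome, kinds = NULL, site = "cohort",
                   rater_b = NULL) {
  predictors <- as.data.frame(predictors)
  if (anyDuplicated(names(predictors)))
    stopf("predictor column names must be unique")
  if (!is_binary01(outcome) || anyNA(outcome))
    stopf("outcome must be binary 0/1 with no missing values")
  if (length(outcome) != nrow(predictors))
    stopf("outcome length (%d) != predictor rows (%d)",
          length(outcome), nrow(predictors))
  if (is.null(kinds)) {
    kinds <- vapply(predictors, function(x)
      if (is_binary01(x)) "binary" else "ordinal", character(1))
  } else {
    kinds <- kinds[names(predictors)]
    if (anyNA(kinds)) stopf("kinds must cover every predictor column")
  }
  if (!is.null(rater_b)) {
    rater_b <- as.data.frame(rater_b)
    if (nrow(rater_b) != nrow(predictors))
      stopf("rater_b row count must match predictor table")
    if (!all(names(rater_b) %in% names(predictors)))
      stopf("rater_b columns must name existing predictors")
  }
  structure(list(predictors = predictors,
                 outcome = as.integer(outcome),
                 kinds = kinds, site = site, rater_b = rater_b),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d patients, %d predictors, outcome prevalence %s>\n",
              x$site, nrow(x$predictors), ncol(x$predictors),
              pct1(mean(x$outcome))))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  p <- object$predictors
  df <- data.frame(
    variable = names(p),
    kind = unname(object$kinds),
    missing_frac = vapply(p, function(c) mean(is.na(c)), numeric(1)),
    mean = vapply(p, function(c) mean(c, na.rm = TRUE), numeric(1)),
    row.names = NULL)
  attr(df, "site") <- object$site
  attr(df, "prevalence") <- mean(object$outcome)
  df
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  cbind(x$predictors, outcome = x$outcome)
}

#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$predictors[i, , drop = FALSE], x$outcome[i],
         kinds = x$kinds, site = x$site,
         rater_b = if (!is.null(x$rater_b)) x$rater_b[i, , drop = FALSE])
}

#' Number of patients in a cohort
#' @param x a [cohort()].
#' @return integer row count.
#' @export
n_patients <- function(x) nrow(x$predictors)

#' Read and write cohorts as CSV with a JSON sidecar
#'
#' Cohorts are stored as plain CSV with a header row and missing values as
#' empty fields; second-rater duplicate columns are suffixed `__rater_b`.
#' A `<path>.meta.json` sidecar records the site label, column kinds and,
#' when the cohort was simulated, the generator seed.
#'
#' @param x a [cohort()].
#' @param path CSV file path.
#' @param seed optional generator seed recorded in the sidecar.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a [cohort()].
#' @export
write_cohort_csv <- function(x, path, seed = NULL) {
  df <- as.data.frame(x)
  if (!is.null(x$rater_b)) {
    rb <- x$rater_b
    names(rb) <- paste0(names(rb), "__rater_b")
    df <- cbind(df, rb)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(site = x$site, kinds = as.list(x$kinds))
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (!"outcome" %in% names(df)) stopf("cohort CSV lacks an 'outcome' column")
  rb_cols <- grep("__rater_b$", names(df), value = TRUE)
  rater_b <- NULL
  if (length(rb_cols)) {
    rater_b <- df[rb_cols]
    names(rater_b) <- sub("__rater_b$", "", rb_cols)
  }
  pred <- df[setdiff(names(df), c("outcome", rb_cols))]
  kinds <- if (!is.null(meta$kinds)) unlist(meta$kinds) else NULL
  cohort(pred, df$outcome, kinds = kinds,
         site = if (!is.null(meta$site)) meta$site else "cohort",
         rater_b = rater_b)
}
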