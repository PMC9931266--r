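#' Permutation importance under the weighted operating score
#'
#' For each predictor, the mean drop in the weighted
#' sensitivity/specificity score over `n_perm` within-cohort shuffles of
#' that column, at the model's frozen operating threshold. Predictors the
#' model's structure does not reference are reported as exactly zero
#' without shuffling.
#'
#' @param model fitted model (`cdi_rule_list`, `cart_tree`,
#'   `rule_ensemble`).
#' @param cohort evaluation [cohort()] without missing values.
#' @param threshold frozen operating risk threshold.
#' @param n_perm number of shuffles per variable.
#' @param seed integer seed (per-variable sub-streams, so results do not
#'   depend on column order).
#' @param w sensitivity weight.
#' @return named numeric vector of importance scores over the cohort's
#'   predictors.
#' @export
permutation_importance <- function(model, cohort, threshold, n_perm = 100,
                                   seed = 1L, w = 5) {
  stopifnot(n_perm >= 1)
  df <- model_frame(model, cohort)
  y <- cohort$outcome
  score_at <- function(d) {
    r <- predict(model, d)
    cc <- confusion(y, as.integer(r >= threshold))
    weighted_score(cc$tp / (cc$tp + cc$fn), cc$tn / (cc$tn + cc$fp), w)
  }
  baseline <- score_at(df)
  used <- model_variables(model)
  out <- stats::setNames(numeric(ncol(cohort$predictors)),
                         names(cohort$predictors))
  n <- nrow(df)
  for (nm in intersect(names(out), used)) {
    drops <- with_seed(substream_seed(seed, "perm", nm), {
      vapply(seq_len(n_perm), function(k) {
        d <- df
        d[[nm]] <- d[[nm]][sample.int(n)]
        baseline - score_at(d)
      }, numeric(1))
    })
    out[nm] <- mean(drops)
  }
  out
}

#' Cross-model variable frequency
#'
#' Counts, per predictor, how many fitted instruments reference it in
#' their serialized structure.
#'
#' @param models named list of fitted models.
#' @param variables optional universe of variable names (defaults to the
#'   union of variables used).
#' @return named integer vector.
#' @export
variable_frequency <- function(models, variables = NULL) {
  stopifnot(length(models) >= 1)
  used <- lapply(models, model_variables)
  if (is.null(variables)) variables <- unique(unlist(used))
  vapply(stats::setNames(variables, variables), function(v)
    sum(vapply(used, function(u) v %in% u, logical(1))), integer(1))
}

#' Variable-level stability table
#'
#' Per-variable frequency across the screened instruments together with
#' the permutation-importance score of each (variable, model) pair.
#'
#' @param models named list of fitted models.
#' @param cohort evaluation [cohort()].
#' @param thresholds named vector of frozen operating thresholds, one per
#'   model.
#' @param n_perm,seed,w passed to [permutation_importance()].
#' @return An object of class `stability_table` with `frequency` (named
#'   vector) and `importance` (variables x models matrix).
#' @export
stability_table <- function(models, cohort, thresholds, n_perm = 100,
                            seed = 1L, w = 5) {
  stopifnot(length(models) >= 1, !is.null(names(models)),
            all(names(models) %in% names(thresholds)))
  vars <- names(cohort$predictors)
  imp <- vapply(names(models), function(id)
    permutation_importance(models[[id]], cohort, thresholds[[id]],
                           n_perm = n_perm,
                           seed = substream_seed(seed, "model", id), w = w),
    numeric(length(vars)))
  structure(list(frequency = variable_frequency(models, vars),
                 importance = imp),
            class = "stability_table")
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Variable-level stability (zeros suppressed in importance)\n")
  ord <- variable_stability_rank(x)
  for (v in ord) {
    nz <- x$importance[v, x$importance[v, ] != 0]
    cat(sprintf("  %-26s freq %d/%d  %s\n", v, x$frequency[[v]],
                ncol(x$importance),
                if (length(nz)) paste(sprintf("%s=%.4f", names(nz), nz),
                                      collapse = " ") else ""))
  }
  invisible(x)
}

#' Rank variables by stability
#'
#' Lexicographic ordering: frequency across instruments (descending),
#' then mean non-zero permutation importance (descending), then name.
#'
#' @param table a [stability_table()].
#' @return character vector of variable names, most stable first.
#' @export
variable_stability_rank <- function(table) {
  vars <- names(table$frequency)
  mean_nz <- vapply(vars, function(v) {
    z <- table$importance[v, ]
    z <- z[z != 0]
    if (length(z)) mean(z) else 0
  }, numeric(1))
  vars[order(-table$frequency, -mean_nz, vars)]
}

#' Development-to-validation performance drop
#'
#' @param dev_report,val_report [diagnostic_report()]s computed with the
#'   same weighted-score definition.
#' @param refit_spread optional refit-randomness score spread.
#' @return list of class `model_stability` with `dev_score`, `val_score`,
#'   `drop` (may be negative) and `refit_spread`.
#' @export
performance_drop <- function(dev_report, val_report, refit_spread = NA_real_) {
  structure(list(dev_score = dev_report$weighted_score,
                 val_score = val_report$weighted_score,
                 drop = dev_report$weighted_score - val_report$weighted_score,
                 refit_spread = refit_spread),
            class = "model_stability")
}

#' Rank candidate instruments
#'
#' Total order over models: validation weighted score (descending), then
#' development-to-validation drop (ascending), then refit-randomness
#' spread (ascending), then name. The full key breakdown is returned.
#'
#' @param dev_reports,val_reports named lists of [diagnostic_report()]s
#'   over the same model set.
#' @param stability optional named list of [performance_drop()] results
#'   supplying refit spreads.
#' @return data.frame ordered best-first with columns `model`,
#'   `val_score`, `drop`, `refit_spread`.
#' @export
rank_cdis <- function(dev_reports, val_reports, stability = NULL) {
  ids <- names(dev_reports)
  stopifnot(setequal(ids, names(val_reports)))
  df <- data.frame(
    model = ids,
    dev_score = vapply(ids, function(i) dev_reports[[i]]$weighted_score,
                       numeric(1)),
    val_score = vapply(ids, function(i) val_reports[[i]]$weighted_score,
                       numeric(1)))
  df$drop <- df$dev_score - df$val_score
  df$refit_spread <- vapply(ids, function(i) {
    if (!is.null(stability[[i]])) stability[[i]]$refit_spread else NA_real_
  }, numeric(1))
  key_spread <- ifelse(is.na(df$refit_spread), 0, df$refit_spread)
  df <- df[order(-df$val_score, df$drop, key_spread, df$model), ]
  row.names(df) <- NULL
  df
}
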