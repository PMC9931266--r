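#' Confusion counts
#'
#' Tallies a binary outcome against a binary prediction, where "positive"
#' means the instrument fires (the patient is *not* classified very low
#' risk).
#'
#' @param outcome binary outcome vector.
#' @param predicted_positive binary prediction vector of equal length.
#' @return list of class `confusion` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(outcome, predicted_positive) {
  if (length(outcome) != length(predicted_positive))
    stopf("outcome and prediction differ in length (%d vs %d)",
          length(outcome), length(predicted_positive))
  stopifnot(is_binary01(outcome), is_binary01(predicted_positive),
            !anyNA(outcome), !anyNA(predicted_positive))
  structure(list(tp = sum(outcome == 1 & predicted_positive == 1),
                 fp = sum(outcome == 0 & predicted_positive == 1),
                 tn = sum(outcome == 0 & predicted_positive == 0),
                 fn = sum(outcome == 1 & predicted_positive == 0)),
            class = "confusion")
}

report_from_counts <- function(tp, fp, tn, fn, brier = NA_real_,
                               threshold = NA_real_, w = 5) {
  stopifnot(is_count(tp), is_count(fp), is_count(tn), is_count(fn))
  if (tp + fp + tn + fn == 0) stopf("empty confusion table")
  flags <- character(0)
  div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      if (num == 0) NaN else Inf
    } else num / den
  }
  sens <- div(tp, tp + fn, "sensitivity")
  spec <- div(tn, tn + fp, "specificity")
  rep <- list(
    counts = structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                       class = "confusion"),
    sensitivity = sens, specificity = spec,
    npv = div(tn, tn + fn, "npv"), ppv = div(tp, tp + fp, "ppv"),
    lr_pos = div(sens, 1 - spec, "lr_pos"),
    lr_neg = div(1 - sens, spec, "lr_neg"),
    f1 = div(2 * tp, 2 * tp + fp + fn, "f1"),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    brier = brier, threshold = threshold,
    weighted_score = if (is.finite(sens) && is.finite(spec))
      weighted_score(sens, spec, w) else NA_real_,
    flags = flags)
  structure(rep, class = "diagnostic_report")
}

#' Diagnostic test characteristics of a risk prediction
#'
#' Computes the full metric battery — sensitivity, specificity, NPV, PPV,
#' likelihood ratios, F1, accuracy, Brier score — at an operating risk
#' threshold (positive iff `risk >= threshold`), together with the
#' weighted sensitivity/specificity score. Ratios with a zero denominator
#' are returned as `Inf`/`NaN` and flagged rather than clamped.
#'
#' @param outcome binary outcome vector.
#' @param risks predicted risk vector in `[0, 1]`.
#' @param threshold operating threshold.
#' @param w sensitivity weight of the weighted score (default 5:1).
#' @return An object of class `diagnostic_report`.
#' @export
diagnostic_report <- function(outcome, risks, threshold, w = 5) {
  stopifnot(length(outcome) == length(risks), length(outcome) > 0,
            is_prob(risks))
  cc <- confusion(outcome, as.integer(risks >= threshold))
  report_from_counts(cc$tp, cc$fp, cc$tn, cc$fn,
                     brier = mean((risks - outcome)^2),
                     threshold = threshold, w = w)
}

#' @rdname diagnostic_report
#' @param tp,fp,tn,fn confusion counts (worked-example interface when only
#'   published counts are available).
#' @param brier optional Brier score to carry alongside count-derived
#'   metrics.
#' @export
diagnostic_report_from_counts <- function(tp, fp, tn, fn,
                                          brier = NA_real_, w = 5) {
  report_from_counts(tp, fp, tn, fn, brier = brier, w = w)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report", if (!is.na(x$threshold))
    sprintf("(threshold %.4g)", x$threshold) else "", "\n")
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  cat(sprintf("  sensitivity %s, specificity %s, NPV %s, PPV %s\n",
              pct1(x$sensitivity), pct1(x$specificity), pct1(x$npv),
              pct1(x$ppv)))
  cat(sprintf("  LR+ %.2f, LR- %.3f, F1 %.3f, accuracy %s\n",
              x$lr_pos, x$lr_neg, x$f1, pct1(x$accuracy)))
  cat(sprintf("  Brier %.3f, weighted score (%.0f:1) %.4f\n",
              x$brier, 5, x$weighted_score))
  if (length(x$flags))
    cat("  undefined:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity-specificity curve
#'
#' One operating point per distinct predicted risk (classification rule:
#' positive iff `risk >= t`), closed by the all-negative point at
#' `t = Inf`. Thresholds are strictly increasing; sensitivity is
#' non-increasing and specificity non-decreasing along the curve.
#'
#' @param risks predicted risks.
#' @param outcome binary outcome with both classes present.
#' @return data.frame of class `sens_spec_curve` with columns
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
sens_spec_curve <- function(risks, outcome) {
  stopifnot(length(risks) == length(outcome))
  npos <- sum(outcome == 1); nneg <- sum(outcome == 0)
  if (npos == 0 || nneg == 0)
    stopf("both outcome classes are required for a curve")
  thr <- sort(unique(risks))
  k <- length(thr)
  at <- match(risks, thr)
  pos_at <- tabulate(at[outcome == 1], nbins = k)
  neg_at <- tabulate(at[outcome == 0], nbins = k)
  # counts strictly below each threshold
  pos_below <- cumsum(c(0, pos_at[-k]))
  neg_below <- cumsum(c(0, neg_at[-k]))
  df <- data.frame(threshold = c(thr, Inf),
                   sensitivity = c((npos - pos_below) / npos, 0),
                   specificity = c(neg_below / nneg, 1))
  structure(df, class = c("sens_spec_curve", "data.frame"))
}

#' @export
plot.sens_spec_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "b", pch = 16,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Weighted sensitivity/specificity score
#'
#' `(w * sensitivity + specificity) / (w + 1)` — the ranking currency
#' with sensitivity weighted five times more heavily than specificity by
#' default.
#'
#' @param sensitivity,specificity fractions in `[0, 1]` (vectorized).
#' @param w positive sensitivity weight.
#' @return score in `[0, 1]`.
#' @export
weighted_score <- function(sensitivity, specificity, w = 5) {
  stopifnot(is_prob(sensitivity), is_prob(specificity), w > 0)
  (w * sensitivity + specificity) / (w + 1)
}

#' Select an operating point on a sensitivity-specificity curve
#'
#' Among points meeting the sensitivity floor, returns the threshold
#' maximizing the weighted score; ties resolve to the lower threshold
#' (the higher-sensitivity side). When no point meets the floor the
#' maximum-sensitivity point is returned flagged `floor_met = FALSE`.
#'
#' @param curve a [sens_spec_curve()].
#' @param w sensitivity weight.
#' @param sens_floor minimum acceptable sensitivity.
#' @return list with `threshold`, `sensitivity`, `specificity`, `score`,
#'   `floor_met`.
#' @export
select_operating_point <- function(curve, w = 5, sens_floor = 0.95) {
  stopifnot(nrow(curve) > 0)
  sc <- weighted_score(curve$sensitivity, curve$specificity, w)
  ok <- curve$sensitivity >= sens_floor
  if (any(ok)) {
    cand <- which(ok)
    best <- cand[which.max(sc[cand])] # first max = lowest threshold
    list(threshold = curve$threshold[best],
         sensitivity = curve$sensitivity[best],
         specificity = curve$specificity[best],
         score = sc[best], floor_met = TRUE)
  } else {
    best <- which.max(curve$sensitivity)
    list(threshold = curve$threshold[best],
         sensitivity = curve$sensitivity[best],
         specificity = curve$specificity[best],
         score = sc[best], floor_met = FALSE)
  }
}

#' Predictive-performance elimination screen
#'
#' Keeps the models whose development-set operating sensitivity is at
#' least `min_sens` (default 90%); the rest are eliminated before
#' stability analysis.
#'
#' @param reports named list of [diagnostic_report()]s on the development
#'   set.
#' @param min_sens sensitivity floor.
#' @return character vector of surviving model identifiers.
#' @export
screen_cdis <- function(reports, min_sens = 0.90) {
  keep <- vapply(reports, function(r) r$sensitivity >= min_sens, logical(1))
  names(reports)[keep]
}

#' Render a battery of reports as a Table-2 style matrix
#'
#' Percentages to one decimal place, likelihood ratios and F1 to common
#' precision, Brier to three decimals; models across columns.
#'
#' @param reports named list of [diagnostic_report()]s.
#' @return character matrix (metrics x models).
#' @export
format_report_table <- function(reports) {
  metrics <- c("Sensitivity", "Specificity", "Negative predictive value",
               "Positive predictive value", "Negative likelihood ratio",
               "Positive likelihood ratio", "F1 score", "Brier score",
               "Weighted score")
  cols <- vapply(reports, function(r) c(
    pct1(r$sensitivity), pct1(r$specificity), pct1(r$npv), pct1(r$ppv),
    sprintf("%.2f", r$lr_neg), sprintf("%.2f", r$lr_pos),
    sprintf("%.3f", r$f1), sprintf("%.3f", r$brier),
    sprintf("%.3f", r$weighted_score)), character(length(metrics)))
  rownames(cols) <- metrics
  cols
}
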