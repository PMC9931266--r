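#' Cohen's kappa with asymptotic 95% confidence interval
#'
#' Unweighted Cohen's kappa for two binary raters,
#' `kappa = (p_o - p_e) / (1 - p_e)`, with the large-sample standard
#' error of Fleiss, Cohen and Everitt and a normal 95% interval
#' `kappa +/- 1.96 * SE`. When both raters use a single category
#' (`p_e = 1`) kappa is undefined and returned as `NaN` with
#' `degenerate = TRUE`.
#'
#' @param ratings_a,ratings_b equal-length binary vectors without missing
#'   entries.
#' @return list with `kappa`, `se`, `ci_low`, `ci_high`, `degenerate`.
#' @export
kappa_with_ci <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stopf("rating vectors differ in length (%d vs %d)",
          length(ratings_a), length(ratings_b))
  stopifnot(length(ratings_a) >= 2, !anyNA(ratings_a), !anyNA(ratings_b),
            is_binary01(ratings_a), is_binary01(ratings_b))
  n <- length(ratings_a)
  # joint proportions p[i, j] = P(a = i-1, b = j-1)
  p <- table(factor(ratings_a, c(0, 1)), factor(ratings_b, c(0, 1))) / n
  pa <- rowSums(p); pb <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pa * pb)
  if (1 - pe < 1e-12)
    return(list(kappa = NaN, se = NaN, ci_low = NaN, ci_high = NaN,
                degenerate = TRUE))
  k <- (po - pe) / (1 - pe)
  a_term <- sum(diag(p) * (1 - (pa + pb) * (1 - k))^2)
  b_term <- (1 - k)^2 * (p[1, 2] * (pb[1] + pa[2])^2 +
                         p[2, 1] * (pb[2] + pa[1])^2)
  c_term <- (k - pe * (1 - k))^2
  se <- sqrt(max(a_term + b_term - c_term, 0) / (n * (1 - pe)^2))
  list(kappa = unname(k), se = unname(se),
       ci_low = unname(k - 1.96 * se), ci_high = unname(k + 1.96 * se),
       degenerate = FALSE)
}

#' Phi correlation of two binary vectors
#' @param a,b binary vectors (pairwise-complete entries are used).
#' @return phi coefficient in `[-1, 1]` (`NA` when either margin is
#'   constant).
#' @export
phi_coefficient <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  den <- sqrt(as.numeric(n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

#' Missingness screen
#'
#' Drops every predictor whose missing fraction strictly exceeds
#' `max_frac` (default 5%); the outcome is never screened.
#'
#' @param cohort a [cohort()].
#' @param max_frac maximum tolerated missing fraction.
#' @return list with `kept` (names) and `dropped` (data.frame of name and
#'   missing fraction).
#' @export
missingness_filter <- function(cohort, max_frac = 0.05) {
  stopifnot(max_frac >= 0, max_frac < 1)
  fr <- vapply(cohort$predictors, function(x) mean(is.na(x)), numeric(1))
  drop <- fr > max_frac
  list(kept = names(fr)[!drop],
       dropped = data.frame(name = names(fr)[drop],
                            missing_frac = unname(fr[drop])))
}

#' Inter-rater reliability screen
#'
#' Drops every binary predictor with duplicate ratings whose kappa 95%
#' confidence interval has a lower bound below `min_ci_low` (default 0.4,
#' i.e. at least moderate agreement). Variables without duplicate ratings
#' pass unscreened and are reported as such.
#'
#' @param cohort a [cohort()] with a `rater_b` table.
#' @param min_ci_low minimum acceptable CI lower bound.
#' @return list with `kept`, `dropped` (data.frame name/kappa/ci_low/
#'   ci_high) and `unscreened` names.
#' @export
reliability_filter <- function(cohort, min_ci_low = 0.4) {
  nms <- names(cohort$predictors)
  screened <- intersect(nms, names(cohort$rater_b %||% list()))
  rows <- lapply(screened, function(nm) {
    a <- cohort$predictors[[nm]]; b <- cohort$rater_b[[nm]]
    ok <- !is.na(a) & !is.na(b)
    k <- kappa_with_ci(a[ok], b[ok])
    data.frame(name = nm, kappa = k$kappa, ci_low = k$ci_low,
               ci_high = k$ci_high)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), kappa = numeric(),
               ci_low = numeric(), ci_high = numeric())
  dropped <- tab[is.nan(tab$ci_low) | tab$ci_low < min_ci_low, , drop = FALSE]
  row.names(dropped) <- NULL
  list(kept = setdiff(nms, dropped$name), dropped = dropped,
       unscreened = setdiff(nms, screened))
}

#' Median imputation
#'
#' Replaces missing entries by the column median of the non-missing
#' values. For binary columns the median resolves to the more frequent
#' category, with an exact 50/50 tie resolved to 0; for ordinal columns a
#' half-integer median is rounded down to stay on the observed support.
#'
#' @param cohort a [cohort()].
#' @return The cohort with no missing predictor values.
#' @export
impute_median <- function(cohort) {
  for (nm in names(cohort$predictors)) {
    x <- cohort$predictors[[nm]]
    if (!anyNA(x)) next
    v <- x[!is.na(x)]
    if (length(v) == 0L)
      stopf("column '%s' is fully missing; screen it out before imputing", nm)
    fill <- if (cohort$kinds[[nm]] == "binary") {
      if (mean(v) > 0.5) 1 else 0
    } else {
      floor(stats::median(v))
    }
    x[is.na(x)] <- fill
    cohort$predictors[[nm]] <- x
  }
  cohort
}

#' Merge redundant binary predictors
#'
#' Binary pairs whose absolute phi correlation reaches `phi_threshold`
#' are combined by logical OR into a single column named
#' `<a>_or_<b>`; merge groups are the connected components of the
#' at-threshold pairs (transitive closure). Expects an imputed cohort.
#'
#' @param cohort a [cohort()] without missing values.
#' @param phi_threshold merge threshold in `(0, 1]`.
#' @return list with the merged `cohort` and a `merges` data.frame
#'   (new name, constituents, realized phi of the seeding pair).
#' @export
merge_redundant <- function(cohort, phi_threshold = 0.95) {
  stopifnot(phi_threshold > 0, phi_threshold <= 1)
  if (anyNA(as.matrix(cohort$predictors)))
    stopf("impute before merging redundant predictors")
  bin <- names(cohort$predictors)[cohort$kinds == "binary"]
  comp <- stats::setNames(seq_along(bin), bin) # union-find over binary cols
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  pair_phi <- list()
  if (length(bin) >= 2) {
    for (i in seq_len(length(bin) - 1)) for (j in (i + 1):length(bin)) {
      ph <- phi_coefficient(cohort$predictors[[bin[i]]],
                            cohort$predictors[[bin[j]]])
      if (!is.na(ph) && abs(ph) >= phi_threshold) {
        pair_phi[[paste(bin[i], bin[j])]] <- ph
        comp[find(j)] <- find(i)
      }
    }
  }
  groups <- split(bin, vapply(seq_along(bin), find, numeric(1)))
  groups <- Filter(function(g) length(g) > 1, groups)
  merges <- data.frame(name = character(), constituents = character(),
                       phi = numeric())
  for (g in groups) {
    new_nm <- paste(g, collapse = "_or_")
    merged <- as.integer(Reduce(`|`, cohort$predictors[g]))
    keys <- grep(paste(g, collapse = "|"), names(pair_phi), value = TRUE)
    merges <- rbind(merges, data.frame(
      name = new_nm, constituents = paste(g, collapse = ","),
      phi = pair_phi[[keys[1]]]))
    pos <- match(g[1], names(cohort$predictors))
    cohort$predictors[[new_nm]] <- merged
    # place the merged column where the first constituent sat
    reorder <- append(setdiff(names(cohort$predictors), c(g, new_nm)),
                      new_nm, after = pos - 1)
    cohort$predictors <- cohort$predictors[reorder]
    cohort$kinds <- c(cohort$kinds[setdiff(names(cohort$kinds), g)],
                      stats::setNames("binary", new_nm))[reorder]
    if (!is.null(cohort$rater_b))
      cohort$rater_b <- cohort$rater_b[setdiff(names(cohort$rater_b), g)]
  }
  list(cohort = cohort, merges = merges)
}

#' Outcome-stratified development/validation split
#'
#' Samples `round(dev_frac * n)` patients per outcome stratum into the
#' development fold, so development and validation prevalences agree to
#' within one patient per stratum.
#'
#' @param cohort a [cohort()] with both outcome classes present.
#' @param dev_frac development fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return list of class `split_pair` with `development`, `validation`,
#'   `dev_frac` and the development row indices `dev_idx`.
#' @export
stratified_split <- function(cohort, dev_frac = 0.663, seed = 1L) {
  stopifnot(dev_frac > 0, dev_frac < 1)
  y <- cohort$outcome
  if (length(unique(y)) < 2) stopf("both outcome classes must be present")
  if (min(table(y)) < 2) stopf("a stratum has fewer than 2 patients")
  dev_idx <- sort(unname(unlist(lapply(split(seq_along(y), y), function(idx) {
    k <- round(dev_frac * length(idx))
    k <- min(max(k, 1L), length(idx) - 1L)
    with_seed(substream_seed(seed, "stratum", y[idx[1]] ), sample(idx, k))
  }))))
  structure(list(development = cohort[dev_idx],
                 validation = cohort[-dev_idx],
                 dev_frac = dev_frac, dev_idx = dev_idx),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("<split_pair: %d development / %d validation (dev_frac %.3f); prevalences %s / %s>\n",
              n_patients(x$development), n_patients(x$validation), x$dev_frac,
              pct1(mean(x$development$outcome)),
              pct1(mean(x$validation$outcome))))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Applies the screens in fixed order — missingness filter, inter-rater
#' reliability filter, median imputation, redundancy merging, stratified
#' split — and records every removal with its reason in a screen report.
#' Re-running the pipeline on its own output changes nothing.
#'
#' @param cohort a [cohort()].
#' @param max_missing missingness threshold (drop when strictly above).
#' @param min_kappa_ci minimum kappa CI lower bound.
#' @param phi_threshold redundancy-merge threshold.
#' @param dev_frac development fraction; `split = FALSE` skips splitting.
#' @param seed split seed.
#' @param split whether to produce a development/validation split.
#' @return list of class `pcs_preprocess` with `cohort` (screened,
#'   imputed, merged), `report` (class `screen_report`) and `split`.
#' @export
preprocess <- function(cohort, max_missing = 0.05, min_kappa_ci = 0.4,
                       phi_threshold = 0.95, dev_frac = 0.663, seed = 1L,
                       split = TRUE) {
  miss <- missingness_filter(cohort, max_missing)
  keep1 <- miss$kept
  ch <- cohort
  ch$predictors <- ch$predictors[keep1]
  ch$kinds <- ch$kinds[keep1]
  if (!is.null(ch$rater_b))
    ch$rater_b <- ch$rater_b[intersect(names(ch$rater_b), keep1)]
  rel <- reliability_filter(ch, min_kappa_ci)
  ch$predictors <- ch$predictors[rel$kept]
  ch$kinds <- ch$kinds[rel$kept]
  ch <- impute_median(ch)
  mg <- merge_redundant(ch, phi_threshold)
  ch <- mg$cohort
  ch$rater_b <- NULL # screening done; duplicates are not analysis columns
  report <- structure(list(kept = names(ch$predictors),
                           dropped_missingness = miss$dropped,
                           dropped_reliability = rel$dropped,
                           unscreened = rel$unscreened,
                           merges = mg$merges),
                      class = "screen_report")
  sp <- if (split) stratified_split(ch, dev_frac, seed) else NULL
  structure(list(cohort = ch, report = report, split = sp),
            class = "pcs_preprocess")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report\n")
  cat(sprintf("  kept (%d): %s\n", length(x$kept),
              paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped_missingness))
    cat(sprintf("  dropped, missingness: %s\n",
                paste(sprintf("%s (%.1f%%)", x$dropped_missingness$name,
                              100 * x$dropped_missingness$missing_frac),
                      collapse = ", ")))
  if (nrow(x$dropped_reliability))
    cat(sprintf("  dropped, reliability: %s\n",
                paste(sprintf("%s (kappa %.2f, CI low %.2f)",
                              x$dropped_reliability$name,
                              x$dropped_reliability$kappa,
                              x$dropped_reliability$ci_low),
                      collapse = ", ")))
  if (length(x$unscreened))
    cat(sprintf("  unscreened (no duplicate ratings): %s\n",
                paste(x$unscreened, collapse = ", ")))
  if (nrow(x$merges))
    cat(sprintf("  merges: %s\n",
                paste(sprintf("%s <- {%s} (phi %.2f)", x$merges$name,
                              x$merges$constituents, x$merges$phi),
                      collapse = "; ")))
  invisible(x)
}

#' @export
print.pcs_preprocess <- function(x, ...) {
  print(x$report)
  if (!is.null(x$split)) print(x$split)
  invisible(x)
}
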