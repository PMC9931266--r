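#' Gini impurity of a two-class node
#'
#' `1 - p^2 - (1 - p)^2` with `p = pos / (pos + neg)`; `pos` and `neg`
#' may be (class-weighted) totals.
#'
#' @param pos,neg non-negative class totals, `pos + neg > 0`.
#' @return impurity in `[0, 0.5]`.
#' @export
gini_impurity <- function(pos, neg) {
  if (any(pos + neg <= 0)) stopf("gini_impurity undefined on an empty node")
  p <- pos / (pos + neg)
  1 - p^2 - (1 - p)^2
}

# ---- split search ---------------------------------------------------------
# Exhaustive search over (column, cutpoint) for the split maximizing the
# size-weighted Gini decrease under per-case class weights. Ties (within
# 1e-10) are broken by column order, then ascending cutpoint; an
# improvement must exceed the current best by more than the tolerance to
# displace it, which keeps the search deterministic under reordering of
# mathematically equivalent candidates.
split_search <- function(X, y, w, kinds, min_leaf = 1L) {
  n <- length(y)
  W <- sum(w); WP <- sum(w * y)
  g_parent <- gini_impurity(WP, W - WP)
  tol <- 1e-10
  best <- NULL
  for (j in seq_along(X)) {
    x <- X[[j]]
    vals <- sort(unique(x))
    if (length(vals) < 2) next
    f <- factor(x, levels = vals)
    w_v <- as.numeric(tapply(w, f, sum, default = 0))
    wp_v <- as.numeric(tapply(w * y, f, sum, default = 0))
    n_v <- as.integer(tabulate(f, nbins = length(vals)))
    cw <- cumsum(w_v); cwp <- cumsum(wp_v); cn <- cumsum(n_v)
    for (i in seq_len(length(vals) - 1)) { # left: x < vals[i + 1]
      nl <- cn[i]; nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      wl <- cw[i]; wpl <- cwp[i]
      wr <- W - wl; wpr <- WP - wpl
      dec <- g_parent - (wl * gini_impurity(wpl, wl - wpl) +
                         wr * gini_impurity(wpr, wr - wpr)) / W
      if (is.null(best) || dec > best$decrease + tol) {
        best <- list(col = names(X)[j], cut = vals[i + 1],
                     kind = kinds[[names(X)[j]]], decrease = dec,
                     n_left = nl, n_right = nr,
                     p_left = wpl / wl, p_right = wpr / wr)
      }
    }
  }
  best
}

#' Best single split of a cohort view
#'
#' Scans every predictor and every admissible cutpoint (for ordinal
#' predictors, between each pair of adjacent observed values) and returns
#' the condition with the largest class-weighted, size-weighted Gini
#' decrease. Ties are broken by column order, then ascending threshold.
#' The returned condition describes the branch on which it evaluates
#' `TRUE`: `name == 1` for binary predictors, `name < t` for ordinal
#' ones (`t` snapped to the upper adjacent observed value, so a cut
#' between 13 and 14 reads `gcs < 14`).
#'
#' @param cohort a [cohort()] without missing values.
#' @param class_weight weight applied to outcome-positive cases in the
#'   impurity and in weighted node risks.
#' @param min_leaf minimum rows on each side.
#' @return `NULL` when no admissible split exists, otherwise a list with
#'   `condition`, `decrease`, and per-side sizes and weighted risks.
#' @export
best_split <- function(cohort, class_weight = 5, min_leaf = 1L) {
  y <- cohort$outcome
  if (length(y) < 2 || length(unique(y)) < 2) return(NULL)
  w <- ifelse(y == 1L, class_weight, 1)
  s <- split_search(cohort$predictors, y, w, cohort$kinds, min_leaf)
  if (is.null(s)) return(NULL)
  condition <- if (s$kind == "binary") rule_condition(s$col, "==", 1)
               else rule_condition(s$col, "<", s$cut)
  list(condition = condition, cut = s$cut, decrease = s$decrease,
       n_left = s$n_left, n_right = s$n_right,
       risk_left = s$p_left, risk_right = s$p_right)
}

# ---- CART decision tree ---------------------------------------------------

#' Fit a greedy Gini decision tree
#'
#' Binary recursive partitioning with the Gini criterion, grown greedily
#' top-down with exhaustive split search at every node; growth stops at
#' `max_depth`, when a side would fall under `min_leaf` rows, or at
#' purity. Leaf risks are the class-weighted positive fractions. The fit
#' is fully deterministic: refitting on the same data always yields the
#' identical tree.
#'
#' @param cohort a [cohort()] without missing values (impute first).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum rows per leaf.
#' @param class_weight weight on outcome-positive cases.
#' @return An object of class `cart_tree`.
#' @export
cart_tree <- function(cohort, max_depth = 3, min_leaf = 10,
                      class_weight = 5) {
  if (anyNA(as.matrix(cohort$predictors)))
    stopf("cohort has missing values; impute before fitting")
  y <- cohort$outcome
  w <- ifelse(y == 1L, class_weight, 1)
  if (length(unique(y)) < 2)
    warning("single-class input; returning a degenerate single-leaf tree",
            call. = FALSE)
  grow <- function(idx, depth) {
    yy <- y[idx]; ww <- w[idx]
    risk <- sum(ww * yy) / sum(ww)
    leaf <- list(leaf = TRUE, risk = risk, n = length(idx), pos = sum(yy))
    if (depth >= max_depth || length(unique(yy)) < 2) return(leaf)
    s <- split_search(lapply(cohort$predictors, `[`, idx), yy, ww,
                      cohort$kinds, min_leaf)
    if (is.null(s) || s$decrease <= 1e-12) return(leaf)
    x <- cohort$predictors[[s$col]][idx]
    cond <- if (s$kind == "binary") rule_condition(s$col, "==", 1)
            else rule_condition(s$col, "<", s$cut)
    left <- x < s$cut
    # `yes` child = branch where the condition holds
    if (s$kind == "binary") {
      list(leaf = FALSE, condition = cond, n = length(idx), pos = sum(yy),
           yes = grow(idx[!left], depth + 1), no = grow(idx[left], depth + 1))
    } else {
      list(leaf = FALSE, condition = cond, n = length(idx), pos = sum(yy),
           yes = grow(idx[left], depth + 1), no = grow(idx[!left], depth + 1))
    }
  }
  root <- grow(seq_along(y), 0L)
  structure(list(root = root,
                 params = list(max_depth = max_depth, min_leaf = min_leaf,
                               class_weight = class_weight),
                 kinds = cohort$kinds),
            class = "cart_tree")
}

tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(tree_depth(node$yes), tree_depth(node$no))
}

#' @export
print.cart_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%srisk %.4f  (n=%d, pos=%d)\n", pad, node$risk,
                  node$n, node$pos))
    } else {
      cc <- node$condition
      cat(sprintf("%sIF %s %s %s:\n", pad, cc$predictor, cc$op, cc$threshold))
      rec(node$yes, indent + 1)
      cat(sprintf("%sELSE:\n", pad))
      rec(node$no, indent + 1)
    }
  }
  cat(sprintf("CART decision tree (depth %d, class weight %g)\n",
              tree_depth(x$root), x$params$class_weight))
  rec(x$root, 1)
  invisible(x)
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  df <- model_frame(object, newdata)
  out <- numeric(nrow(df))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$risk; return() }
    cc <- node$condition
    x <- df[[cc$predictor]]
    fires <- switch(cc$op,
                    "==" = x[idx] == cc$threshold,
                    "<"  = x[idx] < cc$threshold,
                    ">=" = x[idx] >= cc$threshold)
    rec(node$yes, idx[fires])
    rec(node$no, idx[!fires])
  }
  rec(object$root, seq_len(nrow(df)))
  out
}

# ---- CDI rule list --------------------------------------------------------

#' Fit a CART rule list by one-sided partitioning
#'
#' At each step the best Gini split of the remaining patients is found,
#' the higher-risk side is peeled off as an IF-condition leaf carrying
#' its class-weighted risk, and induction recurses on the remainder;
#' growth stops at `max_rules`, when no admissible split remains, or at
#' purity. The remainder forms the default ("very low risk") leaf. Like
#' [cart_tree()], the fit is deterministic.
#'
#' @inheritParams cart_tree
#' @param max_rules maximum number of conditions (interpretability cap,
#'   at most 10 logical steps).
#' @return An object of class `cdi_rule_list` with ordered `conditions`,
#'   `leaf_risks`, `default_risk` and `provenance = "fitted"`.
#' @export
cart_rule_list <- function(cohort, max_rules = 10, min_leaf = 10,
                           class_weight = 5) {
  stopifnot(max_rules >= 1, max_rules <= 10)
  if (anyNA(as.matrix(cohort$predictors)))
    stopf("cohort has missing values; impute before fitting")
  y <- cohort$outcome
  w <- ifelse(y == 1L, class_weight, 1)
  if (length(unique(y)) < 2)
    warning("single-class input; returning a default-only rule list",
            call. = FALSE)
  idx <- seq_along(y)
  conds <- list(); risks <- numeric(); leaf_n <- integer(); leaf_pos <- integer()
  while (length(conds) < max_rules && length(unique(y[idx])) > 1) {
    s <- split_search(lapply(cohort$predictors, `[`, idx), y[idx], w[idx],
                      cohort$kinds, min_leaf)
    if (is.null(s) || s$decrease <= 1e-12) break
    x <- cohort$predictors[[s$col]][idx]
    left <- x < s$cut
    high_left <- s$p_left > s$p_right ||
      (s$p_left == s$p_right && s$n_left <= s$n_right)
    cond <- if (s$kind == "binary") {
      rule_condition(s$col, "==", if (high_left) 0 else 1)
    } else if (high_left) {
      rule_condition(s$col, "<", s$cut)
    } else {
      rule_condition(s$col, ">=", s$cut)
    }
    peel <- if (high_left) left else !left
    conds[[length(conds) + 1L]] <- cond
    risks <- c(risks, if (high_left) s$p_left else s$p_right)
    leaf_n <- c(leaf_n, sum(peel))
    leaf_pos <- c(leaf_pos, sum(y[idx][peel]))
    idx <- idx[!peel]
  }
  wd <- w[idx]; yd <- y[idx]
  default_risk <- if (length(idx)) sum(wd * yd) / sum(wd) else 0
  new_rule_list(conds, risks, default_risk, provenance = "fitted",
                leaf_n = leaf_n, leaf_pos = leaf_pos,
                default_n = length(idx), default_pos = sum(yd),
                params = list(max_rules = max_rules, min_leaf = min_leaf,
                              class_weight = class_weight))
}

new_rule_list <- function(conditions, leaf_risks, default_risk,
                          provenance, leaf_n = NULL, leaf_pos = NULL,
                          default_n = NULL, default_pos = NULL,
                          params = list()) {
  stopifnot(length(conditions) <= 10, is_prob(leaf_risks),
            is_prob(default_risk))
  if (provenance == "reference" && length(leaf_risks) > 1 &&
      any(diff(leaf_risks) >= 0))
    stopf("reference rule lists must have strictly decreasing leaf risks")
  structure(list(conditions = conditions, leaf_risks = leaf_risks,
                 default_risk = default_risk, provenance = provenance,
                 leaf_n = leaf_n, leaf_pos = leaf_pos,
                 default_n = default_n, default_pos = default_pos,
                 params = params),
            class = "cdi_rule_list")
}

#' The frozen reference clinical decision instrument
#'
#' The fixed seven-condition ordered rule list in the style of the PECARN
#' intra-abdominal-injury instrument: a patient is "very low risk"
#' exactly when no condition fires. Condition names, the GCS cut and the
#' (synthetic, monotonically decreasing) leaf risks are configuration —
#' the defaults match the predictors of [pecarn_sim_config()].
#'
#' @param predictors seven predictor names in rule order; the second
#'   entry is the ordinal GCS-type variable thresholded below
#'   `gcs_threshold`.
#' @param gcs_threshold ordinal threshold for the second condition.
#' @param leaf_risks strictly decreasing per-condition risks.
#' @param default_risk very-low-risk leaf risk, below the last leaf risk.
#' @return A `cdi_rule_list` with `provenance = "reference"`.
#' @export
pecarn_cdi <- function(predictors = c("abd_trauma_seatbelt", "gcs",
                                      "abd_tenderness", "vomiting",
                                      "thoracic_wall_trauma", "abd_pain",
                                      "decreased_breath_sounds"),
                       gcs_threshold = 14,
                       leaf_risks = c(0.09, 0.06, 0.03, 0.007, 0.005,
                                      0.0035, 0.0025),
                       default_risk = 0.001) {
  stopifnot(length(predictors) == 7, length(leaf_risks) == 7)
  conds <- c(list(rule_condition(predictors[1], "==", 1),
                  rule_condition(predictors[2], "<", gcs_threshold)),
             lapply(predictors[3:7], rule_condition, op = "==", threshold = 1))
  new_rule_list(conds, leaf_risks, default_risk, provenance = "reference")
}

#' Truncate a rule list to its first k conditions
#'
#' @param object a `cdi_rule_list`.
#' @param k number of leading conditions to keep.
#' @return A `cdi_rule_list` with the same default risk.
#' @export
truncate_rules <- function(object, k) {
  stopifnot(inherits(object, "cdi_rule_list"), k >= 1,
            k <= length(object$conditions))
  new_rule_list(object$conditions[seq_len(k)], object$leaf_risks[seq_len(k)],
                object$default_risk, provenance = object$provenance,
                params = object$params)
}

#' @export
print.cdi_rule_list <- function(x, ...) {
  cat(sprintf("CDI rule list (%s, %d conditions)\n", x$provenance,
              length(x$conditions)))
  for (j in seq_along(x$conditions)) {
    cc <- x$conditions[[j]]
    extra <- if (!is.null(x$leaf_n))
      sprintf("  (n=%d, pos=%d)", x$leaf_n[j], x$leaf_pos[j]) else ""
    cat(sprintf("  %s %s %s %s: risk %.4f%s\n",
                if (j == 1) "IF  " else "ELIF", cc$predictor, cc$op,
                cc$threshold, x$leaf_risks[j], extra))
  }
  extra <- if (!is.null(x$default_n))
    sprintf("  (n=%d, pos=%d)", x$default_n, x$default_pos) else ""
  cat(sprintf("  ELSE very low risk: %.4f%s\n", x$default_risk, extra))
  invisible(x)
}

model_frame <- function(model, newdata) {
  df <- if (inherits(newdata, "cohort")) newdata$predictors else
    as.data.frame(newdata)
  need <- model_variables(model)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("schema error: missing predictor column(s) %s",
          paste(miss, collapse = ", "))
  if (anyNA(df[need]))
    stopf("missing values in model predictors; impute first")
  df
}

#' @export
predict.cdi_rule_list <- function(object, newdata,
                                  type = c("risk", "match", "positive"),
                                  ...) {
  type <- match.arg(type)
  df <- model_frame(object, newdata)
  fm <- first_match(object$conditions, df)
  switch(type,
         match = fm,
         positive = as.integer(fm > 0L),
         risk = c(object$default_risk, object$leaf_risks)[fm + 1L])
}

#' Predictors referenced by a fitted model
#' @param model a `cdi_rule_list`, `cart_tree` or `rule_ensemble`.
#' @return character vector of predictor names.
#' @export
model_variables <- function(model) UseMethod("model_variables")

#' @export
model_variables.cdi_rule_list <- function(model) {
  unique(vapply(model$conditions, `[[`, character(1), "predictor"))
}

#' @export
model_variables.cart_tree <- function(model) {
  rec <- function(node) {
    if (node$leaf) character(0)
    else c(node$condition$predictor, rec(node$yes), rec(node$no))
  }
  unique(rec(model$root))
}

#' @export
coef.cdi_rule_list <- function(object, ...) {
  stats::setNames(c(object$leaf_risks, object$default_risk),
                  c(vapply(object$conditions, function(cc)
                    paste(cc$predictor, cc$op, cc$threshold), character(1)),
                    "(very low risk)"))
}

#' @export
summary.cdi_rule_list <- function(object, ...) {
  data.frame(
    step = c(seq_along(object$conditions), NA),
    condition = c(vapply(object$conditions, function(cc)
      paste(cc$predictor, cc$op, cc$threshold), character(1)),
      "(no condition fires)"),
    risk = c(object$leaf_risks, object$default_risk),
    n = if (!is.null(object$leaf_n)) c(object$leaf_n, object$default_n)
        else NA_integer_,
    pos = if (!is.null(object$leaf_pos)) c(object$leaf_pos, object$default_pos)
          else NA_integer_)
}

# ---- refit randomness -----------------------------------------------------

#' Refit-randomness spread of a model fitter
#'
#' Refits a model under seeds `1..n_seeds` and reports the maximum
#' pairwise difference in the weighted operating score and in the
#' predicted-risk vectors — the "randomness on redevelopment" marker of
#' model-level stability. Deterministic fitters (CART tree, rule list)
#' have spread exactly zero.
#'
#' @param fitter `function(cohort, seed)` returning a fitted model.
#' @param cohort development [cohort()] (no missing values).
#' @param n_seeds number of refits (>= 2).
#' @param w sensitivity weight of the operating score.
#' @param sens_floor sensitivity floor used to pick each refit's
#'   operating point.
#' @return list with `score_spread`, `risk_spread` and per-seed `scores`.
#' @export
refit_randomness <- function(fitter, cohort, n_seeds = 10, w = 5,
                             sens_floor = 0.9) {
  stopifnot(n_seeds >= 2)
  risks <- vapply(seq_len(n_seeds), function(s)
    predict(fitter(cohort, s), cohort), numeric(n_patients(cohort)))
  scores <- apply(risks, 2, function(r) {
    op <- select_operating_point(sens_spec_curve(r, cohort$outcome),
                                 w = w, sens_floor = sens_floor)
    op$score
  })
  list(score_spread = max(scores) - min(scores),
       risk_spread = max(apply(risks, 1, function(z) max(z) - min(z))),
       scores = scores)
}

# ---- JSON serialization ---------------------------------------------------

#' Serialize fitted models to JSON
#'
#' Rule lists, trees and rule ensembles round-trip through a documented
#' JSON schema carrying ordered conditions, risks, provenance and fit
#' parameters.
#'
#' @param model a fitted model.
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   the reconstructed model.
#' @export
write_model_json <- function(model, path) {
  obj <- serialize_model(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "cdi_rule_list")) {
    list(type = "rule_list", provenance = model$provenance,
         conditions = model$conditions, leaf_risks = model$leaf_risks,
         default_risk = model$default_risk, params = model$params)
  } else if (inherits(model, "cart_tree")) {
    list(type = "cart_tree", params = model$params,
         kinds = as.list(model$kinds), root = model$root)
  } else if (inherits(model, "rule_ensemble")) {
    list(type = "rule_ensemble", params = model$params,
         intercept = model$intercept, weights = model$weights,
         rules = lapply(model$rules, function(r) r))
  } else stopf("unsupported model class")
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  conds <- function(lst) lapply(lst, function(cc)
    rule_condition(cc$predictor, cc$op, cc$threshold))
  if (obj$type == "rule_list") {
    new_rule_list(conds(obj$conditions), unlist(obj$leaf_risks),
                  obj$default_risk, provenance = obj$provenance,
                  params = obj$params)
  } else if (obj$type == "cart_tree") {
    fix <- function(node) {
      if (isTRUE(node$leaf)) {
        list(leaf = TRUE, risk = node$risk, n = node$n, pos = node$pos)
      } else {
        list(leaf = FALSE,
             condition = rule_condition(node$condition$predictor,
                                        node$condition$op,
                                        node$condition$threshold),
             n = node$n, pos = node$pos,
             yes = fix(node$yes), no = fix(node$no))
      }
    }
    structure(list(root = fix(obj$root), params = obj$params,
                   kinds = unlist(obj$kinds)),
              class = "cart_tree")
  } else if (obj$type == "rule_ensemble") {
    structure(list(rules = lapply(obj$rules, conds),
                   weights = unlist(obj$weights),
                   intercept = obj$intercept, params = obj$params),
              class = "rule_ensemble")
  } else stopf("unknown model type '%s'", obj$type)
}
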