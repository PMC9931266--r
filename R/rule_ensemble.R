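# Simplified RuleFit-style model: conjunctive rules mined from bagged
# shallow Gini trees, selected greedily under the weighted operating
# score, combined through a logistic link.

#' Fit a sparse rule ensemble
#'
#' Candidate conjunctive rules are the root-to-node condition paths of
#' `n_trees` depth-limited Gini trees fitted on bootstrap resamples;
#' after deduplication, rules are added one at a time, each addition
#' refitting a weighted logistic model on the selected rule indicators
#' and keeping the rule that most improves the best achievable weighted
#' operating score on the development data (excluding the degenerate
#' all-positive operating point, which ignores the model), until
#' `max_rules` or no improvement. The fit is reproducible under `seed`.
#'
#' @inheritParams cart_tree
#' @param n_trees number of bagged trees mined for candidate rules.
#' @param tree_depth depth cap of the mining trees.
#' @param max_rules maximum selected rules (interpretability cap).
#' @param seed integer seed for the bootstrap resamples.
#' @param w,sens_floor weighted-score parameters used during selection.
#' @return An object of class `rule_ensemble`.
#' @export
rule_ensemble <- function(cohort, n_trees = 20, tree_depth = 2,
                          max_rules = 10, min_leaf = 10, class_weight = 5,
                          seed = 1L, w = 5, sens_floor = 0.9) {
  stopifnot(max_rules >= 1, max_rules <= 10, n_trees >= 1)
  if (anyNA(as.matrix(cohort$predictors)))
    stopf("cohort has missing values; impute before fitting")
  y <- cohort$outcome
  n <- length(y)
  cand <- list(); seen <- character(0)
  for (t in seq_len(n_trees)) {
    idx <- with_seed(substream_seed(seed, "bag", t),
                     sample.int(n, n, replace = TRUE))
    boot <- cohort[idx]
    if (length(unique(boot$outcome)) < 2) next
    tr <- cart_tree(boot, max_depth = tree_depth, min_leaf = min_leaf,
                    class_weight = class_weight)
    for (r in tree_paths(tr$root)) {
      key <- rule_key(r)
      if (!key %in% seen) { seen <- c(seen, key); cand[[key]] <- r }
    }
  }
  weights_case <- ifelse(y == 1L, class_weight, 1)
  if (!length(cand)) {
    warning("no candidate rules; returning an intercept-only model",
            call. = FALSE)
    return(structure(list(rules = list(), weights = numeric(0),
                          intercept = stats::qlogis(max(min(mean(y), 1 - 1e-9),
                                                        1e-9)),
                          params = list(n_trees = n_trees,
                                        tree_depth = tree_depth,
                                        max_rules = max_rules, seed = seed)),
                     class = "rule_ensemble"))
  }
  Z <- vapply(cand, function(r) rule_fires(r, cohort$predictors), numeric(n))
  # Selection objective: best achievable weighted score over the
  # candidate model's own operating points. The all-positive point
  # (threshold at the minimum risk) classifies every patient positive
  # regardless of the rules and is excluded, otherwise it dominates every
  # partial-coverage rule set at w = 5 and the greedy search cannot rank
  # candidates.
  score_of <- function(risks) {
    if (length(unique(y)) < 2) return(NA_real_)
    curve <- sens_spec_curve(risks, y)
    if (nrow(curve) > 1) curve <- curve[-1, , drop = FALSE]
    max(weighted_score(curve$sensitivity, curve$specificity, w))
  }
  selected <- integer(0)
  fit <- NULL
  best_score <- -Inf
  repeat {
    if (length(selected) >= max_rules) break
    trial <- setdiff(seq_along(cand), selected)
    gain <- rep(-Inf, length(trial))
    fits <- vector("list", length(trial))
    for (k in seq_along(trial)) {
      cols <- c(selected, trial[k])
      d <- data.frame(y = y, Z[, cols, drop = FALSE])
      fits[[k]] <- suppressWarnings(
        stats::glm(y ~ ., data = d, family = stats::binomial(),
                   weights = weights_case))
      gain[k] <- score_of(stats::predict(fits[[k]], type = "response"))
    }
    k_best <- which.max(gain)
    if (!is.finite(gain[k_best]) || gain[k_best] <= best_score + 1e-12) break
    best_score <- gain[k_best]
    selected <- c(selected, trial[k_best])
    fit <- fits[[k_best]]
  }
  if (is.null(fit)) { # nothing improved over nothing: keep the single best
    d <- data.frame(y = y, Z[, 1, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = d,
                                       family = stats::binomial(),
                                       weights = weights_case))
    selected <- 1L
  }
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  structure(list(rules = unname(cand[selected]),
                 weights = unname(cf[-1]), intercept = unname(cf[1]),
                 params = list(n_trees = n_trees, tree_depth = tree_depth,
                               max_rules = max_rules, min_leaf = min_leaf,
                               class_weight = class_weight, seed = seed)),
            class = "rule_ensemble")
}

# all root-to-node condition paths (condition or its negation per branch)
tree_paths <- function(node, prefix = list()) {
  if (node$leaf) return(if (length(prefix)) list(prefix) else list())
  cc <- node$condition
  neg <- negate_condition(cc)
  c(if (length(prefix)) list(prefix) else list(),
    tree_paths(node$yes, c(prefix, list(cc))),
    tree_paths(node$no, c(prefix, list(neg))))
}

negate_condition <- function(cc) {
  switch(cc$op,
         "==" = rule_condition(cc$predictor, "==", 1 - cc$threshold),
         "<"  = rule_condition(cc$predictor, ">=", cc$threshold),
         ">=" = rule_condition(cc$predictor, "<", cc$threshold))
}

rule_key <- function(conds) {
  paste(sort(vapply(conds, function(cc)
    paste(cc$predictor, cc$op, cc$threshold), character(1))), collapse = " & ")
}

rule_fires <- function(conds, df) {
  out <- rep(TRUE, nrow(df))
  for (cc in conds) {
    x <- df[[cc$predictor]]
    out <- out & switch(cc$op,
                        "==" = x == cc$threshold,
                        "<"  = x < cc$threshold,
                        ">=" = x >= cc$threshold)
  }
  as.numeric(out)
}

#' @export
predict.rule_ensemble <- function(object, newdata, ...) {
  df <- model_frame(object, newdata)
  eta <- rep(object$intercept, nrow(df))
  for (j in seq_along(object$rules))
    eta <- eta + object$weights[j] * rule_fires(object$rules[[j]], df)
  stats::plogis(eta)
}

#' @export
model_variables.rule_ensemble <- function(model) {
  unique(unlist(lapply(model$rules, function(r)
    vapply(r, `[[`, character(1), "predictor"))))
}

#' @export
print.rule_ensemble <- function(x, ...) {
  cat(sprintf("Rule ensemble (%d rules, logistic link, intercept %.3f)\n",
              length(x$rules), x$intercept))
  for (j in seq_along(x$rules)) {
    cat(sprintf("  %+0.3f * [%s]\n", x$weights[j],
                paste(vapply(x$rules[[j]], function(cc)
                  paste(cc$predictor, cc$op, cc$threshold), character(1)),
                  collapse = " & ")))
  }
  invisible(x)
}

#' @export
coef.rule_ensemble <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights),
                  c("(intercept)",
                    vapply(object$rules, function(r)
                      paste(vapply(r, function(cc)
                        paste(cc$predictor, cc$op, cc$threshold),
                        character(1)), collapse = " & "), character(1))))
}
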