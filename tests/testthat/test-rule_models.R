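test_that("gini impurity evaluates its closed form", {
  expect_equal(gini_impurity(5, 5), 0.5)
  expect_equal(gini_impurity(10, 0), 0.0)
  expect_equal(gini_impurity(3, 1), 0.375) # 1 - 0.75^2 - 0.25^2
  expect_error(gini_impurity(0, 0), "empty")
})

test_that("best_split finds perfect separators and breaks ties by column order", {
  set.seed(1)
  df <- data.frame(n1 = rbinom(30, 1, 0.5), sep = 0L, n2 = rbinom(30, 1, 0.5))
  df$sep <- as.integer(seq_len(30) <= 10)
  y <- df$sep
  ch <- cohort(df, y)
  s <- best_split(ch, class_weight = 1)
  expect_equal(s$condition$predictor, "sep")
  w <- ifelse(y == 1, 1, 1)
  expect_equal(s$decrease, gini_impurity(sum(y), sum(1 - y)),
               tolerance = 1e-12)
  # duplicate columns: first by column order wins
  dup <- cohort(data.frame(first = df$sep, second = df$sep), y)
  expect_equal(best_split(dup)$condition$predictor, "first")
  # no admissible split
  flat <- cohort(data.frame(x = rep(1L, 4)), c(0L, 1L, 0L, 1L))
  expect_null(best_split(flat))
})

test_that("best_split equals exhaustive enumeration on random tables", {
  for (s in 1:25) {
    ch <- rand_cohort(n = 10 + (s %% 5) * 10, p = 2 + s %% 5, seed = 100 + s)
    cw <- c(1, 2, 5)[1 + s %% 3]
    got <- best_split(ch, class_weight = cw, min_leaf = 1)
    want <- oracle_best_split(ch$predictors, ch$outcome, class_weight = cw)
    expect_equal(got$condition$predictor, want$col)
    expect_equal(got$decrease, want$decrease, tolerance = 1e-9)
  }
})

test_that("cart_tree is deterministic and recovers an exact predictor", {
  set.seed(7)
  a <- rbinom(60, 1, 0.4)
  ch <- cohort(data.frame(a = a, b = rbinom(60, 1, 0.5)), a)
  tr <- cart_tree(ch)
  expect_false(tr$root$leaf)
  expect_equal(tr$root$condition$predictor, "a")
  expect_true(tr$root$yes$leaf && tr$root$no$leaf)
  expect_equal(tr$root$yes$risk, 1.0)
  expect_equal(tr$root$no$risk, 0.0)
  expect_identical(cart_tree(ch), cart_tree(ch)) # refitting changes nothing
  expect_warning(cart_tree(cohort(data.frame(x = c(0, 1, 0, 1)),
                                  rep(0L, 4))),
                 "single-class")
  expect_error(cart_tree(cohort(data.frame(x = c(NA, 1, 0)), c(0L, 1L, 0L))),
               "impute")
})

test_that("rule list peels disjoint risk groups and respects stopping rules", {
  # outcome = A OR B with disjoint supports
  df <- data.frame(A = rep(c(1, 0, 0), each = 10),
                   B = rep(c(0, 1, 0), each = 10))
  ch <- cohort(df, as.integer(df$A | df$B))
  rl <- cart_rule_list(ch, min_leaf = 5)
  expect_equal(length(rl$conditions), 2L)
  expect_setequal(vapply(rl$conditions, `[[`, character(1), "predictor"),
                  c("A", "B"))
  expect_equal(rl$leaf_risks, c(1, 1))
  expect_equal(rl$default_risk, 0)
  expect_equal(rl$provenance, "fitted")
  # min_leaf larger than any admissible side stops growth immediately
  short <- cart_rule_list(ch, min_leaf = 25)
  expect_equal(length(short$conditions), 0L)
  expect_true(length(cart_rule_list(rand_cohort(200, 6, 9),
                                    min_leaf = 2)$conditions) <= 10)
  expect_error(cart_rule_list(ch, max_rules = 11), "max_rules")
})

test_that("ordinal splits render against the upper adjacent value", {
  gcs <- c(rep(15L, 20), rep(13L, 5), rep(3L, 5))
  ch <- cohort(data.frame(gcs = gcs), as.integer(gcs < 14),
               kinds = c(gcs = "ordinal"))
  s <- best_split(ch, min_leaf = 1)
  expect_equal(s$condition$op, "<")
  expect_equal(s$condition$threshold, 15) # midpoint 13|15 snaps to 15
  rl <- cart_rule_list(ch, min_leaf = 2)
  expect_equal(rl$conditions[[1]]$op, "<")
})

test_that("the reference CDI classifies by first match", {
  cdi <- pecarn_cdi()
  expect_equal(length(cdi$conditions), 7L)
  expect_equal(cdi$provenance, "reference")
  expect_true(all(diff(cdi$leaf_risks) < 0))
  ch <- reference_schema_cohort(n = 4)
  expect_equal(predict(cdi, ch, type = "positive"), rep(0L, 4))
  expect_equal(predict(cdi, ch), rep(cdi$default_risk, 4))
  gcs13 <- ch
  gcs13$predictors$gcs[2] <- 13L
  expect_equal(predict(cdi, gcs13, type = "match")[2], 2L)
  expect_equal(predict(cdi, gcs13)[2], cdi$leaf_risks[2])
  # hand-traced first-match evaluation on 20 crafted patients
  set.seed(42)
  crafted <- reference_schema_cohort(n = 20)
  for (nm in names(crafted$predictors))
    crafted$predictors[[nm]] <- if (nm == "gcs")
      sample(c(3L, 13L, 14L, 15L), 20, replace = TRUE)
    else rbinom(20, 1, 0.3)
  manual <- numeric(20)
  for (i in 1:20) {
    row <- crafted$predictors[i, ]
    risk <- cdi$default_risk
    for (j in seq_along(cdi$conditions)) {
      cc <- cdi$conditions[[j]]
      hit <- switch(cc$op, "==" = row[[cc$predictor]] == cc$threshold,
                    "<" = row[[cc$predictor]] < cc$threshold)
      if (hit) { risk <- cdi$leaf_risks[j]; break }
    }
    manual[i] <- risk
  }
  expect_equal(predict(cdi, crafted), manual)
  expect_error(predict(cdi, cohort(data.frame(gcs = 15L), 0L)),
               "missing predictor")
})

test_that("truncation keeps the leading conditions and the default leaf", {
  cdi <- pecarn_cdi()
  t3 <- truncate_rules(cdi, 3)
  expect_equal(length(t3$conditions), 3L)
  expect_equal(t3$leaf_risks, cdi$leaf_risks[1:3])
  expect_equal(t3$default_risk, cdi$default_risk)
})

test_that("operating sensitivity is non-decreasing in the class weight", {
  ch <- impute_median(generate_cohort(pecarn_sim_config(n = 6000, seed = 5)))
  sens <- vapply(c(1, 2, 5, 10), function(cw) {
    rl <- cart_rule_list(ch, class_weight = cw)
    cc <- confusion(ch$outcome, predict(rl, ch, type = "positive"))
    cc$tp / (cc$tp + cc$fn)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("models round-trip through their JSON schema", {
  ch <- impute_median(generate_cohort(pecarn_sim_config(n = 2000, seed = 8)))
  models <- list(cart_rule_list(ch), cart_tree(ch),
                 rule_ensemble(ch, n_trees = 5, seed = 3), pecarn_cdi())
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    back <- read_model_json(path)
    expect_equal(predict(back, ch), predict(m, ch), tolerance = 1e-12)
    expect_setequal(model_variables(back), model_variables(m))
  }
})

test_that("refit randomness is exactly zero for deterministic fitters", {
  ch <- impute_median(generate_cohort(pecarn_sim_config(n = 3000, seed = 2)))
  rr_tree <- refit_randomness(function(c2, s) cart_tree(c2), ch, n_seeds = 3)
  rr_list <- refit_randomness(function(c2, s) cart_rule_list(c2), ch,
                              n_seeds = 3)
  expect_identical(rr_tree$score_spread, 0)
  expect_identical(rr_tree$risk_spread, 0)
  expect_identical(rr_list$score_spread, 0)
  expect_identical(rr_list$risk_spread, 0)
  # single-tree ensemble on a strong signal stays within tolerance
  rr_ens <- refit_randomness(function(c2, s)
    rule_ensemble(c2, n_trees = 1, seed = s), ch, n_seeds = 5)
  expect_lt(rr_ens$score_spread, 0.05)
  expect_error(refit_randomness(function(c2, s) cart_tree(c2), ch,
                                n_seeds = 1),
               "n_seeds")
})

test_that("rule ensemble selects informative rules reproducibly", {
  set.seed(13)
  a <- rbinom(200, 1, 0.4)
  y <- as.integer(a & rbinom(200, 1, 0.9))
  ch <- cohort(data.frame(a = a, junk = rbinom(200, 1, 0.5)), y)
  en <- rule_ensemble(ch, n_trees = 5, seed = 1, min_leaf = 5)
  expect_true("a" %in% model_variables(en))
  expect_equal(en, rule_ensemble(ch, n_trees = 5, seed = 1, min_leaf = 5))
  # the selected set scores at least as well as any of its single rules
  sel_score <- function(risks) {
    curve <- sens_spec_curve(risks, y)
    if (nrow(curve) > 1) curve <- curve[-1, ]
    max(weighted_score(curve$sensitivity, curve$specificity, 5))
  }
  full <- sel_score(predict(en, ch))
  for (j in seq_along(en$rules)) {
    single <- en
    single$rules <- en$rules[j]
    single$weights <- en$weights[j]
    fit <- suppressWarnings(stats::glm(
      y ~ z, data = data.frame(y = y, z = predict(single, ch)),
      family = stats::binomial(), weights = ifelse(y == 1, 5, 1)))
    expect_gte(full + 1e-9, sel_score(stats::fitted(fit)))
  }
  # single binary predictor rules cannot beat the selected set either
  for (nm in names(ch$predictors)) {
    fit <- suppressWarnings(stats::glm(
      y ~ z, data = data.frame(y = y, z = ch$predictors[[nm]]),
      family = stats::binomial(), weights = ifelse(y == 1, 5, 1)))
    expect_gte(full + 1e-9, sel_score(stats::fitted(fit)))
  }
})

test_that("fitted models respect the ten-step interpretability cap", {
  for (s in 1:5) {
    ch <- rand_cohort(300, 8, seed = 400 + s, prevalence = 0.4)
    expect_lte(length(cart_rule_list(ch, min_leaf = 2)$conditions), 10L)
    expect_lte(length(rule_ensemble(ch, n_trees = 5, seed = s,
                                    min_leaf = 5)$rules), 10L)
  }
})
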