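test_that("generation is deterministic and column-order independent", {
  cfg <- tiny_config(n = 400, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # permuting the predictor list leaves every column's draw unchanged
  cfg2 <- cfg
  cfg2$predictors <- rev(cfg2$predictors)
  ch <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg2)
  for (nm in names(ch$predictors))
    expect_identical(ch$predictors[[nm]], ch2$predictors[[nm]])
  expect_identical(ch$outcome, ch2$outcome)
})

test_that("realized marginals and outcome prevalence match the configuration", {
  cfg <- pecarn_sim_config(n = 12044, seed = 3)
  ch <- generate_cohort(cfg)
  for (sp in cfg$predictors) {
    if (sp$kind != "binary") next
    p <- sp$prevalence
    se <- sqrt(p * (1 - p) / cfg$n)
    expect_lt(abs(mean(ch$predictors[[sp$name]], na.rm = TRUE) - p),
              3 * se + 1e-12, label = sp$name)
  }
  prev <- implied_prevalence(cfg)
  expect_equal(prev, 0.0173, tolerance = 0.01)
  se <- sqrt(prev * (1 - prev) / cfg$n)
  # ~205 expected outcome-positive patients at the development site scale
  expect_lt(abs(mean(ch$outcome) - prev), 3 * se)
  # GCS < 14 mass
  expect_equal(mean(ch$predictors$gcs < 14, na.rm = TRUE), 0.066,
               tolerance = 0.15)
})

test_that("degenerate rules behave as specified", {
  expect_warning(
    cfg <- tiny_config(n = 300, seed = 5, risks = c(0, 0), default_risk = 0),
    "degenerate")
  expect_true(all(generate_cohort(cfg)$outcome == 0L))
  expect_error(tiny_config(risks = c(0.2, 0.4)), "non-increasing")
  expect_warning(
    generator_config(list(binary_spec("a", 0.5)),
                     true_rule(list(rule_condition("a", "==", 1)), 1, 1),
                     n = 10),
    "degenerate")
  expect_error(
    generator_config(list(binary_spec("a", 0.5)),
                     true_rule(list(rule_condition("zz", "==", 1)), 0.5, 0.1),
                     n = 10),
    "unknown predictor")
})

test_that("redundant pairs attain their target phi", {
  preds <- list(binary_spec("a", 0.4),
                binary_spec("a_copy", 0.4, redundant_with = "a", phi = 1.0),
                binary_spec("b", 0.3, redundant_with = "a", phi = 0.6))
  rule <- true_rule(list(rule_condition("a", "==", 1)), 0.3, 0.05)
  cfg <- generator_config(preds, rule, n = 20000, seed = 9)
  ch <- generate_cohort(cfg)
  expect_identical(ch$predictors$a, ch$predictors$a_copy)
  expect_equal(phi_coefficient(ch$predictors$a, ch$predictors$a_copy), 1.0)
  expect_equal(phi_coefficient(ch$predictors$a, ch$predictors$b), 0.6,
               tolerance = 0.05)
  # infeasible phi for mismatched prevalences is rejected
  expect_error(
    generate_cohort(generator_config(
      list(binary_spec("a", 0.9),
           binary_spec("c", 0.1, redundant_with = "a", phi = 1.0)),
      rule, n = 100, seed = 1)),
    "infeasible")
})

test_that("simulated second rater attains its target kappa", {
  preds <- list(binary_spec("x", 0.3), binary_spec("y", 0.5))
  rule <- true_rule(list(rule_condition("x", "==", 1)), 0.2, 0.02)
  ch <- generate_cohort(generator_config(preds, rule, n = 20000, seed = 4))
  perfect <- generate_rater_pair(ch, c(x = 1.0), seed = 1)
  expect_identical(perfect$rater_b$x, perfect$predictors$x)
  chance <- generate_rater_pair(ch, c(y = 0.0), seed = 2)
  expect_lt(abs(kappa_with_ci(chance$predictors$y,
                              chance$rater_b$y)$kappa), 0.03)
  mid <- generate_rater_pair(ch, c(x = 0.4), seed = 3)
  cells <- agreement_cells(mid$predictors$x, mid$rater_b$x)
  ok <- oracle_kappa(cells[["n11"]], cells[["n10"]], cells[["n01"]],
                     cells[["n00"]])
  expect_equal(ok$kappa, 0.4, tolerance = 0.03)
  expect_equal(kappa_with_ci(mid$predictors$x, mid$rater_b$x)$kappa,
               ok$kappa, tolerance = 1e-12)
  # ordinal variables cannot carry a kappa target
  ord <- cohort(data.frame(g = c(3L, 15L, 14L)), c(0, 1, 0))
  expect_error(generate_rater_pair(ord, c(g = 0.5)), "binary")
})

test_that("shift_site overrides marginals and scales risks without touching the input", {
  cfg <- pecarn_sim_config(n = 2000, seed = 1)
  shifted <- shift_site(cfg, prevalence = list(mvc = 0.463))
  expect_equal(shifted$predictors$mvc$prevalence, 0.463)
  expect_equal(cfg$predictors$mvc$prevalence, 0.318) # original untouched
  expect_equal(shift_site(cfg), cfg)                 # empty override = identity
  expect_error(shift_site(cfg, prevalence = list(mvc = 1.2)), "\\[0, 1\\]")
  expect_error(shift_site(cfg, prevalence = list(nope = 0.2)), "unknown")
})

test_that("risk scaling moves the implied prevalence from 1.7% to 2.8%", {
  cfg <- pecarn_sim_config(n = 2188, seed = 6)
  sc <- risk_scale_for_prevalence(cfg, 0.028)
  ext <- shift_site(cfg, risk_scale = sc)
  expect_equal(implied_prevalence(ext), 0.028, tolerance = 1e-9)
  ch <- generate_cohort(ext)
  se <- sqrt(0.028 * 0.972 / 2188)
  expect_lt(abs(mean(ch$outcome) - 0.028), 3 * se)
})

test_that("exact implied prevalence agrees with Monte Carlo", {
  cfg <- tiny_config(n = 100, seed = 2)
  exact <- implied_prevalence(cfg)
  mc <- implied_prevalence(cfg, method = "mc", n_mc = 2e5, seed = 8)
  expect_lt(abs(exact - mc), 3 * sqrt(exact * (1 - exact) / 2e5))
})

test_that("empirical risks decrease strictly across the true-rule strata", {
  cfg <- pecarn_sim_config(n = 200000, seed = 1)
  ch <- generate_cohort(cfg)
  complete <- impute_median(ch)
  fm <- predict(pecarn_cdi(), complete, type = "match")
  rates <- vapply(1:7, function(k) mean(ch$outcome[fm == k]), numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("cohort CSV and generator YAML round-trip", {
  cfg <- tiny_config(n = 50, seed = 3)
  ch <- generate_rater_pair(generate_cohort(cfg), c(a = 0.7), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ch, path, seed = cfg$seed)
  back <- read_cohort_csv(path)
  expect_equal(back$predictors, ch$predictors)
  expect_identical(back$outcome, ch$outcome)
  expect_identical(back$site, ch$site)
  expect_equal(back$rater_b$a, ch$rater_b$a)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_generator_yaml(pecarn_sim_config(n = 100, seed = 5), ypath)
  cfg2 <- read_generator_yaml(ypath)
  expect_equal(cfg2, pecarn_sim_config(n = 100, seed = 5))
})
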