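test_that("variable matching is explicit and guards critical predictors", {
  src <- c("a", "b", "gcs")
  tgt <- c("a", "b", "gcs")
  vm <- match_variables(src, tgt, stats::setNames(tgt, src), critical = src)
  expect_true(all(vm$kind == "direct"))
  expect_error(
    match_variables(src, c("a", "b"), c(a = "a", b = "b"),
                    critical = c("a", "gcs")),
    "gcs")
  vm2 <- match_variables(c("a", "extra"), c("a", "only_ext"), c(a = "a"))
  expect_equal(vm2$kind[vm2$source == "extra" & !is.na(vm2$source)],
               "unmatched_source_only")
  expect_equal(vm2$kind[!is.na(vm2$target) & vm2$target == "only_ext"],
               "unmatched_target_only")
})

test_that("a renamed and transformed column round-trips predictions", {
  ch <- impute_median(generate_cohort(pecarn_sim_config(n = 1500, seed = 12)))
  cdi <- pecarn_cdi()
  internal_pred <- predict(cdi, ch)
  # external site stores the same content under a renamed, recoded GCS
  ext <- ch
  names(ext$predictors)[names(ext$predictors) == "gcs"] <- "gcs_total"
  ext$predictors$gcs_total <- ext$predictors$gcs_total - 3L # shifted coding
  spec <- stats::setNames(names(ch$predictors), names(ch$predictors))
  spec["gcs"] <- "gcs_total"
  vm <- match_variables(names(ch$predictors), names(ext$predictors), spec,
                        critical = model_variables(cdi),
                        transforms = list(gcs = function(x) x + 3L),
                        transform_notes = list(gcs = "recode to 3..15"))
  mapped <- apply_variable_map(vm, ext)
  expect_equal(predict(cdi, mapped), internal_pred)
})

test_that("external validation of frozen models reproduces internal reports", {
  ch <- impute_median(generate_cohort(pecarn_sim_config(n = 2500, seed = 14)))
  models <- list(reference = pecarn_cdi(), rules = cart_rule_list(ch))
  thr <- c(reference = 0.0025, rules = 0.01)
  internal <- external_validate(models, ch, thresholds = thr)
  again <- external_validate(models, ch, thresholds = thr)
  expect_equal(internal, again)
  direct <- diagnostic_report(ch$outcome, predict(models$reference, ch),
                              thr[["reference"]])
  expect_equal(internal$reference, direct)
  empty <- ch[integer(0)]
  expect_error(external_validate(models, empty, thresholds = thr), "empty")
})

test_that("prediction-tree reports conserve patients and outcomes", {
  cdi <- pecarn_cdi()
  allneg <- reference_schema_cohort(n = 30)
  rep0 <- prediction_tree_report(cdi, allneg)
  expect_equal(rep0$residual$n, 30)
  expect_true(all(rep0$nodes$n == 0))
  for (s in 1:10) {
    ch <- reference_schema_cohort(n = 200)
    set.seed(500 + s)
    for (nm in names(ch$predictors))
      ch$predictors[[nm]] <- if (nm == "gcs")
        sample(3:15, 200, replace = TRUE) else rbinom(200, 1, 0.2)
    ch$outcome <- rbinom(200, 1, 0.3)
    rp <- prediction_tree_report(cdi, ch)
    expect_equal(sum(rp$nodes$n) + rp$residual$n, 200)
    expect_equal(sum(rp$nodes$outcomes) + rp$residual$outcomes,
                 sum(ch$outcome))
    expect_equal(utils::tail(rp$cumulative_capture, 1) +
                   rp$residual$outcomes, rp$total_outcomes)
  }
})

test_that("rank agreement computes Kendall tau by pairwise concordance", {
  ids <- paste0("m", 1:5)
  same <- rank_agreement(ids, ids)
  expect_equal(same$kendall_tau, 1.0)
  expect_true(same$exact_match)
  rev4 <- rank_agreement(paste0("m", 1:4), paste0("m", 4:1))
  expect_equal(rev4$kendall_tau, -1.0)
  set.seed(23)
  for (i in 1:10) {
    a <- sample(paste0("m", 1:6))
    b <- sample(paste0("m", 1:6))
    got <- rank_agreement(a, b)$kendall_tau
    want <- stats::cor(match(paste0("m", 1:6), a),
                       match(paste0("m", 1:6), b), method = "kendall")
    expect_equal(got, want)
  }
  expect_error(rank_agreement(c("a", "b"), c("a", "c")), "same model set")
})

test_that("marginal comparison reflects the built-in covariate shift", {
  expect_true(all(compare_marginals(
    reference_schema_cohort(5), reference_schema_cohort(5))$abs_diff == 0))
  a <- generate_cohort(pecarn_sim_config(n = 12044, seed = 31))
  b <- generate_cohort(pedsrc_sim_config(n = 2188, seed = 32))
  tab <- compare_marginals(a, b)
  # 3-SE Monte-Carlo bands around the configured shifts
  expect_lt(abs(tab$abs_diff[tab$variable == "mvc"] - (0.463 - 0.318)), 0.04)
  expect_lt(abs(tab$abs_diff[tab$variable == "outcome"] - 0.011), 0.012)
  expect_false("sex_male" %in% tab$variable)
})

test_that("the pipeline runs end-to-end and freezes models against the external site", {
  cfg <- pipeline_config(
    internal = pecarn_sim_config(n = 3000, seed = 41),
    external = pedsrc_sim_config(n = 1000, seed = 42),
    seed = 9, n_perm = 5, n_refit_seeds = 2,
    ensemble = list(n_trees = 5, tree_depth = 2, max_rules = 5,
                    min_leaf = 10, class_weight = 5))
  b <- run_pipeline(cfg)
  expect_s3_class(b, "pcs_vetting")
  expect_true(length(b$surviving) >= 2)
  expect_true(all(vapply(b$dev_reports, function(r)
    is.finite(r$weighted_score), logical(1))))
  expect_equal(sort(b$ranking$model), sort(b$surviving))
  expect_true(abs(b$concordance$kendall_tau) <= 1)
  # no information flows from the external cohort into fitting: changing
  # the external site leaves every fitted model identical
  cfg2 <- cfg
  cfg2$external <- pedsrc_sim_config(n = 1000, seed = 99)
  b2 <- run_pipeline(cfg2)
  expect_equal(b$models, b2$models)
  expect_equal(b$thresholds, b2$thresholds)
})

test_that("an overfit deep tree ranks below a stable rule list internally and externally", {
  cfg <- pipeline_config(
    internal = pecarn_sim_config(n = 2500, seed = 61),
    external = pedsrc_sim_config(n = 1200, seed = 62),
    seed = 13, n_perm = 3, n_refit_seeds = 2, reference = NULL,
    tree = list(max_depth = 6, min_leaf = 1, class_weight = 5), # overfits
    rules = list(max_rules = 7, min_leaf = 20, class_weight = 5),
    ensemble = list(n_trees = 3, tree_depth = 1, max_rules = 3,
                    min_leaf = 20, class_weight = 5))
  b <- run_pipeline(cfg)
  rank_int <- b$ranking$model
  if (all(c("cart_rule_list", "cart_tree") %in% rank_int)) {
    expect_lt(match("cart_rule_list", rank_int), match("cart_tree", rank_int))
    expect_lt(match("cart_rule_list", b$external_rank),
              match("cart_tree", b$external_rank))
  }
})
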