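#' Explicit variable matching between development and external schemas
#'
#' Validates a hand-written mapping from development-cohort variable
#' names to external-cohort column names; nothing is ever matched by
#' name similarity. Any model-critical variable left unmatched is a hard
#' error naming the variable; other unmatched variables (present on one
#' side only) are recorded with their disposition.
#'
#' @param source_schema character vector of development variable names.
#' @param target_schema character vector of external column names.
#' @param map_spec named character vector, `source name -> target name`.
#' @param critical variables a frozen model references; must all resolve.
#' @param transforms optional named list of functions (by source name)
#'   applied to the target column to recover the development coding,
#'   with a one-line description in `names(transform_notes)`.
#' @param transform_notes optional named character descriptions.
#' @return data.frame of class `variable_map` with columns `source`,
#'   `target`, `kind` (`direct`, `mapped`, `unmatched_source_only`,
#'   `unmatched_target_only`) and `transform`.
#' @export
match_variables <- function(source_schema, target_schema, map_spec,
                            critical = character(0), transforms = NULL,
                            transform_notes = NULL) {
  stopifnot(is.character(map_spec), !is.null(names(map_spec)))
  bad_src <- setdiff(names(map_spec), source_schema)
  if (length(bad_src))
    stopf("map_spec names unknown source variable(s): %s",
          paste(bad_src, collapse = ", "))
  bad_tgt <- setdiff(unname(map_spec), target_schema)
  if (length(bad_tgt))
    stopf("map_spec targets missing external column(s): %s",
          paste(bad_tgt, collapse = ", "))
  if (anyDuplicated(unname(map_spec)))
    stopf("two source variables map to the same external column")
  unmapped_critical <- setdiff(critical, names(map_spec))
  if (length(unmapped_critical))
    stopf("model-critical variable(s) unmatched: %s",
          paste(unmapped_critical, collapse = ", "))
  has_tr <- function(s) !is.null(transforms[[s]])
  rows <- data.frame(
    source = names(map_spec), target = unname(map_spec),
    kind = ifelse(names(map_spec) == unname(map_spec) &
                    !vapply(names(map_spec), has_tr, logical(1)),
                  "direct", "mapped"),
    transform = vapply(names(map_spec), function(s)
      if (!is.null(transform_notes[[s]])) transform_notes[[s]]
      else if (has_tr(s)) "custom transform" else "", character(1)))
  so <- setdiff(source_schema, names(map_spec))
  to <- setdiff(target_schema, unname(map_spec))
  rows <- rbind(rows,
                if (length(so)) data.frame(source = so, target = NA,
                                           kind = "unmatched_source_only",
                                           transform = ""),
                if (length(to)) data.frame(source = NA, target = to,
                                           kind = "unmatched_target_only",
                                           transform = ""))
  row.names(rows) <- NULL
  structure(rows, class = c("variable_map", "data.frame"),
            transforms = transforms)
}

#' Recode an external cohort into the development schema
#'
#' Builds a cohort whose predictor columns carry the development names
#' (and transforms, where declared), so frozen models can be applied
#' unchanged.
#'
#' @param map a [match_variables()] result.
#' @param external external [cohort()].
#' @return A [cohort()] in the development schema.
#' @export
apply_variable_map <- function(map, external) {
  tr <- attr(map, "transforms")
  mapped <- map[map$kind %in% c("direct", "mapped"), , drop = FALSE]
  cols <- lapply(seq_len(nrow(mapped)), function(i) {
    x <- external$predictors[[mapped$target[i]]]
    f <- tr[[mapped$source[i]]]
    if (!is.null(f)) f(x) else x
  })
  names(cols) <- mapped$source
  cohort(as.data.frame(cols), external$outcome, site = external$site)
}

#' Externally validate frozen instruments
#'
#' Applies models fitted (and thresholds selected) on the development
#' site to an external cohort, after explicit schema mapping. Nothing is
#' refit: models and thresholds enter frozen.
#'
#' @param models named list of fitted models.
#' @param external external [cohort()] (imputed; no missing values among
#'   mapped predictors).
#' @param map optional [match_variables()] result; omit when the schemas
#'   are identical.
#' @param thresholds named vector of frozen operating thresholds.
#' @param w sensitivity weight.
#' @return named list of [diagnostic_report()]s.
#' @export
external_validate <- function(models, external, map = NULL, thresholds,
                              w = 5) {
  if (n_patients(external) == 0) stopf("external cohort is empty")
  stopifnot(all(names(models) %in% names(thresholds)))
  eval_cohort <- if (is.null(map)) external else
    apply_variable_map(map, external)
  stats::setNames(lapply(names(models), function(id) {
    risks <- predict(models[[id]], eval_cohort)
    diagnostic_report(eval_cohort$outcome, risks, thresholds[[id]], w = w)
  }), names(models))
}

#' Prediction-tree report for an ordered rule list
#'
#' First-match patient counts, captured outcomes and empirical node risk
#' per condition, the residual very-low-risk node, and the cumulative
#' outcome-capture curve over the first k conditions. Node counts
#' partition the cohort; captured plus missed outcomes equal the outcome
#' total. Non-monotone empirical node risks are flagged.
#'
#' @param rule_list a `cdi_rule_list`.
#' @param cohort evaluation [cohort()].
#' @return An object of class `prediction_tree_report` with `nodes`
#'   (data.frame), `residual`, `cumulative_capture` and `monotone`.
#' @export
prediction_tree_report <- function(rule_list, cohort) {
  fm <- predict(rule_list, cohort, type = "match")
  y <- cohort$outcome
  k <- length(rule_list$conditions)
  n_k <- tabulate(fm[fm > 0], nbins = k)
  pos_k <- vapply(seq_len(k), function(j) sum(y[fm == j]), integer(1))
  nodes <- data.frame(
    step = seq_len(k),
    condition = vapply(rule_list$conditions, function(cc)
      paste(cc$predictor, cc$op, cc$threshold), character(1)),
    n = n_k, outcomes = pos_k,
    risk = ifelse(n_k > 0, pos_k / n_k, NA_real_))
  residual <- list(n = sum(fm == 0), outcomes = sum(y[fm == 0]))
  obs <- nodes$risk[!is.na(nodes$risk)]
  structure(list(nodes = nodes, residual = residual,
                 cumulative_capture = cumsum(pos_k),
                 total_outcomes = sum(y),
                 monotone = all(diff(obs) < 0) || length(obs) < 2),
            class = "prediction_tree_report")
}

#' @export
print.prediction_tree_report <- function(x, ...) {
  cat("Prediction tree report\n")
  for (i in seq_len(nrow(x$nodes)))
    cat(sprintf("  %d. %-32s n=%5d  outcomes=%3d  risk=%s\n",
                x$nodes$step[i], x$nodes$condition[i], x$nodes$n[i],
                x$nodes$outcomes[i],
                ifelse(is.na(x$nodes$risk[i]), "-", pct1(x$nodes$risk[i]))))
  cat(sprintf("  very low risk: n=%d, outcomes missed=%d\n",
              x$residual$n, x$residual$outcomes))
  if (!x$monotone) cat("  warning: node risks are not monotone decreasing\n")
  invisible(x)
}

#' Rank concordance between internal and external orderings
#'
#' Kendall's tau by direct pairwise concordance count over two orderings
#' of the same model set, plus an exact-match flag.
#'
#' @param internal,external character vectors ordering the same model
#'   identifiers (best first).
#' @return list of class `rank_concordance` with `kendall_tau` and
#'   `exact_match`.
#' @export
rank_agreement <- function(internal, external) {
  if (!setequal(internal, external) ||
      length(internal) != length(external))
    stopf("orderings must cover the same model set")
  n <- length(internal)
  pos_ext <- match(internal, external)
  conc <- 0L; disc <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (pos_ext[j] > pos_ext[i]) conc <- conc + 1L else disc <- disc + 1L
  }
  structure(list(internal = internal, external = external,
                 kendall_tau = (conc - disc) / (n * (n - 1) / 2),
                 exact_match = identical(internal, external)),
            class = "rank_concordance")
}

#' @export
print.rank_concordance <- function(x, ...) {
  cat(sprintf("Rank concordance: tau = %.3f (%s)\n", x$kendall_tau,
              if (x$exact_match) "exact match" else "orderings differ"))
  cat("  internal:", paste(x$internal, collapse = " > "), "\n")
  cat("  external:", paste(x$external, collapse = " > "), "\n")
  invisible(x)
}

#' Tabular marginal comparison of two cohorts
#'
#' Per shared variable: prevalence (binary) or mean (ordinal) in each
#' cohort and the absolute difference, plus the outcome prevalence row —
#' a tabular stand-in for side-by-side distribution plots.
#'
#' @param cohort_a,cohort_b [cohort()]s with mapped (shared) schemas.
#' @return data.frame with columns `variable`, `kind`, `a`, `b`,
#'   `abs_diff`.
#' @export
compare_marginals <- function(cohort_a, cohort_b) {
  shared <- intersect(names(cohort_a$predictors), names(cohort_b$predictors))
  stat <- function(ch, nm) mean(ch$predictors[[nm]], na.rm = TRUE)
  df <- data.frame(
    variable = c(shared, "outcome"),
    kind = c(unname(cohort_a$kinds[shared]), "binary"),
    a = c(vapply(shared, stat, numeric(1), ch = cohort_a),
          mean(cohort_a$outcome)),
    b = c(vapply(shared, stat, numeric(1), ch = cohort_b),
          mean(cohort_b$outcome)))
  df$abs_diff <- abs(df$a - df$b)
  row.names(df) <- NULL
  df
}

# ---- end-to-end pipeline --------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Bundles the generator configurations (or cohort CSV paths), model
#' hyperparameters, screening thresholds, the explicit variable map and
#' the master seed for one end-to-end vetting run.
#'
#' @param internal,external [generator_config()]s, or paths to cohort
#'   CSVs written by [write_cohort_csv()].
#' @param seed master seed for split, ensemble bootstrap and permutation
#'   streams.
#' @param map_spec explicit source-to-target variable map (named
#'   character); `NULL` means the schemas are declared identical.
#' @param w sensitivity weight; `sens_floor_dev` governs operating-point
#'   selection and `screen_min_sens` the elimination screen;
#'   `sens_floor_external` is the external comparison bound.
#' @param dev_frac,max_missing,min_kappa_ci,phi_threshold preprocessing
#'   parameters.
#' @param tree,rules,ensemble per-model hyperparameter lists.
#' @param reference arguments for [pecarn_cdi()] (or `NULL` to skip the
#'   reference instrument).
#' @param n_perm permutation-importance shuffles; `n_refit_seeds` refit
#'   replicates.
#' @param exclude_from_fitting development variables withheld from model
#'   development because the external site cannot supply them (the
#'   default withholds the sex column, which the default external
#'   configuration lacks); they still appear in screening reports and
#'   marginal comparisons.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(internal = pecarn_sim_config(),
                            external = pedsrc_sim_config(),
                            seed = 1L, map_spec = NULL,
                            w = 5, sens_floor_dev = 0.90,
                            sens_floor_external = 0.95,
                            screen_min_sens = 0.90,
                            dev_frac = 0.663, max_missing = 0.05,
                            min_kappa_ci = 0.4, phi_threshold = 0.95,
                            tree = list(max_depth = 3, min_leaf = 10,
                                        class_weight = 5),
                            rules = list(max_rules = 10, min_leaf = 10,
                                         class_weight = 5),
                            ensemble = list(n_trees = 20, tree_depth = 2,
                                            max_rules = 10, min_leaf = 10,
                                            class_weight = 5),
                            reference = list(),
                            n_perm = 50, n_refit_seeds = 5,
                            exclude_from_fitting = "sex_male") {
  structure(as.list(environment()), class = "pipeline_config")
}

drop_predictors <- function(cohort, nms) {
  keep <- setdiff(names(cohort$predictors), nms)
  cohort$predictors <- cohort$predictors[keep]
  cohort$kinds <- cohort$kinds[keep]
  if (!is.null(cohort$rater_b))
    cohort$rater_b <- cohort$rater_b[intersect(names(cohort$rater_b), keep)]
  cohort
}

# replay the development-site merge recipe on another cohort (same
# missing-data and redundancy strategy on both sites)
apply_merges <- function(cohort, merges) {
  for (i in seq_len(nrow(merges))) {
    parts <- strsplit(merges$constituents[i], ",", fixed = TRUE)[[1]]
    if (!all(parts %in% names(cohort$predictors))) next
    cohort$predictors[[merges$name[i]]] <-
      as.integer(Reduce(`|`, cohort$predictors[parts]))
    keep <- setdiff(names(cohort$predictors), parts)
    cohort$predictors <- cohort$predictors[keep]
    cohort$kinds <- c(cohort$kinds[setdiff(keep, merges$name[i])],
                      stats::setNames("binary", merges$name[i]))[keep]
  }
  cohort
}

load_cohort_input <- function(x) {
  if (inherits(x, "generator_config")) generate_cohort(x)
  else if (is.character(x)) read_cohort_csv(x)
  else if (inherits(x, "cohort")) x
  else stopf("cohort input must be a generator_config, cohort or CSV path")
}

#' Run the full vetting pipeline
#'
#' Executes the stages in fixed order: preprocess the development-site
#' cohort (screens, imputation, merging, stratified split); fit the
#' instrument grid on the development fold; compute development and
#' internal-validation reports and curves at operating points selected
#' on the development fold (frozen reference rule lists instead keep
#' their defining operating point: positive iff any condition fires);
#' eliminate instruments below the sensitivity
#' screen; measure variable-level stability (frequency, permutation
#' importance on the validation fold) and model-level stability (refit
#' randomness, performance drop); rank; then freeze everything, map the
#' external schema, validate externally and compare rankings. Wall time
#' per stage is logged (reported, never asserted). With an output
#' directory the artifact bundle (JSON, CSV, markdown) is written;
#' artifacts are byte-identical under a fixed master seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @return list of class `pcs_vetting`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list(); clock <- function() proc.time()[["elapsed"]]
  tick <- function(stage, t0) timings[[stage]] <<- round(clock() - t0, 3)

  t0 <- clock()
  internal <- load_cohort_input(config$internal)
  external <- load_cohort_input(config$external)
  tick("load", t0)

  t0 <- clock()
  prep <- preprocess(internal, max_missing = config$max_missing,
                     min_kappa_ci = config$min_kappa_ci,
                     phi_threshold = config$phi_threshold,
                     dev_frac = config$dev_frac,
                     seed = substream_seed(config$seed, "split"))
  dev <- drop_predictors(prep$split$development, config$exclude_from_fitting)
  val <- drop_predictors(prep$split$validation, config$exclude_from_fitting)
  tick("preprocess", t0)

  t0 <- clock()
  models <- list()
  if (!is.null(config$reference))
    models$reference <- do.call(pecarn_cdi, config$reference)
  models$cart_tree <- do.call(cart_tree, c(list(dev), config$tree))
  models$cart_rule_list <- do.call(cart_rule_list, c(list(dev), config$rules))
  models$rule_ensemble <- do.call(
    rule_ensemble, c(list(dev), config$ensemble,
                     list(seed = substream_seed(config$seed, "ensemble"),
                          w = config$w, sens_floor = config$sens_floor_dev)))
  tick("fit", t0)

  t0 <- clock()
  dev_risks <- lapply(models, predict, newdata = dev)
  dev_curves <- lapply(dev_risks, sens_spec_curve, outcome = dev$outcome)
  ops <- lapply(dev_curves, select_operating_point, w = config$w,
                sens_floor = config$sens_floor_dev)
  thresholds <- vapply(ops, `[[`, numeric(1), "threshold")
  # a reference rule list carries its defining operating point — a
  # patient is very low risk exactly when no condition fires — rather
  # than a curve-optimized threshold
  for (id in names(models)) {
    m <- models[[id]]
    if (inherits(m, "cdi_rule_list") && m$provenance == "reference")
      thresholds[[id]] <- min(m$leaf_risks)
  }
  dev_reports <- stats::setNames(lapply(names(models), function(id)
    diagnostic_report(dev$outcome, dev_risks[[id]], thresholds[[id]],
                      w = config$w)), names(models))
  val_reports <- stats::setNames(lapply(names(models), function(id)
    diagnostic_report(val$outcome, predict(models[[id]], val),
                      thresholds[[id]], w = config$w)), names(models))
  tick("internal_reports", t0)

  t0 <- clock()
  surviving <- screen_cdis(dev_reports, config$screen_min_sens)
  models_s <- models[surviving]
  tick("screen", t0)

  t0 <- clock()
  stab_tab <- stability_table(models_s, val, thresholds,
                              n_perm = config$n_perm,
                              seed = substream_seed(config$seed, "perm"),
                              w = config$w)
  fitters <- list(
    cart_tree = function(ch, s) do.call(cart_tree, c(list(ch), config$tree)),
    cart_rule_list = function(ch, s)
      do.call(cart_rule_list, c(list(ch), config$rules)),
    rule_ensemble = function(ch, s)
      do.call(rule_ensemble, c(list(ch), config$ensemble,
                               list(seed = s, w = config$w,
                                    sens_floor = config$sens_floor_dev))))
  refits <- lapply(fitters[intersect(names(fitters), surviving)],
                   refit_randomness, cohort = dev,
                   n_seeds = config$n_refit_seeds, w = config$w,
                   sens_floor = config$sens_floor_dev)
  stability <- stats::setNames(lapply(surviving, function(id)
    performance_drop(dev_reports[[id]], val_reports[[id]],
                     refit_spread = if (!is.null(refits[[id]]))
                       refits[[id]]$score_spread else 0)), surviving)
  ranking <- rank_cdis(dev_reports[surviving], val_reports[surviving],
                       stability)
  tick("stability", t0)

  t0 <- clock()
  external_imp <- apply_merges(impute_median(external), prep$report$merges)
  map <- if (!is.null(config$map_spec)) {
    match_variables(names(prep$cohort$predictors),
                    names(external_imp$predictors), config$map_spec,
                    critical = unique(unlist(lapply(models_s,
                                                    model_variables))))
  } else NULL
  ext_reports <- external_validate(models_s, external_imp, map = map,
                                   thresholds = thresholds, w = config$w)
  ext_scores <- vapply(ext_reports, `[[`, numeric(1), "weighted_score")
  external_rank <- names(ext_scores)[order(-ext_scores, names(ext_scores))]
  concordance <- rank_agreement(ranking$model, external_rank)
  tick("external", t0)

  t0 <- clock()
  tree_reports <- list()
  for (id in intersect(c("reference", "cart_rule_list"), surviving)) {
    tree_reports[[id]] <- list(
      internal_validation = prediction_tree_report(models_s[[id]], val),
      external = prediction_tree_report(
        models_s[[id]],
        if (is.null(map)) external_imp
        else apply_variable_map(map, external_imp)))
  }
  marginals <- compare_marginals(internal, external)
  tick("report", t0)

  bundle <- structure(list(
    config = config, screen_report = prep$report, split = prep$split,
    models = models, thresholds = thresholds, operating_points = ops,
    dev_reports = dev_reports, val_reports = val_reports,
    dev_curves = dev_curves, surviving = surviving,
    stability_table = stab_tab, refits = refits, stability = stability,
    ranking = ranking, variable_map = map, external_reports = ext_reports,
    external_rank = external_rank, concordance = concordance,
    tree_reports = tree_reports, marginals = marginals,
    timings = timings), class = "pcs_vetting")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.pcs_vetting <- function(x, ...) {
  cat("PCS vetting run\n")
  print(x$screen_report)
  cat(sprintf("\nSurviving instruments (dev sensitivity >= %s): %s\n",
              pct1(x$config$screen_min_sens),
              paste(x$surviving, collapse = ", ")))
  cat("\nInternal ranking:\n"); print(x$ranking)
  cat("\nTop stable variables:",
      paste(utils::head(variable_stability_rank(x$stability_table), 3),
            collapse = ", "), "\n")
  print(x$concordance)
  invisible(x)
}

report_to_list <- function(r) {
  list(tp = r$counts$tp, fp = r$counts$fp, tn = r$counts$tn,
       fn = r$counts$fn, sensitivity = r$sensitivity,
       specificity = r$specificity, npv = r$npv, ppv = r$ppv,
       lr_pos = r$lr_pos, lr_neg = r$lr_neg, f1 = r$f1,
       accuracy = r$accuracy, brier = r$brier, threshold = r$threshold,
       weighted_score = r$weighted_score, flags = as.list(r$flags))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  wj <- function(obj, file) jsonlite::write_json(
    obj, file.path(out_dir, file), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  for (id in names(bundle$models))
    write_model_json(bundle$models[[id]],
                     file.path(out_dir, "models", paste0(id, ".json")))
  wj(list(kept = bundle$screen_report$kept,
          dropped_missingness = bundle$screen_report$dropped_missingness,
          dropped_reliability = bundle$screen_report$dropped_reliability,
          unscreened = bundle$screen_report$unscreened,
          merges = bundle$screen_report$merges), "screen_report.json")
  utils::write.csv(
    data.frame(row_id = seq_len(n_patients(bundle$split$development) +
                                  n_patients(bundle$split$validation)),
               fold = ifelse(seq_len(n_patients(bundle$split$development) +
                                       n_patients(bundle$split$validation))
                             %in% bundle$split$dev_idx,
                             "development", "validation")),
    file.path(out_dir, "split.csv"), row.names = FALSE)
  wj(list(thresholds = as.list(bundle$thresholds),
          development = lapply(bundle$dev_reports, report_to_list),
          internal_validation = lapply(bundle$val_reports, report_to_list),
          external = lapply(bundle$external_reports, report_to_list)),
     "reports.json")
  for (part in c("dev", "val")) {
    reports <- if (part == "dev") bundle$dev_reports else bundle$val_reports
    utils::write.csv(format_report_table(reports),
                     file.path(out_dir, paste0("table_", part, ".csv")))
  }
  utils::write.csv(format_report_table(bundle$external_reports),
                   file.path(out_dir, "table_external.csv"))
  for (id in names(bundle$dev_curves))
    utils::write.csv(as.data.frame(bundle$dev_curves[[id]]),
                     file.path(out_dir, paste0("curve_dev_", id, ".csv")),
                     row.names = FALSE)
  utils::write.csv(
    data.frame(variable = names(bundle$stability_table$frequency),
               frequency = unname(bundle$stability_table$frequency),
               bundle$stability_table$importance),
    file.path(out_dir, "stability_table.csv"), row.names = FALSE)
  wj(list(internal = bundle$ranking,
          external = bundle$external_rank,
          kendall_tau = bundle$concordance$kendall_tau,
          exact_match = bundle$concordance$exact_match), "ranking.json")
  utils::write.csv(bundle$marginals, file.path(out_dir, "marginals.csv"),
                   row.names = FALSE)
  md <- c("# Vetting summary", "",
          sprintf("Surviving instruments: %s",
                  paste(bundle$surviving, collapse = ", ")),
          sprintf("Internal ranking: %s",
                  paste(bundle$ranking$model, collapse = " > ")),
          sprintf("External ranking: %s",
                  paste(bundle$external_rank, collapse = " > ")),
          sprintf("Kendall tau: %.3f", bundle$concordance$kendall_tau),
          sprintf("Top stable variables: %s",
                  paste(utils::head(
                    variable_stability_rank(bundle$stability_table), 3),
                    collapse = ", ")))
  writeLines(md, file.path(out_dir, "summary.md"))
  # wall-time log kept out of the deterministic artifact set
  wj(bundle$timings, "timings.json")
  invisible(out_dir)
}
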