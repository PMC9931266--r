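#' Predictor specifications for the cohort simulator
#'
#' `binary_spec()` describes a presence/absence finding drawn as a
#' Bernoulli variable; `ordinal_spec()` describes an integer-valued scale
#' (e.g. the Glasgow Coma Scale over 3..15) drawn from a categorical
#' distribution. A binary predictor may be declared redundant with an
#' earlier one, in which case it is generated conditionally on its parent
#' so the pair attains a target phi correlation, and may carry a target
#' Cohen's kappa used to simulate an imperfect second rater.
#'
#' @param name column name.
#' @param prevalence Bernoulli probability in `[0, 1]`.
#' @param missing_rate completely-at-random missingness fraction in `[0, 1)`.
#' @param rater_kappa optional target Cohen's kappa in `[0, 1]` for the
#'   simulated second rater.
#' @param redundant_with optional name of an earlier binary predictor this
#'   one duplicates.
#' @param phi target phi correlation with the `redundant_with` parent.
#' @param support integer support of an ordinal predictor.
#' @param probs category probabilities over `support` (sums to 1).
#' @return A `predictor_spec` list.
#' @export
binary_spec <- function(name, prevalence, missing_rate = 0,
                        rater_kappa = NULL, redundant_with = NULL,
                        phi = NULL) {
  stopifnot(is_prob(prevalence), length(prevalence) == 1L,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(redundant_with) && is.null(phi))
    stopf("'%s': redundant_with requires a target phi", name)
  if (!is.null(phi) && (phi < -1 || phi > 1))
    stopf("'%s': phi must lie in [-1, 1]", name)
  if (!is.null(rater_kappa) && !is_prob(rater_kappa))
    stopf("'%s': rater_kappa must lie in [0, 1]", name)
  structure(list(name = name, kind = "binary", prevalence = prevalence,
                 missing_rate = missing_rate, rater_kappa = rater_kappa,
                 redundant_with = redundant_with, phi = phi),
            class = "predictor_spec")
}

#' @rdname binary_spec
#' @export
ordinal_spec <- function(name, support, probs, missing_rate = 0) {
  stopifnot(length(support) == length(probs), is_prob(probs),
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(probs) - 1) > 1e-9)
    stopf("'%s': category probabilities must sum to 1", name)
  structure(list(name = name, kind = "ordinal",
                 support = as.integer(support), probs = probs,
                 missing_rate = missing_rate, rater_kappa = NULL,
                 redundant_with = NULL, phi = NULL),
            class = "predictor_spec")
}

#' Ground-truth ordered rule list for outcome generation
#'
#' The simulator assigns each patient the outcome probability of the first
#' matching condition (or `default_risk` when none matches), mirroring the
#' structure of an ordered clinical rule list whose subgroup risks
#' decrease monotonically from top to bottom.
#'
#' @param predictor,op,threshold a single condition: `op` is `"=="` for
#'   binary predictors and `"<"`/`">="` for ordinal ones.
#' @param conditions list of [rule_condition()]s, highest risk first.
#' @param leaf_risks per-condition outcome probabilities, non-increasing
#'   down the list (the shipped configurations use strictly decreasing
#'   risks; ties accommodate degenerate cases such as an all-zero-risk
#'   rule).
#' @param default_risk outcome probability when no condition fires; at
#'   most the last leaf risk.
#' @return A `true_rule` list.
#' @export
rule_condition <- function(predictor, op, threshold) {
  if (!op %in% c("==", "<", ">="))
    stopf("unsupported operator '%s'", op)
  list(predictor = predictor, op = op, threshold = threshold)
}

#' @rdname rule_condition
#' @export
true_rule <- function(conditions, leaf_risks, default_risk) {
  stopifnot(length(conditions) == length(leaf_risks),
            is_prob(leaf_risks), is_prob(default_risk))
  if (length(leaf_risks) > 1 && any(diff(leaf_risks) > 0))
    stopf("leaf risks must be non-increasing down the rule list")
  if (default_risk > leaf_risks[length(leaf_risks)])
    stopf("default risk must not exceed the last leaf risk")
  structure(list(conditions = conditions, leaf_risks = leaf_risks,
                 default_risk = default_risk), class = "true_rule")
}

#' Full simulator configuration
#'
#' @param predictors list of [binary_spec()] / [ordinal_spec()] objects.
#' @param rule a [true_rule()] referencing existing predictors.
#' @param n patient count (>= 1).
#' @param seed master integer seed; every column, the outcome, the second
#'   rater and the missingness masks draw from deterministic sub-streams
#'   derived from it, so results do not depend on column order.
#' @param site site label.
#' @return A `generator_config` list.
#' @export
generator_config <- function(predictors, rule, n, seed = 1L,
                             site = "internal") {
  stopifnot(is_count(n), n >= 1)
  nms <- vapply(predictors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("duplicate predictor names")
  names(predictors) <- nms
  for (sp in predictors) {
    if (!is.null(sp$redundant_with)) {
      if (!sp$redundant_with %in% nms)
        stopf("'%s' is redundant with unknown predictor '%s'",
              sp$name, sp$redundant_with)
      parent <- predictors[[sp$redundant_with]]
      if (!is.null(parent$redundant_with))
        stopf("redundancy chains are not supported ('%s' -> '%s')",
              sp$name, sp$redundant_with)
    }
  }
  for (cond in rule$conditions) {
    if (!cond$predictor %in% nms)
      stopf("rule references unknown predictor '%s'", cond$predictor)
    kind <- predictors[[cond$predictor]]$kind
    ok <- if (kind == "binary") cond$op == "==" else cond$op %in% c("<", ">=")
    if (!ok) stopf("operator '%s' invalid for %s predictor '%s'",
                   cond$op, kind, cond$predictor)
  }
  cfg <- structure(list(predictors = predictors, rule = rule, n = n,
                        seed = as.integer(seed), site = site),
                   class = "generator_config")
  prev <- implied_prevalence(cfg)
  if (prev <= 0 || prev >= 1)
    warning(sprintf("implied outcome prevalence %.4g is degenerate", prev),
            call. = FALSE)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config '%s': n=%d, %d predictors, %d rule conditions, implied prevalence %s>\n",
              x$site, x$n, length(x$predictors),
              length(x$rule$conditions), pct1(implied_prevalence(x))))
  invisible(x)
}

# first-matching rule condition per row; 0 = no condition fires
first_match <- function(conditions, data) {
  n <- nrow(data)
  idx <- rep.int(0L, n)
  for (j in rev(seq_along(conditions))) {
    cond <- conditions[[j]]
    x <- data[[cond$predictor]]
    fires <- switch(cond$op,
                    "==" = x == cond$threshold,
                    "<"  = x < cond$threshold,
                    ">=" = x >= cond$threshold)
    fires[is.na(fires)] <- FALSE
    idx[fires] <- j
  }
  idx
}

#' Analytic implied outcome prevalence of a configuration
#'
#' Computes the expectation of the true-rule risk over the joint law of the
#' predictors the rule references. Those predictors are mutually
#' independent by construction (redundant pairs are supported only among
#' columns the rule does not reference), so the expectation is an exact
#' finite sum over the product of their marginals; `method = "mc"` checks
#' it by Monte Carlo instead.
#'
#' @param config a [generator_config()].
#' @param method `"exact"` (enumeration) or `"mc"`.
#' @param n_mc Monte-Carlo draws when `method = "mc"`.
#' @param seed Monte-Carlo seed.
#' @return implied prevalence as a fraction.
#' @export
implied_prevalence <- function(config, method = c("exact", "mc"),
                               n_mc = 1e6, seed = 1L) {
  method <- match.arg(method)
  rule <- config$rule
  vars <- unique(vapply(rule$conditions, `[[`, character(1), "predictor"))
  specs <- config$predictors[vars]
  for (sp in specs) {
    if (!is.null(sp$redundant_with) && sp$redundant_with %in% vars)
      stopf("exact implied prevalence needs rule predictors independent; use method='mc'")
  }
  if (method == "exact") {
    supports <- lapply(specs, function(sp)
      if (sp$kind == "binary") c(0L, 1L) else sp$support)
    probs <- lapply(specs, function(sp)
      if (sp$kind == "binary") c(1 - sp$prevalence, sp$prevalence) else sp$probs)
    grid <- expand.grid(supports, KEEP.OUT.ATTRS = FALSE)
    names(grid) <- vars
    w <- rep(1, nrow(grid))
    for (j in seq_along(vars))
      w <- w * probs[[j]][match(grid[[j]], supports[[j]])]
    risks <- c(rule$default_risk, rule$leaf_risks)[first_match(rule$conditions, grid) + 1L]
    sum(w * risks)
  } else {
    draws <- with_seed(seed, {
      as.data.frame(lapply(specs, function(sp) {
        if (sp$kind == "binary") stats::rbinom(n_mc, 1L, sp$prevalence)
        else sample(sp$support, n_mc, replace = TRUE, prob = sp$probs)
      }))
    })
    names(draws) <- vars
    risks <- c(rule$default_risk, rule$leaf_risks)[first_match(rule$conditions, draws) + 1L]
    mean(risks)
  }
}

# conditional P(child = 1 | parent) pair attaining a target phi:
# P11 = pq + phi * sqrt(p(1-p)q(1-q)), then condition on the parent.
redundant_child_probs <- function(p_parent, q_child, phi) {
  p11 <- q_child * p_parent +
    phi * sqrt(p_parent * (1 - p_parent) * q_child * (1 - q_child))
  c1 <- if (p_parent > 0) p11 / p_parent else 0
  c0 <- if (p_parent < 1) (q_child - p11) / (1 - p_parent) else 0
  if (c1 < -1e-12 || c1 > 1 + 1e-12 || c0 < -1e-12 || c0 > 1 + 1e-12)
    stopf("phi target %.3f infeasible for prevalences %.3f / %.3f",
          phi, p_parent, q_child)
  c(p_given_0 = min(max(c0, 0), 1), p_given_1 = min(max(c1, 0), 1))
}

#' Generate a synthetic cohort
#'
#' Draws every predictor from its marginal specification (redundant
#' children conditionally on their parent), assigns each patient a
#' Bernoulli outcome at the risk of the first matching true-rule
#' condition, simulates the second rater for predictors carrying a kappa
#' target, and finally injects completely-at-random missingness per
#' column. Identical configurations (including the seed) yield
#' bitwise-identical cohorts.
#'
#' @param config a [generator_config()].
#' @return A [cohort()].
#' @export
generate_cohort <- function(config) {
  n <- config$n
  specs <- config$predictors
  complete <- as.data.frame(matrix(NA_integer_, n, 0))
  # independent columns first, redundant children after their parents
  ord <- order(vapply(specs, function(sp) !is.null(sp$redundant_with), logical(1)))
  for (sp in specs[ord]) {
    s <- substream_seed(config$seed, "col", sp$name)
    complete[[sp$name]] <- with_seed(s, {
      if (sp$kind == "ordinal") {
        sample(sp$support, n, replace = TRUE, prob = sp$probs)
      } else if (is.null(sp$redundant_with)) {
        stats::rbinom(n, 1L, sp$prevalence)
      } else {
        parent <- complete[[sp$redundant_with]]
        pp <- specs[[sp$redundant_with]]$prevalence
        cp <- redundant_child_probs(pp, sp$prevalence, sp$phi)
        stats::rbinom(n, 1L, ifelse(parent == 1L, cp["p_given_1"], cp["p_given_0"]))
      }
    })
  }
  complete <- complete[names(specs)]
  fm <- first_match(config$rule$conditions, complete)
  risks <- c(config$rule$default_risk, config$rule$leaf_risks)[fm + 1L]
  outcome <- with_seed(substream_seed(config$seed, "outcome"),
                       stats::rbinom(n, 1L, risks))
  kinds <- vapply(specs, `[[`, character(1), "kind")
  ch <- cohort(complete, outcome, kinds = kinds, site = config$site)
  kap <- Filter(function(sp) !is.null(sp$rater_kappa), specs)
  if (length(kap)) {
    targets <- vapply(kap, `[[`, numeric(1), "rater_kappa")
    ch <- generate_rater_pair(ch, targets,
                              seed = substream_seed(config$seed, "rater"))
  }
  for (sp in specs) {
    if (sp$missing_rate > 0) {
      drop <- with_seed(substream_seed(config$seed, "miss", sp$name),
                        stats::runif(n) < sp$missing_rate)
      ch$predictors[[sp$name]][drop] <- NA
    }
  }
  ch
}

# symmetric flip probability that attains a target kappa at prevalence p;
# at a degenerate prevalence kappa is undefined and the duplicate rating
# simply copies the first rater
flip_prob_for_kappa <- function(kappa, p) {
  if (kappa >= 1 || p <= 0 || p >= 1) return(0)
  f <- function(e) {
    pb <- p + e * (1 - 2 * p)
    pe <- p * pb + (1 - p) * (1 - pb)
    (1 - e - pe) / (1 - pe) - kappa
  }
  if (kappa <= 0) return(0.5)
  stats::uniroot(f, c(0, 0.5), tol = 1e-12)$root
}

#' Simulate a second rater at target Cohen's kappa
#'
#' The duplicate rating equals the first rating except for symmetric
#' random flips, with the flip probability solved so the pair attains the
#' requested kappa given the variable's realized prevalence.
#'
#' @param cohort a [cohort()].
#' @param kappa_targets named vector of kappa targets in `[0, 1]` for
#'   binary predictors.
#' @param seed integer seed.
#' @return The cohort with its `rater_b` table filled.
#' @export
generate_rater_pair <- function(cohort, kappa_targets, seed = 1L) {
  stopifnot(is_prob(unlist(kappa_targets)))
  rb <- if (is.null(cohort$rater_b)) list() else as.list(cohort$rater_b)
  for (nm in names(kappa_targets)) {
    if (!nm %in% names(cohort$predictors))
      stopf("unknown predictor '%s'", nm)
    if (cohort$kinds[[nm]] != "binary")
      stopf("kappa simulation supports binary variables only ('%s' is %s)",
            nm, cohort$kinds[[nm]])
    a <- cohort$predictors[[nm]]
    p <- mean(a, na.rm = TRUE)
    e <- flip_prob_for_kappa(kappa_targets[[nm]], p)
    flip <- with_seed(substream_seed(seed, "flip", nm),
                      stats::runif(length(a)) < e)
    rb[[nm]] <- ifelse(flip, 1L - a, a)
  }
  cohort$rater_b <- as.data.frame(rb)
  cohort
}

#' Derive a shifted-site configuration
#'
#' Returns a copy of `config` with overridden binary prevalences and/or
#' all rule risks (leaf and default) scaled by a common factor — the
#' covariate- and prevalence-shift mechanism used to emulate an external
#' validation site. The input configuration is not modified.
#'
#' @param config a [generator_config()].
#' @param prevalence named list/vector of new binary prevalences.
#' @param risk_scale positive scalar applied to every rule risk.
#' @param n,seed,site optional replacements.
#' @return A new [generator_config()].
#' @export
shift_site <- function(config, prevalence = NULL, risk_scale = NULL,
                       n = NULL, seed = NULL, site = NULL) {
  preds <- config$predictors
  for (nm in names(prevalence)) {
    if (!nm %in% names(preds)) stopf("unknown predictor '%s'", nm)
    if (preds[[nm]]$kind != "binary")
      stopf("prevalence override targets binary predictors ('%s')", nm)
    pv <- prevalence[[nm]]
    if (!is_prob(pv)) stopf("prevalence override for '%s' outside [0, 1]", nm)
    preds[[nm]]$prevalence <- pv
  }
  rule <- config$rule
  if (!is.null(risk_scale)) {
    stopifnot(risk_scale > 0)
    lr <- rule$leaf_risks * risk_scale
    dr <- rule$default_risk * risk_scale
    if (any(lr > 1) || dr > 1) stopf("risk_scale pushes a risk above 1")
    rule <- true_rule(rule$conditions, lr, dr)
  }
  generator_config(preds, rule,
                   n = if (is.null(n)) config$n else n,
                   seed = if (is.null(seed)) config$seed else seed,
                   site = if (is.null(site)) config$site else site)
}

#' @rdname shift_site
#' @param target_prevalence implied outcome prevalence the scaled rule
#'   should attain; the scale is exact because the implied prevalence is
#'   linear in the rule risks.
#' @export
risk_scale_for_prevalence <- function(config, target_prevalence) {
  stopifnot(is_prob(target_prevalence))
  target_prevalence / implied_prevalence(config)
}

#' Default synthetic development-site configuration
#'
#' A PECARN-like blunt-torso-trauma cohort: seven rule predictors (three
#' strong — abdominal wall trauma/seat-belt sign, GCS < 14, abdominal
#' tenderness — and four weak), plus mechanism/demographic noise columns,
#' one highly redundant pair, one high-missingness column and one
#' low-reliability column so every preprocessing screen is exercised. The
#' embedded rule implies an outcome prevalence of ~1.7%; the companion
#' [pedsrc_sim_config()] shifts MVC prevalence to 46.3% and scales risks
#' to an implied prevalence of 2.8% at n = 2,188.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param site site label.
#' @return A [generator_config()].
#' @export
pecarn_sim_config <- function(n = 12044, seed = 1L, site = "pecarn") {
  gcs_probs <- c(0.010, 0.003, 0.003, 0.004, 0.004, 0.004, 0.004,
                 0.005, 0.006, 0.008, 0.015, 0.034, 0.900)
  predictors <- list(
    binary_spec("abd_trauma_seatbelt", 0.08, missing_rate = 0.01,
                rater_kappa = 0.85),
    ordinal_spec("gcs", 3:15, gcs_probs, missing_rate = 0.005),
    binary_spec("abd_tenderness", 0.18, missing_rate = 0.02,
                rater_kappa = 0.80),
    binary_spec("vomiting", 0.13, missing_rate = 0.01, rater_kappa = 0.75),
    binary_spec("thoracic_wall_trauma", 0.09, missing_rate = 0.02,
                rater_kappa = 0.70),
    binary_spec("abd_pain", 0.25, missing_rate = 0.04, rater_kappa = 0.70),
    binary_spec("decreased_breath_sounds", 0.02, missing_rate = 0.01,
                rater_kappa = 0.60),
    binary_spec("mvc", 0.318, rater_kappa = 0.90),
    binary_spec("mvc_report", 0.318, redundant_with = "mvc", phi = 0.97),
    binary_spec("age_lt2", 0.097),
    binary_spec("sex_male", 0.613),
    binary_spec("distracting_injury", 0.15, missing_rate = 0.01,
                rater_kappa = 0.25),
    binary_spec("bowel_sounds_abnormal", 0.05, missing_rate = 0.08))
  rule <- true_rule(
    conditions = list(
      rule_condition("abd_trauma_seatbelt", "==", 1),
      rule_condition("gcs", "<", 14),
      rule_condition("abd_tenderness", "==", 1),
      rule_condition("vomiting", "==", 1),
      rule_condition("thoracic_wall_trauma", "==", 1),
      rule_condition("abd_pain", "==", 1),
      rule_condition("decreased_breath_sounds", "==", 1)),
    leaf_risks = c(0.09, 0.06, 0.03, 0.007, 0.005, 0.0035, 0.0025),
    default_risk = 0.001)
  generator_config(predictors, rule, n = n, seed = seed, site = site)
}

#' Default synthetic external-site configuration
#'
#' The development configuration under covariate and prevalence shift:
#' higher motor-vehicle-collision prevalence (46.3%), no sex column, an
#' extra femur-fracture column present only externally, and rule risks
#' scaled uniformly so the implied outcome prevalence is 2.8%.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param base development configuration to shift.
#' @return A [generator_config()].
#' @export
pedsrc_sim_config <- function(n = 2188, seed = 2L,
                              base = pecarn_sim_config()) {
  cfg <- shift_site(base,
                    prevalence = list(mvc = 0.463, mvc_report = 0.463),
                    n = n, seed = seed, site = "pedsrc")
  cfg <- shift_site(cfg, risk_scale = risk_scale_for_prevalence(cfg, 0.028))
  preds <- cfg$predictors
  preds$sex_male <- NULL
  preds$femur_fracture <- binary_spec("femur_fracture", 0.12)
  generator_config(preds, cfg$rule, n = cfg$n, seed = cfg$seed,
                   site = cfg$site)
}

#' Read and write generator configurations as YAML
#'
#' @param config a [generator_config()].
#' @param path YAML file path.
#' @return `write_generator_yaml` returns `path` invisibly;
#'   `read_generator_yaml` returns a [generator_config()].
#' @export
write_generator_yaml <- function(config, path) {
  preds <- lapply(config$predictors, function(sp) {
    sp <- unclass(sp)
    sp[!vapply(sp, is.null, logical(1))]
  })
  conds <- lapply(config$rule$conditions, function(cc)
    list(predictor = cc$predictor, op = cc$op, threshold = cc$threshold))
  obj <- list(n = config$n, seed = config$seed, site = config$site,
              predictors = unname(preds),
              rule = list(conditions = conds,
                          leaf_risks = config$rule$leaf_risks,
                          default_risk = config$rule$default_risk))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_generator_yaml
#' @export
read_generator_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  preds <- lapply(obj$predictors, function(sp) {
    if (identical(sp$kind, "ordinal")) {
      ordinal_spec(sp$name, unlist(sp$support), unlist(sp$probs),
                   missing_rate = sp$missing_rate %||% 0)
    } else {
      binary_spec(sp$name, sp$prevalence,
                  missing_rate = sp$missing_rate %||% 0,
                  rater_kappa = sp$rater_kappa,
                  redundant_with = sp$redundant_with, phi = sp$phi)
    }
  })
  rule <- true_rule(
    lapply(obj$rule$conditions, function(cc)
      rule_condition(cc$predictor, cc$op, cc$threshold)),
    unlist(obj$rule$leaf_risks), obj$rule$default_risk)
  generator_config(preds, rule, n = obj$n, seed = obj$seed, site = obj$site)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
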