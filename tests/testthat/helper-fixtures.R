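# Small fixtures built in code.

# compact two-condition configuration for fast generator tests
tiny_config <- function(n = 500, seed = 1L,
                        risks = c(0.6, 0.3), default_risk = 0.05) {
  predictors <- list(
    binary_spec("a", 0.3),
    binary_spec("b", 0.4),
    ordinal_spec("score", 1:5, c(0.1, 0.2, 0.3, 0.25, 0.15)),
    binary_spec("noise", 0.5))
  rule <- true_rule(list(rule_condition("a", "==", 1),
                         rule_condition("b", "==", 1)),
                    leaf_risks = risks, default_risk = default_risk)
  generator_config(predictors, rule, n = n, seed = seed, site = "tiny")
}

# random all-binary cohort with a noisy linear-ish outcome
rand_cohort <- function(n, p, seed, prevalence = 0.3) {
  set.seed(seed)
  X <- as.data.frame(matrix(rbinom(n * p, 1, runif(p, 0.2, 0.8)[rep(1:p, each = n)]),
                            nrow = n))
  names(X) <- paste0("v", seq_len(p))
  eta <- as.matrix(X) %*% rnorm(p) + rnorm(n)
  y <- as.integer(eta > quantile(eta, 1 - prevalence))
  if (sum(y) == 0) y[1] <- 1L
  if (sum(y) == n) y[1] <- 0L
  cohort(X, y, site = "rand")
}

# cohort holding the seven reference-CDI columns, all negative by default
reference_schema_cohort <- function(n = 10, outcome = rep(0L, n)) {
  df <- data.frame(abd_trauma_seatbelt = rep(0L, n), gcs = rep(15L, n),
                   abd_tenderness = 0L, vomiting = 0L,
                   thoracic_wall_trauma = 0L, abd_pain = 0L,
                   decreased_breath_sounds = 0L)
  if (all(outcome == 0)) outcome[1] <- 0L
  cohort(df, outcome, site = "ref")
}
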