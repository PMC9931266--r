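# pcsvet

Stability-based vetting of rule-based clinical decision instruments (CDIs)
before external validation.

## The problem

Clinical decision instruments stratify patients with explicit IF/THEN
rules — the motivating example is identifying children at *very low risk*
of intra-abdominal injury undergoing acute intervention (IAI-I) after
blunt torso trauma, so that CT scans can safely be forgone. Prospective
external validation of a CDI is expensive, and many CDIs lose accuracy
when they reach it. `pcsvet` implements a
predictability–computability–stability (PCS) style vetting pipeline that
screens candidate CDIs *before* that investment:

1. **Preprocess** a development cohort: drop variables missing in more
   than 5% of patients, drop variables whose inter-rater Cohen's kappa
   has a 95% CI lower bound below 0.4, impute medians, merge redundant
   binary predictors (|phi| ≥ 0.95) by logical OR, and split
   development/validation stratified on the outcome (66/34 by default).
2. **Fit** interpretable rule-based instruments, each capped at ten
   logical steps: greedy Gini CART trees, one-sided CART rule lists
   (conditions peeled off highest-risk-first, so subgroup risks decrease
   down the list), a sparse rule ensemble mined from bagged shallow
   trees, and the frozen seven-condition reference rule list.
3. **Screen** by diagnostic performance. The ranking currency is the
   weighted operating score

   `score = (w · sensitivity + specificity) / (w + 1)`, with `w = 5`

   (sensitivity weighted five times more heavily than specificity, with a
   90% development-sensitivity elimination floor and a 95% external
   comparison bound).
4. **Measure stability**: per-variable frequency across instruments and
   permutation importance (drop in weighted score when a column is
   shuffled), development→validation performance drop, and refit
   randomness.
5. **Validate frozen models externally** on a second, covariate-shifted
   cohort after explicit (never fuzzy) variable matching, and compare the
   internal and external rankings by Kendall's tau.

Because the original patient-level cohorts are not publicly deposited,
the package ships a synthetic-cohort generator that emulates their
structure: binary findings at configured prevalences, ordinal GCS
(3–15, mass at 15), an embedded ordered rule with monotonically
decreasing leaf risks driving an outcome prevalence of 1.7% at the
development site (2.8%, with MVC prevalence shifted from 31.8% to 46.3%,
at the external site), injected MCAR missingness, a highly correlated
redundant predictor pair, and an imperfect second rater.

## Worked example

```r
library(pcsvet)
cfg <- pecarn_sim_config(n = 12044, seed = 1)   # development-site simulator
ch  <- generate_cohort(cfg)
pp  <- preprocess(ch, seed = 1)
pp$report
#> Screen report
#>   kept (10): abd_trauma_seatbelt, gcs, abd_tenderness, vomiting, ...
#>   dropped, missingness: bowel_sounds_abnormal (8.1%)
#>   dropped, reliability: distracting_injury (kappa 0.24, CI low 0.22)
#>   merges: mvc_or_mvc_report <- {mvc,mvc_report} (phi 0.97)

rl <- cart_rule_list(pp$split$development)
rl
#> CDI rule list (fitted, 7 conditions)
#>   IF   abd_trauma_seatbelt == 1: risk 0.3575  (n=629, pos=63)
#>   ELIF gcs < 14: risk 0.2654  (n=460, pos=31)
#>   ELIF abd_tenderness == 1: risk 0.1469  (n=1262, pos=42)
#>   ...
#>   ELSE very low risk: 0.0000  (n=3073, pos=0)
```

The first three conditions recover the generator's three strong
predictors (abdominal wall trauma/seat-belt sign, GCS < 14, abdominal
tenderness). Evaluating on the held-out internal validation fold at the
operating point selected on the development fold:

```r
risks <- predict(rl, pp$split$validation)
op  <- select_operating_point(sens_spec_curve(risks, pp$split$validation$outcome),
                              w = 5, sens_floor = 0.9)
diagnostic_report(pp$split$validation$outcome, risks, op$threshold)
#> Diagnostic report (threshold 0.02994)
#>   tp=69 fp=1639 tn=2344 fn=6
#>   sensitivity 92.0%, specificity 58.9%, NPV 99.7%, PPV 4.0%
#>   LR+ 2.24, LR- 0.136, F1 0.077, accuracy 59.5%
#>   Brier 0.028, weighted score (5:1) 0.8648
```

A sensitivity of 92.0% means 69 of 75 validation-fold IAI-I patients
fall outside the "very low risk" group; the weighted score 0.8648 is the
5:1 ranking currency. `run_pipeline(pipeline_config())` chains all five
stages — including external validation of the frozen instruments on the
shifted site and the rank-concordance comparison — and writes a JSON/CSV
artifact bundle.

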