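---
title: "Vetting rule-based clinical decision instruments with pcsvet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vetting rule-based clinical decision instruments with pcsvet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pcsvet)
```

## The vetting problem

A clinical decision instrument (CDI) is an explicit rule applied to
patient findings. The instruments handled here stratify children after
blunt torso trauma into "very low risk" of intra-abdominal injury
undergoing acute intervention (IAI-I) versus everyone else; very-low-risk
patients are candidates to forgo CT. Before a CDI is put through an
expensive prospective external validation, we want evidence that (a) it
predicts well out of sample, (b) it is computationally trivial to apply,
and (c) its structure is *stable* — the same predictors would be selected
under reasonable alternative modelling judgment calls. `pcsvet`
operationalizes that vetting loop on synthetic cohorts whose statistical
structure mirrors the motivating trauma datasets.

## The synthetic cohort model

`generate_cohort()` draws each predictor independently from its marginal
specification: binary findings as Bernoulli variables, the Glasgow Coma
Scale as a categorical variable on 3–15 with 90% of its mass at 15 and
6.6% below 14. Two deliberate departures from independence are
supported:

* **Redundant pairs.** A child column is drawn conditionally on its
  parent so the pair attains a target phi correlation. With parent
  prevalence $p$, child prevalence $q$ and target $\phi$, the joint cell
  is $P_{11} = pq + \phi\sqrt{p(1-p)q(1-q)}$ and the child is Bernoulli
  with probability $P_{11}/p$ given parent $=1$ and $(q-P_{11})/(1-p)$
  otherwise. This is exact, seedable, and rejected loudly when the
  target is infeasible for the marginals.
* **A second rater.** For variables carrying a kappa target, the
  duplicate rating equals the first except for symmetric random flips;
  the flip probability is solved numerically (to $10^{-12}$) so the pair
  attains the requested Cohen's kappa at the variable's prevalence. At a
  degenerate prevalence (0 or 1) kappa is undefined and the duplicate
  simply copies the first rater.

The outcome is generated by an embedded ordered rule list: each patient
receives the Bernoulli risk of the *first* matching condition, or a
default risk when none matches. The default development configuration
(`pecarn_sim_config()`) embeds three strong conditions — abdominal wall
trauma/seat-belt sign (prevalence 8%, risk 9%), GCS < 14 (6.6%, risk
6%), abdominal tenderness (18%, risk 3%) — followed by four weak
conditions (vomiting, thoracic wall trauma, abdominal pain, decreased
breath sounds) with small, strictly decreasing risk increments, and a
0.1% default risk. The implied outcome prevalence, computable exactly by
enumeration over the rule predictors' joint law
(`implied_prevalence()`), is 1.73%; the marginals that the original
study reports (MVC 31.8%, age < 2 9.7%, outcome 1.7%) are matched by
construction. The external configuration (`pedsrc_sim_config()`) shifts
MVC to 46.3%, scales every rule risk uniformly so the implied prevalence
is 2.8%, drops the sex column, and adds a femur-fracture column present
only externally — exercising exactly the schema-mismatch dispositions an
external validation has to handle.

Missingness is injected completely at random per column *after* outcome
assignment; the preprocessing screen being exercised is a column-rate
rule, so MCAR suffices. One column (8% missing) is calibrated to fail
the missingness screen and one rater (kappa 0.25) to fail the
reliability screen.

Every column, the outcome, the rater flips and the missingness masks
draw from deterministic sub-streams keyed by the master seed and the
column name, so identical configurations produce bitwise-identical
cohorts and results do not depend on the order in which predictors are
listed.

What the generator does *not* emulate: joint correlations among the rule
predictors (unpublished for the motivating datasets, and set to zero
here apart from the explicit redundant pair), informative missingness,
injury-severity scores, correlated vitals, or longitudinal structure.
Tests passing on these cohorts therefore certify the pipeline's
mechanics — screens, fitters, metrics, freezing — not its behaviour under
real-world predictor dependence.

## Preprocessing rules

The pipeline order is fixed: missingness filter → reliability filter →
median imputation → redundancy merge → stratified split. Choices worth
stating:

* Missingness drops **strictly above** 5% (a column missing exactly
  5/100 survives).
* The kappa confidence interval uses the Fleiss–Cohen–Everitt
  asymptotic standard error with a normal 95% interval; a variable is
  dropped when the lower bound falls below 0.4 ("at least moderate
  agreement"). Variables without duplicate ratings pass unscreened but
  are flagged.
* Binary medians resolve to the more frequent category, an exact 50/50
  tie to 0; ordinal half-integer medians round down to stay on the
  observed support.
* Redundant binary pairs at $|\phi| \ge 0.95$ merge by logical OR
  (clinical predictors are presence flags; OR preserves sensitivity),
  with merge groups taken as connected components. The threshold is a
  configuration default, not an empirical constant.
* The development fraction defaults to 0.663, reproducing a 7,985/4,059
  split of 12,044 patients; the split is stratified on the outcome so
  the two folds' prevalences agree to within one patient per stratum.

## Rule induction

All fitters operate on a complete (imputed) cohort and share the split
engine: an exhaustive scan over every predictor and every admissible
cutpoint (ordinal cutpoints between adjacent observed values, rendered
against the upper value, so a cut between 13 and 14 reads `gcs < 14`),
maximizing the class-weighted, size-weighted Gini decrease

$$\Delta = G(S) - \tfrac{W_L}{W} G(S_L) - \tfrac{W_R}{W} G(S_R),
  \qquad G = 1 - p^2 - (1-p)^2,$$

with outcome-positive cases up-weighted by `class_weight` (default 5,
mirroring the 5:1 sensitivity preference; exposed as configuration
because the original derivation's internal weighting is not stated).
Ties within an absolute tolerance of $10^{-10}$ resolve by column order,
then ascending threshold; an improvement must exceed the incumbent by
more than the tolerance to displace it. With integer class weights every
node total is an exact integer in double precision, so the enumeration
oracle used in the tests agrees with the cumulative-sum implementation
bit for bit. The CART tree and rule-list fitters contain no randomness
at all — refitting on the same data returns the identical model, which
is exactly the refit-randomness contract `refit_randomness()` verifies.

The **rule list** grows one-sidedly: at each step the best split's
higher-risk side is peeled off as an IF-condition leaf carrying its
class-weighted risk and induction recurses on the remainder, which
mirrors derivations that identify high-risk subgroups sequentially and
produces leaf risks that tend to decrease down the list. Growth stops at
`max_rules` (default 10 — the interpretability cap of fewer than ten
logical steps), at `min_leaf` (default 10 rows per side), or at purity.

The **rule ensemble** mines candidate conjunctive rules from the
root-to-node paths of bagged depth-limited Gini trees, then selects
greedily, refitting a case-weighted logistic model at each step. The
selection objective is the best weighted operating score achievable at
any of the candidate model's own operating points *excluding the
all-positive point*: classifying every patient positive scores $w/(w+1)
= 5/6$ regardless of the rules, so leaving it in would make the
objective flat and the greedy search unable to rank candidates. The
excluded point remains available (and is often selected) when the final
operating threshold is chosen for reporting.

The **reference CDI** (`pecarn_cdi()`) is a frozen seven-condition rule
list: a patient is very low risk exactly when no condition fires. The
original publication names only three of its predictors in prose, so all
seven names, the GCS cut and the (synthetic) leaf risks are
configuration, defaulting to the generator's schema with the generator's
strictly decreasing risks.

## Diagnostics and screening

`diagnostic_report()` computes the full battery — sensitivity,
specificity, NPV, PPV, likelihood ratios, F1, accuracy, Brier score — at
an operating threshold with the half-open convention *positive iff risk
≥ t*, which makes the all-positive point reachable and every curve point
bit-reproducible. Ratios with a zero denominator are reported as
`Inf`/`NaN` and flagged, never clamped. Two sensitivity floors coexist
deliberately: 90% as the development-set elimination screen and 95% as
the external comparison bound; both are parameters. Percentages render
to one decimal place and Brier scores to three, matching the reporting
style of the motivating study.

## Stability measures

Permutation importance is the mean drop in the weighted operating score
over `n_perm` within-cohort shuffles of one column at the model's frozen
threshold; variables a model's structure does not reference short-circuit
to exactly zero. The variable-stability ordering is lexicographic —
frequency across screened instruments, then mean non-zero importance,
then name — because the motivating description reports frequency and
non-zero permutation scores without stating how they combine; the
lexicographic rule is this package's documented choice. Model-level
stability combines the development→validation drop in weighted score
with the refit-randomness spread; the final ranking orders by validation
score, then drop, then spread, then name, making it a total order
invariant to input ordering.

## External validation

Variable matching is explicit configuration (`match_variables()`): a
named source→target map with optional transforms, validated so that any
model-critical variable left unmatched is a hard error naming the
variable, while one-sided variables are logged with their disposition.
Silent name-similarity matching is deliberately absent — expert-reviewed
linkage is the failure mode worth surfacing, not hiding. Models and
thresholds enter the external stage frozen; the development-side merge
recipe is replayed on the external cohort so merged columns resolve. The
internal and external rankings are compared by Kendall's tau computed by
pairwise concordance.

## Numerical and degenerate-input conventions

* Split ties: column order, then ascending threshold, tolerance
  $10^{-10}$.
* Single-class fitting inputs yield a degenerate single-leaf model with
  a warning, not an error.
* A true-rule configuration whose implied prevalence is 0 or 1 warns
  (the all-zero-risk rule is a legitimate degenerate case producing an
  all-negative outcome).
* Kappa on a single-category table is `NaN` with a `degenerate` flag.
* The development pipeline withholds the sex column from fitting by
  default because the default external site cannot supply it — the same
  disposition an expert matching step would impose — while keeping it in
  screening reports and marginal comparisons.
* Wall time per pipeline stage is logged and reported, never asserted:
  computational feasibility is hardware-dependent.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep a full run
inside a couple of minutes while leaving Monte-Carlo margins of three
standard errors: generator calibration at n = 12,044 and 2,188 (the
study-scale cohort sizes), ground-truth monotonicity at n = 200,000,
rule recovery on 20 replicates at n = 8,000, split-engine oracle
equivalence on 200 random cohorts of up to 8 binary predictors and 60
rows, and end-to-end determinism on cohorts of 2,500/900 patients. The
acceptance script runs the full pipeline once at study scale.

## Known limitations

Predictor independence (beyond one redundant pair) is the largest gap
between the generator and real trauma registries; stability conclusions
on real data would additionally need the data-perturbation sweeps
(alternative preprocessing judgment calls) that are out of scope here.
The rule ensemble is a deliberately simplified sparse re-implementation
of the rule-fit idea — rules from bagged shallow trees plus greedy
forward selection — not a faithful reproduction of the published
algorithm; published third-party learners (Bayesian rule lists,
iterative random forests, optimal sparse trees, greedy tree sums) are
not re-implemented, but any model honouring the predict-risk contract
can be attached to the same vetting surface.
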