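---
title: "Methods: emulating a two-arm endocrine-therapy trial in registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a two-arm endocrine-therapy trial in registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emutrial)
```

# The estimation problem

The package estimates the comparative effect of initiating (and of
sustaining) adjuvant aromatase-inhibitor versus tamoxifen therapy on
5-year all-cause mortality in postmenopausal women with hormone
receptor-positive breast cancer, using only the data streams a linked
national registry provides: a patient table with tumour characteristics
and vital status, a pharmacy dispensation table, and diagnosis and
drug-exposure tables with dates. Two causal contrasts are targeted:

* the **effect of dispensation** (intention-to-treat analogue): the
  effect of starting one strategy, defined by the first endocrine
  dispensation, regardless of later adherence; and
* the **per-protocol effect**: the effect of starting and continuing the
  assigned strategy, estimated by censoring patients when they deviate
  and re-weighting for the selection that censoring induces.

Because treatment in routine care is chosen, not randomized, both
contrasts rely on *conditional exchangeability*: the assumption that
assignment is as-if random within levels of the measured baseline
covariates, and (for the per-protocol effect) that deviation is
explained by the measured baseline and time-varying covariates. They
also require *positivity* — every covariate pattern must have a
non-negligible probability of receiving either strategy — a point that
matters below.

# Discrete-time survival machinery

Follow-up is cut into 1-month intervals of 30.4375 days; a patient
contributes one person-period record per interval from baseline (first
dispensation) until the first of death, emigration, 60 months, or the
administrative end of follow-up (2015-12-31). One month is used because
the outcome model's spline knots are specified in months and monthly
death probabilities are small (well under 1%), which keeps the pooled
logistic model numerically close to a continuous-time hazard model. The
interval length is a config knob (`interval_days`), not a constant
buried in code.

Three boundary rules are worth stating because they are easy to get
wrong:

* death is assigned to the interval containing the death date, and that
  interval is kept (the event is counted) even if the patient would also
  have been censored there — censoring is defined at interval start,
  death happens during the interval;
* administrative censoring keeps the partially observed final interval
  (a patient enrolled 91 days before the administrative end contributes
  3 records);
* emigration drops the interval containing the emigration date, because
  partial intervals without a terminal event are not modelled.

The weighted pooled logistic model is

$$\operatorname{logit} P(Y_k = 1 \mid A, \text{at risk}) =
  \beta_0 + \beta_A A + s(k)'\gamma + A \, s(k)'\delta ,$$

with $s(k)$ a restricted cubic spline with knots at 6, 12, 24 and 36
months in the truncated-power (Harrell) parameterization: with $K$
knots the basis has $K-1$ columns (the linear term plus $K-2$
constrained cubic terms), is cubic between the knots and linear outside
them. The 6- and 36-month knots are treated as the boundary knots of
the restricted basis, so the fitted log-hazard is linear before 6 and
after 36 months; the alternative (boundary knots at the data range
0–60) would free two more curvature degrees where events are sparse,
and is available by passing different knots to `spline_spec()`. The
basis implementation is oracle-tested against a direct evaluation of
the truncated-power formula and a finite-difference check of linearity
beyond the last knot.

Cumulative incidence uses the product-limit identity
$R_a(t) = 1 - \prod_{k \le t}\bigl(1 - h_a(k)\bigr)$ on the predicted
interval hazards. With a saturated (indicator-per-interval) time model
this reproduces the weighted Kaplan–Meier estimate exactly, which the
test suite exploits as an oracle. Effect measures at 60 months are the
risk difference (percentage points) and risk ratio; the "average hazard
ratio by 5 years" is the exponentiated strategy coefficient from the
model *without* the product term. No proportional-hazards claim is
attached to it: it is a weighted average of interval hazard contrasts
over the 5 years, reported because the index trial reported a Cox
hazard ratio.

Interval hazards are kept on the logistic inverse-link scale
throughout; no continuous-time conversion is applied, since the
discrete-time model is the estimand's native scale.

# Exposure episodes and the deviation clock

Days of supply per dispensation are `pills × strength / DDD`, rounded
to whole days (letrozole 2.5 mg, anastrozole 1 mg, exemestane 25 mg,
tamoxifen 20 mg; shipped as an editable table, `ddd_table()`). Unused
supply carries forward: a refill extends coverage from the later of its
fill date and the current end of supply. This stockpiling convention is
standard in pharmacoepidemiology; the alternative (discarding leftover
supply) would manufacture spurious gaps for early refillers.

Treatment is continuous while any gap between end of supply and the
next same-class fill is under 60 days. The deviation date for a gap is
the 60th day without supply — the day the gap is *confirmed* — i.e.
`covered_until + 59` when `covered_until` is the first uncovered day. A
fill of the other drug class before a confirmed gap is a switch
deviation dated at that fill. Whether the 60-day allowance should be
measured from end-of-supply or from the previous fill date is not
something registry conventions fix uniquely; end-of-supply is
implemented because the grace period is meant to absorb refill
friction, not to shorten long prescriptions, and the choice is
documented rather than silently assumed. The engine is validated
against a brute-force day-by-day supply simulator on 1000 random fill
streams.

Discontinuation because of a contraindication is allowed by the
protocol but is indistinguishable from any other stop in dispensation
data; all stops are therefore treated as deviations in the per-protocol
analysis. This is a fidelity limit of the data, not a modelling choice.

# Weighting

Treatment weights come from a main-effects logistic model of the
assigned strategy on the full baseline covariate roster (age, year of
baseline, time from diagnosis, stage, T and N classification, grade,
HER2, laterality, chemotherapy, radiotherapy, antibody treatment, five
comorbidity flags, six co-medication flags, marital status, education,
employment). Weights are stabilized by default (marginal assignment
probability in the numerator) and untruncated; symmetric percentile
truncation is available (`truncate_pct`). Stabilization is used because
it preserves the estimand while bounding the weighted pseudo-population
size; truncation is off by default because it changes the estimand
slightly and should be a deliberate choice.

Censoring weights are fitted separately per arm — deviation mechanisms
plausibly differ between drug classes — as pooled logistic models of
remaining uncensored on the baseline covariates, the eleven
time-varying flags, and the same restricted-cubic-spline time basis as
the outcome model (one spline implementation, fewer knobs). The weight
attached to interval $k$ is $\prod_{j \le k} 1/\hat
P(C_j = 0 \mid \cdot)$; interval 0 carries weight 1 because an episode
starts covered, so deviation in the first interval is impossible.
Censoring weights are left unstabilized: the outcome model conditions
on the same time basis, so the usual stabilizing numerator (a marginal
time model) would cancel out of the risk contrast while adding one more
fitted object.

Categorical covariates carry an explicit `"missing"` level that enters
every model as an ordinary level; the complete-case sensitivity variant
drops those patients instead.

# The synthetic registry

`scenario_config()` defines the data-generating process;
`simulate_registry()` materializes the four linked tables. The default
scenario emulates, at the published cohort's size (12 536), the
structure the real analysis faced:

* **covariates**: marginal prevalences set to the pooled published
  baseline table (e.g. 21.6% chemotherapy, 34.3% cardiovascular
  disease, 30.1% opioid use); comorbidity and co-medication flags share
  a latent patient-level factor (`comorbidity_cor`, default 0.8) plus
  age loadings, so multimorbidity clusters the way opioid and
  antidepressant use proxy for frailty in real data. The dependence
  structure among comorbidities is not published; the shared-factor
  form and its scale are a modelling choice, exposed as a knob.
* **treatment choice**: a logistic model whose coefficients were
  calibrated once, at large n, so the simulated arms reproduce the
  published arm-specific covariate mix (about 30% chemotherapy among
  aromatase-inhibitor initiators versus 6% among tamoxifen initiators,
  later calendar years favouring aromatase inhibitors, and so on).
* **outcome**: a constant-in-time monthly logistic hazard on the
  baseline covariates, intercept calibrated so the standardized 5-year
  risk under sustained tamoxifen is near 10%, with a conditional
  treatment log-odds ratio (`true_treatment_log_or`, default
  log 1.10) applied in months currently covered by an aromatase
  inhibitor.
* **adherence**: per-arm monthly discontinuation hazards (0.0091 and
  0.0095) calibrated so 5-year adherence lands near the published 58%
  and 57%; a quarter of discontinuations are switches, executed as
  stop-then-start of the other class at the next scheduled fill date
  (at most one switch per patient, so the exposure trajectory stays
  well-defined); refill delays are 0 with probability 0.7, otherwise
  exponential with mean 12 days, which makes confirmed 60-day gaps
  possible but uncommon. Deviation is independent of covariates by
  default (`disc_model_coefs` adds dependence when a scenario needs
  it).
* **censoring**: emigration at 2 × 10⁻⁴ per month, and administrative
  end of follow-up on 2015-12-31 with enrollment uniform over
  2009-08-01 to 2015-12-31.
* **missingness**: injected completely at random at the published
  rates (grade 3.6%, HER2 4.7%, education 1.2%, employment 0.2%).
  The real mechanism is unknown; since the analysis handles
  missingness by category rather than by mechanism, MCAR is the least
  committal choice. A consequence worth noting: the generator's
  treatment and hazard models read the *observed* (post-injection)
  covariates, with the missing level contributing zero to every linear
  predictor, so the estimator's missing-category weight model is
  exactly correctly specified under the default scenario.

`true_counterfactual_risks()` is the oracle: for every generated
patient the 5-year risk under each sustained strategy is available in
closed form from the discrete hazard, so the standardized truth carries
Monte Carlo error only from the covariate draw (reported, and shrinking
as $1/\sqrt{n}$).

What the generator deliberately does **not** emulate: breast-cancer
biology (recurrence, cause-specific death), dose intensity within a
covered interval, real diagnosis/procedure/drug coding systems, and
informative missingness. Passing tests on this generator therefore
demonstrate that the estimators are correct when their identifying
assumptions hold — not that those assumptions hold in any particular
registry.

# Validation scenarios and the positivity lesson

`scenario_recovery()` is the parameter-recovery scenario used by the
acceptance suite: full adherence, no emigration, no missingness, a
conditional effect of log 1.25, and confounding through a compact set
of strong prognostic covariates (chemotherapy, stage, nodal status,
cardiovascular disease, opioid use, age, calendar year) with moderate
coefficients. The compactness is deliberate. An earlier draft reused
the default scenario's fully calibrated treatment model; its fitted assignment
probabilities reach 0.98+ for rare high-risk covariate combinations,
and the resulting heavy-tailed weights (tamoxifen-arm maxima above 40)
produced the textbook finite-sample bias of inverse-probability
weighting under practical positivity violation — covariate balance was
excellent and the weighted Kaplan–Meier agreed with the pooled-logistic
estimate, yet both sat about one percentage point above the truth at
n = 20 000. Since positivity is part of the estimand's identifying
conditions, the recovery scenario was redesigned to satisfy it
comfortably rather than weakening the estimator or the check; the
default scenario keeps the strong confounding, which is the honest
picture of what the emulated analysis faces. With the recovery
scenario, the weighted estimate is unbiased across seeds while the
unadjusted contrast is biased upward by about four percentage points.

`scenario_null()` removes the effect and the confounding; it backs the
null-recovery and censoring-weight-null checks (when deviation is
independent of covariates, weighting must change nothing).

# Inference

Confidence intervals are percentile bootstrap over patients — the
resampling unit is the patient, never the person-period — with every
weight model and outcome model re-fitted inside each replicate, so the
intervals reflect weight-estimation uncertainty. The percentile method
is used because it is the simplest method consistent with
"nonparametric bootstrap with 1000 samples"; percentile intervals need
not bracket the point estimate in small samples, and no such bracketing
is asserted. Replicates whose fits fail are dropped and counted; more
than 10% failures aborts the run. For the weighted intention-to-treat
analysis the outcome design depends on a person-period only through its
(strategy, interval) cell, so each replicate collapses to 2 × 60
weighted event/at-risk totals before fitting — an exact algebraic
rewrite, verified against the general row-level engine in the tests —
which makes 200-replicate bootstraps on 2000-patient cohorts a
per-second affair. Subgroup analyses re-estimate the weight models
within the subgroup; whether the original analysis re-estimated or
reused full-cohort weights is not stated anywhere, and re-estimation is
the choice that keeps the subgroup analysis self-contained.

Model fitting uses a small compiled IRLS logistic solver
(RcppArmadillo), pinned coefficient-for-coefficient to `glm` in the
tests; it exists because the bootstrap hot path spends its time in
model-frame construction otherwise.

# Numerical and degenerate-input choices

* "9 months" = 274 days; all date arithmetic is in whole days.
* A patient whose first-day fills span both drug classes has no defined
  strategy and is excluded (ledger row `ambiguous_first_fill`).
* Postmenopausal status is operationalized as age ≥ 50 at diagnosis or
  an explicit flag column, with the ≥ 40 age floor applied regardless;
  registries do not record menopause directly.
* Comorbidity lookback is all available history; co-medication lookback
  is 183 days. The windows used in the original analysis are defined in
  supplementary code lists that are not reproduced here, so both are
  configurable arguments with these defaults.
* Zero-patient scenarios yield empty tables with full headers;
  separation in a censoring model raises an error naming the problem
  rather than returning silently explosive weights; fitted assignment
  probabilities at machine 0/1 raise a non-overlap error listing the
  offending patients.

# Problem sizes in the test suite

The suite validates at sizes chosen to keep the full run under ten
minutes on one CPU while leaving Monte Carlo error well inside the
asserted tolerances: exact oracles (spline basis, Kaplan–Meier
equivalence, closed-form weights) run at n ≤ 4000; the episode engine
is checked against the day-level simulator on 1000 random streams;
parameter recovery uses 10 seeds at n = 20 000; bootstrap coverage uses
200 simulated cohorts of n = 2000 with 200 replicates each, asserting
coverage between 90% and 99% at nominal 95%.

# Known limitations

* All stops count as deviations; contraindication-driven
  discontinuation cannot be separated, so the per-protocol estimand is
  "sustained dispensation", slightly stricter than the clinical
  protocol.
* The generator's constant-in-time conditional hazard makes spline
  misspecification undetectable by construction; the spline's value
  shows up only through the marginal hazard's time dependence (frailty
  depletion, calendar censoring), which the recovery tests do exercise.
* Unmeasured confounding — the central interpretive problem of the real
  benchmark — is out of scope of the default scenarios; users can
  create it by putting a covariate in `hazard_model_coefs` and omitting
  it from `analysis_config(covariates = ...)`.
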