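# emutrial

Target-trial emulation of adjuvant endocrine therapy — aromatase
inhibitors versus tamoxifen — on 5-year all-cause mortality, built for
linked registry-style data (a breast-cancer quality registry joined to a
prescribed-drug register, patient register, cause-of-death register and
socioeconomic tables).

The package is aimed at pharmacoepidemiologists who want a tested,
reusable implementation of the full analysis chain:

1. **Cohort construction** — eligibility screening (postmenopausal women
   ≥ 40, hormone-receptor-positive stage 1–3 disease, surgery with clear
   margins, first endocrine dispensation within 9 months of surgery and
   inside the study window), with an exclusion ledger; baseline is the
   first dispensation and the assigned strategy is its drug class.
2. **Exposure episodes** — days of supply per fill as
   `pills × strength / DDD`, stockpiling of unused supply, and the first
   protocol deviation per patient: a 60-day gap in supply or a switch to
   the other drug class.
3. **Person-time expansion** — discrete 1-month person-period records
   (`Y_k` death-in-interval, `C_k` deviation-censoring, time-varying
   comorbidity and co-medication flags `L_k`).
4. **Weighting** — stabilized inverse-probability-of-treatment weights
   from a logistic model of strategy on all baseline covariates, and
   per-arm cumulative inverse-probability-of-censoring weights for the
   per-protocol analysis.
5. **Outcome model** — weighted pooled logistic regression of `Y_k` on
   strategy `A`, a restricted cubic spline in follow-up time (knots at 6,
   12, 24, 36 months) and their product:

   `logit P(Y_k = 1 | A, uncensored) = β₀ + β_A A + s(k)'γ + A·s(k)'δ`

   Cumulative incidence by the product-limit identity
   `R_a(t) = 1 − Π_{k≤t} (1 − h_a(k))`, compared at 60 months as a risk
   difference and risk ratio; the average hazard ratio by 5 years is
   `exp(β_A)` from the model without the product term.
6. **Inference** — nonparametric bootstrap (resampling patients,
   re-fitting every model per replicate) with percentile 95% CIs;
   subgroup analyses (age, chemotherapy, opioid/antidepressant use) and
   sensitivity analyses (covariate adjustment with g-formula
   standardization instead of weighting; complete-case).

Real registry data cannot be shipped, so the package includes a
**synthetic linked-registry generator** (`simulate_registry()`) that
reproduces the statistical structure the analysis assumes — confounded
treatment choice calibrated to the published cohort's covariate mix,
a covariate-dependent monthly death hazard with a known conditional
treatment effect, realistic dispensation streams with gaps, stops and
switches, emigration and administrative censoring — plus an oracle
(`true_counterfactual_risks()`) for the true counterfactual risks, so
every estimator can be validated against known truth.

## Worked example

```r
library(emutrial)

registry <- simulate_registry(scenario_config(n_patients = 3000, seed = 42))
registry
#> <emul_registry> 3000 patients, 28551 dispensations, 2370 diagnosis records, 39979 co-medication fills

analysis <- run_analysis(registry, analysis_config(contrast = "itt"))
analysis
#> <emul_analysis> itt/iptw, n = 3000
#> <emul_effects> at 60 months
#>   risk (aromatase inhibitor):  11.2%
#>   risk (tamoxifen):             9.2%
#>   risk difference:             +2.0 percentage points
#>   risk ratio:                  1.22
#>   average hazard ratio:        1.17

cis <- bootstrap_cis(registry, analysis_config(n_bootstrap = 500, seed = 42))
tidy(cis)
#> # A tibble: 5 × 4
#>   measure     estimate conf.low conf.high
#>   <chr>          <dbl>    <dbl>     <dbl>
#> 1 risk_ai_5y    0.112    0.0939     0.131
#> 2 risk_tam_5y   0.0920   0.0450     0.155
#> 3 rd            1.99    -4.80       7.20
#> 4 rr            1.22     0.683      2.58
#> 5 avg_hr        1.17     0.649      2.50
```

The intention-to-treat ("effect of dispensation") estimate weights each
of the 3000 patients by the inverse probability of the strategy they
actually started, then contrasts the standardized 5-year cumulative
incidence curves: here 11.2% under aromatase-inhibitor initiation versus
9.2% under tamoxifen initiation, a risk difference of +2.0 percentage
points whose bootstrap interval (−4.8 to +7.2) is wide at this sample
size. `autoplot(analysis)` draws the adjusted cumulative-incidence
curves; `run_analysis(..., analysis_config(contrast = "per_protocol"))`
censors at the first deviation and adds censoring weights;
`run_subgroup(registry, ~ opioids == 1 | antidepressants == 1, ...)`
re-runs everything inside a subgroup.

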