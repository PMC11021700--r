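---
title: "Methods: predicting cardiovascular risk under hypothetical interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting cardiovascular risk under hypothetical interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A clinical prediction model (CPM) answers "what is this person's 5-year
cardiovascular risk, given their current profile?". Clinicians routinely ask
a different question: "what would the risk be *if* this person quit smoking,
lowered their blood pressure, or started a statin?". That is a counterfactual
(risk-under-intervention) quantity, and a CPM fitted to observational data
does not answer it: its coefficients describe associations in the source
population, not effects of acting on a covariate.

`riskintervene` implements and compares the three strategies used in
practice, for five intervention scenarios in a primary-care CVD
risk-assessment setting modelled on the PREDICT cohort:

| Scenario | Intervention | Eligible at baseline | Treated at the index visit |
|---|---|---|---|
| I | smoking cessation | current smoker | ex-smoker |
| IIa | SBP lowering (lifestyle) | SBP ≥ 140 | SBP ≤ 130 |
| IIb | BP-lowering medication | SBP ≥ 140, no BPLM | on BPLM |
| IIIa | TC/HDL lowering (lifestyle) | TC/HDL ≥ 5 | TC/HDL ≤ 3.5 |
| IIIb | lipid-lowering medication | TC/HDL ≥ 5, no LLM | on LLM |

Thresholds are inclusive. The *index visit* is the latest follow-up visit
within 24 months of baseline (`index_visit = "first"` is a sensitivity
mode).

## The three strategies

**1. Non-causal covariate conditioning** (`risk_pairs()`, `mean_rr()`).
Predict risk from the CPM as-is, edit the scenario's covariate
(`modify_records()`), and predict again. The individual relative risk is the
ratio; the packaged point estimate is its arithmetic mean, with a
descriptive mean ± 1.96 SD spread (not a sampling interval). This strategy
is valid only if the edited coefficient happens to equal the causal effect —
which confounding of the covariate generally prevents.

**2. Two-stage with an in-cohort IPW effect** (`estimate_ipw_rr()`). The CPM
still supplies the absolute risk without intervention. The average causal
effect of the intervention is estimated from the cohort's own follow-up:

- *Selection.* Only participants with a follow-up visit have an observable
  treatment status. A logistic model of return within the window on baseline
  covariates gives weights `1/Pr(return | X)` for the included, restoring
  the eligible cohort's covariate distribution.
- *Treatment.* Stabilized weights `Pr(A = a) / Pr(A = a | L)`, with the
  confounder model fitted both linearly and with restricted cubic splines
  (4 knots at the 5/35/65/95th percentiles) for continuous confounders; the
  lower-AIC specification is used. The confounder sets are all measured
  pre-treatment risk factors except the scenario's own treatment variable.
- *Censoring.* Competing death and loss to follow-up are handled as a
  time-varying "treatment": pooled logistic models of remaining uncensored
  on (A, L, X0, month) (denominator) and (A, month) (numerator) give
  stabilized weights as cumulative products over person-months.
- *Marginal structural model.* A weighted pooled logistic discrete-time
  hazard `logit h_k = β0 + β1 k + β2 A + β3 A·k` on the person-month
  expansion; counterfactual survival is `S_a(K) = Π (1 − h_k(a))` and
  `RR = (1 − S1(60)) / (1 − S0(60))`.
- *Interval.* A person-level nonparametric bootstrap (default 200
  replicates) refits every model per replicate; the 2.5/97.5 percentiles of
  the replicate RRs form the interval.

Identification requires consistency, exchangeability given the measured
confounders, and positivity — all explicit, inspectable assumptions
(weight diagnostics are returned with the estimate).

**3. Two-stage with an external effect** (`external_effect()`,
`combine_risk()`). `risk_under_intervention = risk_original × RR`, with the
RR taken from published meta-analytic summaries (shipped in
`builtin_effects()`). Because multiplication by a positive constant commutes
with order statistics, the published intervention-risk medians/quartiles are
reproduced exactly by scaling the published original-risk columns —
`two_stage_worked_example()` demonstrates this against the shipped published
estimates.

## The synthetic cohort generator

The original cohort is not available, so the package ships a generator
(`generator_config()`, `generate_cohort()`) that reproduces the *structure*
the three strategies care about, with published marginals as calibration
targets:

- **Baseline covariates.** Truncated-normal age/SBP/TC-HDL (age 53 (9.8) in
  30–74, SBP 130 (15), TC/HDL 4.1 (1.2)), 56% male, 54% European, 15/17/68%
  current/ex/never smokers, 10% family history, 11% diabetes, 1% AF,
  23/17/10% BPLM/LLM/ATM. Binary fields are threshold constructions on a
  shared latent health-burden factor `U` (exact marginals, realistic
  correlations).
- **Outcomes.** Exponential proportional-hazards CVD times with sex-specific
  baseline hazards calibrated by root finding to a 3% marginal 5-year risk
  and the published male:female mean-risk ratio; competing death (1.5% per
  5 years), optional dropout, administrative censoring at 84 months.
- **Selection.** Return to follow-up depends on measured covariates, with
  the diabetes coefficient sized to reproduce the published 11% → 29%
  enrichment among returners; the intercept is calibrated to the marginal
  return probability (24.3%).
- **Confounded uptake.** Among eligible returners, uptake of the active
  scenario's intervention follows a logistic model in a *measured*
  confounder score (diabetes, age, SBP, TC/HDL, BPLM), so IPW with the
  default confounder sets can fully adjust. The marginal uptake probability
  is calibrated (default 11% for smoking cessation, the published quit
  fraction).
- **A known true effect.** Uptake multiplies the hazard from the index
  visit onward by a hazard ratio found by `uniroot()` so that the
  population 5-year risk ratio over the eligible cohort equals the
  configured `true_rr`; `true_standardized_rr()` recomputes it exactly from
  the stored per-person hazards. For smoking cessation the baseline
  ex-smoker coefficient is tied to `current + log(HR)` so prevalent
  ex-smokers and sustained quitters share one hazard.
- **Unmeasured confounding of the non-causal contrast.** Smoking status is
  drawn by ordered thresholds on a score loaded on `U`
  (`status_confounding`), and `U` also enters the hazard (`latent_hazard`).
  The CPM cannot adjust for `U`, so the baseline ex-vs-current contrast —
  exactly what strategy 1 uses — is biased, while strategies 2 and 3 are
  unaffected. This reproduces the qualitative finding that motivates the
  comparison.

Dropout is drawn last in the RNG stream, so switching it on changes nothing
else — a convenient oracle for censoring-weight tests.

What the generator does *not* emulate: time-varying risk factors between
visits, an open-cohort administrative censoring pattern, regional
deprivation structure, or non-proportional hazards.

## Study sizes and the recovery design

The published rates are honest but stingy for simulation: at a 3% 5-year
event rate, a 24% return rate and 11% uptake, a cohort of 20,000 yields only
a handful of treated events, so no estimator can be evaluated on it. The
package's parameter-recovery experiments therefore *enrich the rates while
keeping the structure*: `cvd_risk_5y = 0.12`, `followup_prob_base = 0.6`,
`uptake_prob = 0.4`. With n = 20,000 this gives roughly 3,000 eligible,
1,900 included, 700 treated and a per-replicate RR standard deviation of
about 0.06 — enough for a 20-replicate bias/coverage check against true RRs
in {0.6, 0.8, 1.0, 1.2}. This is a Monte-Carlo design choice, not a claim
about the source cohort.

Typical timings (one CPU): generating 20,000 participants ≈ 2 s; the full
IPW pipeline with a 200-replicate bootstrap ≈ 25–30 s.

## Numerical choices

- Cox models: `survival::coxph` with Efron ties; absolute risk via the
  baseline survival at a reference profile (continuous predictors at the
  stratum mean, categories at the mode).
- Quantiles: linear-interpolation (type 7) throughout the reporting layer.
- Weight models and the MSM use an internal damped Newton–Raphson logistic
  solver on prebuilt design matrices. It is exactly the binomial MLE
  (agreement with `stats::glm` is unit-tested); it exists because the
  bootstrap refits every model a few thousand times, which it supports with
  frequency weights and warm starts. Two structural shortcuts keep this
  cheap without changing the estimates: models whose regressors depend only
  on the (month, treatment) cell are fitted on weighted cell aggregates,
  and the censoring denominator exploits that only the month index varies
  within person. Bootstrap replicates converge to a relative deviance
  change of 1e-7 (point fits 1e-9); the treatment-model specification
  chosen by AIC at the point fit is held fixed across replicates.
- Stabilized treatment weights are not truncated by default (`truncate`
  winsorizes at chosen quantiles if requested); positivity problems should
  surface, not be hidden.

## Limitations

- The non-causal interval (mean ± 1.96 SD of individual RRs) describes
  spread, not sampling uncertainty; it is kept because the strategy itself
  is a descriptive comparator.
- The external-effect strategy assumes a constant relative effect across
  people and transportability of the published RR.
- The MSM's linear-in-month log-odds hazard is an approximation; with rare
  per-month events it tracks the continuous-time model closely.
- The IPW estimand is a population-average effect; applying it uniformly in
  the two-stage identity ignores effect heterogeneity.
- The bootstrap resamples people, not visits; visit-process uncertainty
  within person is not separately propagated.
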