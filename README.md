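# persistkit

Treatment-persistence analysis for infliximab therapeutic drug monitoring
(TDM) in inflammatory bowel disease, built for longitudinal
patient-support-program records: one row per administered infusion (date,
dose in mg, weight), plus trough TDM results (serum infliximab
concentration in µg/mL, antibodies-to-infliximab status).

**Who it is for.** Pharmacoepidemiologists and biostatisticians asking
whether dose optimization prompted by a low trough concentration is
associated with longer persistence on therapy — and anyone who needs the
building blocks: a reproducible discontinuation rule for claims-style
infusion data, dose-escalation detection, time-dependent-exposure Cox
models, and quantitative bias analysis.

## What it computes

* **Persistence** — a patient with a between-treatment gap (or a final
  treatment-to-censoring gap) strictly greater than the grace period
  (20 weeks; 12 weeks as sensitivity) is deemed discontinued as of 8 weeks
  after the last infusion preceding the gap; otherwise right-censored.
  Kaplan–Meier curves via the product-limit estimator.
* **Dose optimization** — interval/dose-level escalations against
  predefined thresholds.  Low: interval decrease ≥ 11 d with posterior
  interval ≤ 46 d, and/or dose increase ≥ 1.5 mg/kg with posterior level
  ≥ 7 mg/kg.  High: posterior interval ≤ 35 d / posterior level ≥ 9 mg/kg.
  Maintenance phase only (after Week 9), mg/kg resolved from recorded
  weights.
* **Cohorts** — overall-population inclusion rules (initiation 2015–2018,
  age 18–90, first weight < 130 kg, 8-month lookback) and the TDM subgroup
  (first maintenance-phase TDM with a recorded result before
  discontinuation/censoring), split into subsets below/above a
  concentration threshold (3/5/10 µg/mL) with (B) or without (A) dose
  optimization within 9/17 weeks post-TDM.
* **Models** — stratified Cox proportional-hazards fits in
  counting-process form, `Surv(start, stop, event)`, with the exposure
  (TDM use, or post-TDM dose optimization) as a time-dependent 0/1
  covariate — exposed person-time starts at the exposure date, which
  removes immortal-time bias.  Fixed covariates: age group, gender, weight
  quartiles, province/region, log(days to TDM); strata: initiation year.  A
  four-model ladder tests exposure×covariate interactions and the
  proportional-hazards assumption (exposure×log t), with HR read-outs at 4
  and 6 weeks when PH fails.
* **Tipping-point bias analysis** — the post-exposure persistence of
  exposed patients is shortened on a 25-day grid until the protective
  association is no longer significant; reported as the median achieved
  per-patient reduction in days and 8-week cycles (`round(days/56, 1)`).
* **Synthetic cohorts** — `simulate_cohort()` generates
  patient-support-program-style data (induction 0/2/6 weeks, q8w
  maintenance, TDM ordering, a low-concentration/ATI stratum, physician
  escalation policy, latent discontinuation hazard with a true exposure
  hazard ratio θ) with ground truth, so the whole pipeline is testable
  without access to real records.

## Worked example

```r
library(persistkit)

sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 42))  # theta_do = 0.36

# overall population: persistence from initiation
ov <- prepare_overall(sim)
km <- km_estimate(ov$outcomes)
round(100 * km_survival_at(km, c(365, 4 * 365)), 1)
#> [1] 74.0 35.7

# TDM subgroup, serum IFX < 3 ug/mL, dose optimization within 9 weeks
prep <- prepare_subgroup(sim, conc_threshold = 3, window_weeks = 9)
table(prep$data$subset)
#>
#>   A   B
#> 237 220

fit <- fit_cox(prep$cp, standard_covariates("subgroup"))
exposure_hr(fit)
#>          hr     hr_lo     hr_hi            p      coef        se
#> 1 0.3100768 0.2153327 0.4465072 3.092946e-10 -1.170935 0.1860385
```

One-year persistence is 74.0% and the time-dependent exposure hazard ratio
0.31 (95% CI 0.22–0.45): dose-optimized below-threshold patients (subset B)
persist longer than non-optimized ones (subset A), consistent with the
generator's true θ = 0.36 at this cohort size (the replicate-study median
in `scripts/acceptance.R` sits on top of it).  `model_ladder()` runs the four-model
selection, `tipping_point()` the bias analysis, and `run_pipeline()` the
whole chain (simulation or CSV inputs → persistence, dose-optimization
events, subset labels, model fits, manifest) from a config; a thin CLI over
the same functions lives in `inst/cli/persistkit.R`.

## Not in scope

Assay mechanics and lab-level ATI testing practice, pharmacokinetic
modelling of concentrations, cause-of-discontinuation inference, and
reproduction of real-cohort estimates (the underlying program data are not
public; access is by application to the data holder).
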