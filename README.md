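# qgcmix

Quantile g-computation for multi-chemical exposure mixtures, built for
the epidemiology of prenatal heavy-metal exposure and child
neurodevelopment: maternal blood lead, mercury and cadmium and urinary
arsenic (µg/L) as the mixture, binary neurodevelopmental-impairment
outcomes from a four-domain developmental assessment as the endpoints.

## What it computes

Each exposure is scored into `q` quantile categories
`X_j^q ∈ {0,…,q−1}` and a logistic model is fit jointly:

```
logit Pr(Y=1) = β0 + Σ_j β_j X_j^q + γ'Z
```

* **ψ (psi1)** `= Σ_j β_j` — the joint log-odds effect of raising every
  mixture member one quantile simultaneously.
* **Directional weights** `w_k = β_k / Σ_{j in sign class} β_j` — each
  chemical's share of the positive or negative part of the joint
  effect; magnitudes sum to 1 within each direction.
* **Prevalence ratio** — g-computation standardization: set all members
  to joint level `s`, average fitted probabilities, regress
  `log p_s` on `s` (log-linear marginal structural model), anti-log the
  slope. `PR = exp(ψ_marginal)` per simultaneous one-quantile increase.
* **95% CI** — subject-level percentile bootstrap (default B = 1000),
  re-running the whole pipeline per replicate; fully seed-deterministic.
* Plus: chemical-specific comparison fits, forward–backward stepwise
  covariate selection (AIC/deviance) with a per-step log, developmental
  impairment scoring (fail > 2 age-normed items in a domain ⇒ impaired;
  global impairment = impaired in ≥ 1 domain), Cronbach's alpha,
  household wealth → SES classification (>9 / 6–9 / <6), reference-value
  dichotomization (Pb 35, Hg 0.8, Cd 0.3, As 15 µg/L), percentile
  summary tables, and a seeded synthetic cohort generator (Gaussian
  copula over log-normal marginals) so everything runs without external
  data.

## Worked example

```r
library(qgcmix)

co <- generate_cohort(
  1000,
  truths = list(language = default_mixture_truth("language")),
  seed = 7)

f <- fit_mixture_model(
  co, "impaired_language",
  covariates = c("sex", "birth_weight_kg", "maternal_education",
                 "child_age_months", "ses_score"),
  B = 200, seed = 7)
f
#> Quantile g-computation mixture fit -- impaired_language
#>   mixture: Pb + Hg + Cd + As  (q = 4 , n = 1000 )
#>   adjusted for: sex, birth_weight_kg, maternal_education, child_age_months, ses_score
#>   psi1: PR = 0.4619 (95% CI: 0.3973, 0.5268) per one-quantile increase in all members
#>   conditional psi = -1.193 (OR 0.3035)
#>   negative partial: Pb + Hg + Cd + As = 0.3035
#>   weights (sign = direction):
#>      Pb      Hg      Cd      As
#> -0.5608 -0.1294 -0.2354 -0.0744
```

The synthetic language-impairment truth is all-negative with lead
dominant (generating weights 0.610/0.223/0.131/0.036); the fit recovers
that structure: a PR of 0.46 means each simultaneous one-quartile rise
in all four metals multiplies language-impairment prevalence by 0.46
(a 53.8% reduction in the "not impaired" direction of the scale — use
`percent_change(0.4619)` for the table convention), with lead carrying
56% of the negative direction. `render_model_table()`,
`export_weight_plot_data()` and `export_msm_curve()` turn fits into the
standard table/figure data; `run_pipeline("config.yaml", "out/")`
(or `inst/scripts/qgcmix-pipeline.R`) runs
simulate → prep → score → fit → report end to end with a manifest.

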