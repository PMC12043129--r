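---
title: "Methods: quantile g-computation for a four-metal exposure mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantile g-computation for a four-metal exposure mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgcmix)
```

## The problem and the estimator

Children in artisanal and small-scale gold-mining areas are prenatally
exposed to several neurotoxic metals at once — lead, mercury and cadmium
measured in maternal blood, arsenic in maternal urine, all in µg/L.
Single-chemical regressions cannot express the joint effect of such a
mixture, and they behave badly under the strong mutual correlation of
co-occurring exposures. Quantile g-computation addresses both problems.

Each exposure $X_j$ is scored into $q$ ordered categories
$X_j^q \in \{0, \dots, q-1\}$ by its own empirical quantiles ($q = 4$,
quartiles, by default). A logistic model for the binary impairment
outcome $Y$ is fit jointly on the scores and any covariates $Z$:

$$\operatorname{logit} \Pr(Y = 1) = \beta_0 + \sum_{j=1}^{d} \beta_j X_j^q + \gamma' Z .$$

The **conditional joint effect** is $\psi = \sum_j \beta_j$, the log-odds
change when *every* mixture member rises one quantile simultaneously.
Because the coefficients may point in either direction, the mixture
decomposes into **directional partial effects**
$\psi^+ = \sum_{\beta_j > 0} \beta_j$ and
$\psi^- = \sum_{\beta_j < 0} \beta_j$ (reported exponentiated), and each
chemical carries a **directional weight**

$$w_k = \frac{\beta_k}{\sum_{j \in \text{sign class of } k} \beta_j},$$

so the weights within each sign class sum to 1 in magnitude. The naive
normalization by $\sum_j \beta_j$ over *all* members is only coherent
when every coefficient shares one sign; the per-direction partition is
the convention this package enforces on every fit (and validates as an
invariant in its test suite).

### From odds to a prevalence ratio

Epidemiological reporting prefers prevalence ratios. The package obtains
a marginal PR by g-computation standardization: for each joint level
$s = 0, \dots, q-1$, every member's score is set to $s$ for every subject
and the fitted probabilities are averaged, giving the standardized
probability $p_s$. The log-linear **marginal structural model** is then
the least-squares fit of $\log p_s$ on $s$; its slope is the marginal
log-RR per joint quantile, $\psi_{\text{marg}}$, and
$\text{PR} = e^{\psi_{\text{marg}}}$. Both scales are reported:
$\psi$ (conditional, odds) and $\psi_{\text{marg}}$ (marginal, risk);
the PR is primary. The directional partial effects are likewise emitted
on both scales (`partial_pos`/`partial_neg` exponentiate coefficient
sums; `partial_pos_marginal`/`partial_neg_marginal` standardize varying
only one sign class), since the two are genuinely different quantities
for a non-rare outcome.

Note the two scales do **not** coincide: for a common outcome the
marginal log-RR is attenuated relative to the conditional log-odds
(noncollapsibility plus the link mismatch). This matters for how
simulation recovery is judged — see *Estimands in the simulation checks*
below.

### Uncertainty

Confidence intervals come from a subject-level nonparametric bootstrap:
resample rows with replacement, re-run the whole pipeline
(re-quantization included) on each replicate, and take the percentile
interval of the replicate PRs. Defaults: $B = 1000$ resamples, 95%
level; a log-scale normal-approximation interval is available as an
option. Replicates whose logistic fit does not converge (IRLS failure or
a coefficient beyond ±15 log-odds, the practical signature of
separation) are dropped and counted; the interval is flagged unreliable
when more than 20% fail. All resampling is driven by a single integer
seed, so identical seeds give bit-identical intervals.

### Comparison models and covariate selection

`chemical_specific_fit()` runs the identical pipeline with a
single-member mixture, so its PR is per quantile of one chemical
adjusted for covariates; a $d = 1$ mixture fit is definitionally equal
to it. `stepwise_select()` performs forward–backward greedy selection
over candidate covariates by AIC (or deviance with a stated penalty),
with the mixture scores held fixed, a full per-step log, and
deterministic tie-breaking by candidate order. The conventional adjusted
covariate set is child sex, birth weight, maternal education, child age
and household SES.

## Upstream scoring stages

**Impairment scoring.** The developmental instrument has four domains
(gross motor, fine motor, language, social), each scored 0–34 over 34
pass/fail items. A child failing **more than two** items that carry an
age-referenced 90th-percentile norm in a domain is impaired for that
domain; failing one or two is usual (the boundary sits at exactly two).
Global impairment is the union: impaired in at least one domain. The
instrument's true normative tables are proprietary; the package ships a
synthetic norm generator (`make_norm_table()`, which marks an item/age
band as "expected pass" when at least 90% of a simulated reference
population passes) plus a CSV loader for user-supplied norms, so the
classification rule itself is fully testable. Scale reliability is
Cronbach's $\alpha = \frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_T^2\bigr)$.

**Wealth/SES.** The household wealth score is the sum of binary asset
indicators. The three-level classification adopts the non-overlapping
partition: score $> 9$ high, $6$–$9$ moderate, $< 6$ low. The prose
version of the rule ("$\geq 9$ high, $6$–$9$ moderate") overlaps at 9;
the package defaults to the partition reading and offers
`rule = "text"` (which moves only score 9 into the high class) for
sensitivity analysis.

**Reference-value dichotomization.** Concentrations are dichotomized at
human-biomonitoring reference values — blood Pb 35, Hg 0.8, Cd 0.3 µg/L
and urinary As 15 µg/L — with "elevated" meaning at or above the
threshold; stratum counts and percentages (one decimal) are returned.
Percentile summaries (P10, P25, median with a binomial order-statistic
95% CI, P75, P95, max) use the linear-interpolation quantile definition
(R type 7) throughout; the published descriptive table this layout
mirrors contains a few percentages that differ from the printed counts
by 0.1 after recomputation, and the package always reports the computed
value.

## The synthetic cohort generator

The generator exists so every downstream stage can be exercised and
validated without any external data. It emulates:

* **Exposures.** A Gaussian copula over log-normal marginals. Each
  marginal is parameterized from a target (P25, median, P75):
  `meanlog = log(median)`,
  `sdlog = (log(P75) - log(P25)) / (2 qnorm(0.75))`. Defaults (µg/L):
  Pb (17.2, 27.2, 42.5), Hg (0.8, 1.2, 1.9), Cd (0.17, 0.20, 0.30),
  As (4.5, 8.3, 14.9). The published Cd quartiles are inconsistent after
  rounding (printed P25 above the median), so the default Cd P25 is set
  between the printed P10 and P25. Spearman targets are converted to
  latent Pearson correlations by $2\sin(\pi\rho/6)$; the default
  inter-metal rank correlation of 0.3 is an assumption (field reports
  describe the multicollinearity only qualitatively) and is
  configurable. Non-positive-semi-definite matrices are rejected with a
  diagnostic.
* **Covariates.** Sex 52.7% male; age at assessment Normal(43.9, 3.4)
  months truncated to 36–59; birth weight Normal(3.1, 0.5) kg truncated
  to 1.5–5.0 (a typical East-African birth-cohort distribution; the
  source tables do not print one); education none/primary/ordinary/
  tertiary at 19.7/55/20/5.3% (the source collapses everything above
  "none" into 80.3%, so the split within it is a package choice); wealth
  scores drawn to give 68.1/20.6/11.3% high/moderate/low SES.
* **Outcomes.** Bernoulli draws from the logistic model on *quantized*
  exposures — the same model family the estimator fits, so recovery
  checks are well-posed. The only noise is the Bernoulli draw itself; no
  additive residual exists on the latent scale. Covariate effects act on
  covariates centered at the generator's target means, so the truth's
  intercept directly controls the baseline log-odds. A
  `mixture_truth` can be built from coefficients, from
  $(\psi, \text{shares})$, or from directional
  $(\psi^+, \psi^-, \text{signed weights})$; per-direction weight sums
  of 1 are enforced at construction. The shipped per-domain default
  truths copy the sign structure and weight profile of the adjusted
  study fits (e.g. language all-negative, Pb weight 0.610) with
  intercepts tuned to the observed domain prevalences.
* **Item responses.** A two-parameter logistic IRT model: pass
  probability `plogis(a (theta + 0.5 z_age - d))` with domain ability
  `theta ~ N(0,1)`, item difficulties spread over (-3.5, 0.5) and common
  discrimination 1.2, chosen so a 34-item domain has internal
  consistency near the 0.85–0.95 reliability band instruments of this
  class report.

What the generator does **not** emulate: laboratory measurement error,
limits of detection/censoring, matrix effects, missingness mechanisms,
postnatal exposure, and any true nonlinearity or interaction in the
dose–response. Passing recovery tests therefore show the estimator is
correct *under its own assumptions*, not that those assumptions hold in
field data.

## Estimands in the simulation checks

The generator's $\psi_{\text{true}}$ is a conditional log-odds per
quantile. The PR the pipeline reports estimates the marginal log-RR
slope, a *different* number for a non-rare outcome (at
$\psi_{\text{true}} = -0.2$ and ~28% prevalence the true marginal PR is
about 0.87 versus $e^{-0.2} = 0.82$). The package's simulation checks
therefore compare like with like:

* recovery of $\psi$ is judged on the conditional scale,
  $e^{\hat\psi}$ versus $e^{\psi_{\text{true}}}$, within Monte-Carlo
  error across seeded replicates;
* the bootstrap interval is a CI for the marginal PR, so its coverage is
  assessed against the generating process's true standardized PR,
  computed by `true_marginal_pr()` — the exact population version of the
  MSM slope, evaluated on a large reference covariate draw.

Conflating the two scales would charge the interval with a
noncollapsibility bias that is a property of the estimand definition,
not of the interval.

## Numerical and design choices

* Quantile definition: linear interpolation of the empirical CDF
  (R type 7) everywhere — scoring cut points, percentile summaries,
  bootstrap percentile intervals.
* Ties at a scoring cut point go to the **lower** bin; with fewer
  distinct values than bins the duplicated cut points collapse, a
  warning is emitted, and occupancy counts make the collapse visible.
* Aliased (rank-deficient) design columns are detected by QR and dropped
  with a record before fitting; a bootstrap replicate that loses a
  factor level simply drops the aliased dummy.
* The MSM line is fit by ordinary least squares on
  $(s, \log p_s)$, $s = 0,\dots,q-1$; a standardized probability of
  exactly 0 or 1 makes the log-RR undefined and raises an error rather
  than a silent NaN.
* Stepwise ties are resolved by candidate order (adds enumerated before
  drops), making selection deterministic; a small numerical epsilon
  ($10^{-8}$) guards the improvement comparison.
* Significance convention, where p-values are discussed, is two-sided
  5%; no multiplicity correction is applied across the five outcome
  domains — a deliberate mirror of common practice in this literature
  and a documented caveat, not an endorsement.
* Missing concentrations or covariates are handled by complete-case
  exclusion with a logged count; no imputation is attempted.

## Problem sizes used by the shipped checks

The test suite validates the estimator against exhaustive brute-force
standardization on cohorts of 50–100 subjects; parameter recovery runs
20 seeded replicates of $n = 5000$ at each
$\psi_{\text{true}} \in \{-0.4, -0.2, 0, +0.2\}$; interval coverage uses
200 replicate cohorts of $n = 500$ with $B = 200$ bootstrap resamples
(the same experiment `scripts/acceptance.R` reruns from scratch); the
end-to-end pipeline smoke runs $n = 800$ with $B = 25$ over all five
domains. These sizes were chosen as the smallest at which the
Monte-Carlo error bands in the corresponding checks are meaningful.

## Known limitations

* The estimator assumes the logistic model on quantile scores is
  correctly specified; real dose–response shapes (thresholds,
  supralinearity at low dose) are approximated only as well as $q$
  categories allow.
* The marginal PR construction (logistic fit, then log-linear MSM on
  standardized probabilities) is one of several defensible conversions
  from odds to risk; intervals may shift slightly under alternatives.
* Percentile bootstrap intervals undercover mildly at small $n$ and
  small $B$; the shipped coverage experiment quantifies this at its
  stated scale.
* The synthetic norms make the impairment *rule* testable but say
  nothing about the instrument's real normative calibration.
* No causal identification is claimed beyond the estimator's stated
  assumptions (no unmeasured confounding, consistency, positivity
  within quantile strata).
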