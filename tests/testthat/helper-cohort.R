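# shared fixtures: small study-shaped cohorts and truths built in code

adjusted_covariates <- c("sex", "birth_weight_kg", "maternal_education",
                         "child_age_months", "ses_score")

# single-direction truth with the language-style weight profile
language_truth <- function(psi = -0.2, prevalence = 0.283, q = 4L,
                           covariate_coef = default_covariate_effects()) {
  mixture_truth(stats::qlogis(prevalence) - 1.5 * psi, psi = psi,
                weights = c(Pb = 0.610, Hg = 0.223, Cd = 0.131, As = 0.036),
                covariate_coef = covariate_coef, q = q)
}

# covariate-free truth: outcome depends on the quantized mixture only
bare_truth <- function(psi, prevalence = 0.3, q = 4L,
                       weights = c(Pb = 0.610, Hg = 0.223, Cd = 0.131,
                                   As = 0.036)) {
  mixture_truth(stats::qlogis(prevalence) - 1.5 * psi, psi = psi,
                weights = weights, covariate_coef = numeric(0), q = q)
}

small_cohort <- function(n = 500, psi = -0.2, seed = 1) {
  generate_cohort(n, truths = list(y = language_truth(psi)), seed = seed)
}

# hand-buildable norm table for scoring-rule tests: one domain, 5 items,
# all normed (expected pass) in a single wide age band
toy_norms <- function(items = paste0("dom_i", 1:5), expected = rep(TRUE, 5)) {
  out <- data.frame(domain = "dom", item = items, age_band = "[36,60]",
                    pass_rate = 0.95, expected_pass = expected)
  attr(out, "age_breaks") <- c(36, 60)
  out
}
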