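#' Exposure marginal and correlation profile
#'
#' Describes the joint distribution the exposure generator draws from: one
#' log-normal marginal per chemical, parameterized from its target median
#' and quartiles, tied together by a Gaussian copula with a specified
#' Spearman rank-correlation matrix.
#'
#' The log-normal `meanlog` is `log(median)`; `sdlog` is
#' `(log(p75) - log(p25)) / (2 * qnorm(0.75))`, i.e. the value that puts
#' the target quartiles at the 25th/75th percentiles of the fitted
#' distribution (the two constraints are averaged when the printed
#' quartiles are not exactly log-symmetric).
#'
#' @param chemicals data frame with columns `chemical`, `p25`, `median`,
#'   `p75` (all concentrations in ug/L, strictly positive, ordered
#'   `p25 < median < p75`).
#' @param rank_cor either a single off-diagonal Spearman correlation
#'   applied to every pair, or a full symmetric positive semi-definite
#'   correlation matrix with unit diagonal (rows/cols in the order of
#'   `chemicals$chemical`).
#' @return Object of class `"exposure_profile"`.
#' @seealso [default_exposure_profile()] for the study-calibrated defaults.
#' @export
exposure_profile <- function(chemicals, rank_cor = 0.3) {
  req <- c("chemical", "p25", "median", "p75")
  if (!all(req %in% names(chemicals))) {
    stop("chemicals must have columns: ", paste(req, collapse = ", "))
  }
  with(chemicals, {
    if (any(p25 <= 0 | median <= 0 | p75 <= 0)) {
      stop("marginal targets must be strictly positive")
    }
    if (any(!(p25 < median & median < p75))) {
      stop("marginal targets must satisfy p25 < median < p75")
    }
  })
  d <- nrow(chemicals)
  if (is.matrix(rank_cor)) {
    R <- rank_cor
    if (!isTRUE(all.equal(R, t(R)))) stop("correlation matrix must be symmetric")
    if (any(abs(diag(R) - 1) > 1e-12)) stop("correlation matrix must have unit diagonal")
    if (nrow(R) != d) stop("correlation matrix dimension must match chemicals")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite (min eigenvalue ",
           signif(min(ev), 3), ")")
    }
  } else {
    R <- matrix(rank_cor, d, d)
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("equicorrelation ", rank_cor, " is not positive semi-definite for d = ", d)
    }
  }
  dimnames(R) <- list(chemicals$chemical, chemicals$chemical)
  chemicals$meanlog <- log(chemicals$median)
  chemicals$sdlog <- (log(chemicals$p75) - log(chemicals$p25)) /
    (2 * stats::qnorm(0.75))
  structure(list(chemicals = chemicals, rank_cor = R),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("Exposure profile (log-normal marginals, Gaussian copula)\n")
  print(x$chemicals[, c("chemical", "p25", "median", "p75")], row.names = FALSE)
  cat("Spearman rank correlations:\n")
  print(round(x$rank_cor, 3))
  invisible(x)
}

#' Default exposure profile for the four-metal mixture
#'
#' Marginal targets (ug/L) for maternal blood Pb, Hg, Cd and urinary As in
#' an artisanal-gold-mining cohort: Pb (17.2, 27.2, 42.5), Hg (0.8, 1.2,
#' 1.9), Cd (0.17, 0.20, 0.30), As (4.5, 8.3, 14.9). The published Cd
#' quartiles are not mutually consistent after rounding (printed P25 above
#' the median), so the default Cd P25 is set between the printed P10 and
#' P25; see the methods vignette. The default inter-metal Spearman
#' correlation of 0.3 is an assumption: co-exposure correlations are
#' reported only qualitatively in field studies of this setting.
#'
#' @param rank_cor pairwise Spearman correlation (scalar or matrix).
#' @return An [exposure_profile()] object.
#' @export
default_exposure_profile <- function(rank_cor = 0.3) {
  exposure_profile(
    data.frame(
      chemical = c("Pb", "Hg", "Cd", "As"),
      p25    = c(17.2, 0.8, 0.17, 4.5),
      median = c(27.2, 1.2, 0.20, 8.3),
      p75    = c(42.5, 1.9, 0.30, 14.9)
    ),
    rank_cor = rank_cor
  )
}

# Spearman rank correlation -> Pearson correlation of the latent normals
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Draw correlated exposure concentrations
#'
#' Gaussian-copula sampler: latent multivariate normals with the Pearson
#' correlation implied by the profile's Spearman targets
#' (`2 sin(pi rho / 6)`), mapped through the log-normal marginal quantile
#' functions. Identical `(n, profile, seed)` give identical output.
#'
#' @param n number of subjects (>= 1).
#' @param profile an [exposure_profile()].
#' @param seed integer seed.
#' @return data frame of positive concentrations, one column per chemical.
#' @export
generate_exposures <- function(n, profile = default_exposure_profile(),
                               seed = 1L) {
  if (!inherits(profile, "exposure_profile")) stop("profile must be an exposure_profile")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  Rp <- spearman_to_pearson(profile$rank_cor)
  diag(Rp) <- 1
  ev <- eigen(Rp, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("implied latent correlation matrix is not positive semi-definite")
  }
  # eigen square root tolerates semi-definite matrices (chol does not)
  A <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  d <- nrow(profile$chemicals)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * d), n, d) %*% A
  U <- stats::pnorm(Z)
  out <- as.data.frame(mapply(function(u, ml, sl) stats::qlnorm(u, ml, sl),
                              as.data.frame(U),
                              profile$chemicals$meanlog,
                              profile$chemicals$sdlog))
  names(out) <- profile$chemicals$chemical
  out
}

#' Draw baseline covariates for a synthetic cohort
#'
#' Emulates the covariate structure of a rural mining-area birth cohort:
#' child sex (52.7% male), child age at assessment ~ Normal(43.9, 3.4)
#' months truncated to 36-59, birth weight ~ Normal(3.1, 0.5) kg truncated
#' to 1.5-5.0, maternal education (none 19.7%, primary 55%, ordinary 20%,
#' tertiary 5.3%), and a household wealth score drawn so the three SES
#' classes occur with frequencies 68.1% high (score 10-12), 20.6% moderate
#' (6-9) and 11.3% low (0-5).
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data frame with columns `sex` (factor male/female),
#'   `child_age_months`, `birth_weight_kg`, `maternal_education` (ordered
#'   factor), `ses_score` (integer) and `ses_category` (factor).
#' @export
generate_covariates <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed + 1L)
  sex <- factor(ifelse(stats::runif(n) < 0.527, "male", "female"),
                levels = c("male", "female"))
  age <- pmin(pmax(stats::rnorm(n, 43.9, 3.4), 36), 59)
  bw <- pmin(pmax(stats::rnorm(n, 3.1, 0.5), 1.5), 5.0)
  edu_levels <- c("none", "primary", "ordinary", "tertiary")
  edu <- factor(sample(edu_levels, n, replace = TRUE,
                       prob = c(0.197, 0.550, 0.200, 0.053)),
                levels = edu_levels, ordered = TRUE)
  cls <- sample(c("low", "moderate", "high"), n, replace = TRUE,
                prob = c(0.113, 0.206, 0.681))
  ses <- integer(n)
  ses[cls == "low"] <- sample(0:5, sum(cls == "low"), replace = TRUE)
  ses[cls == "moderate"] <- sample(6:9, sum(cls == "moderate"), replace = TRUE)
  ses[cls == "high"] <- sample(10:12, sum(cls == "high"), replace = TRUE)
  data.frame(
    sex = sex,
    child_age_months = age,
    birth_weight_kg = bw,
    maternal_education = edu,
    ses_score = as.integer(ses),
    ses_category = classify_ses(ses)
  )
}

# Numeric design used by the outcome generator: documented encoding of the
# covariate columns (female indicator, ordinal education level 0-3, raw
# age/weight/wealth score).
covariate_design <- function(covariates) {
  cbind(
    sex_female = as.numeric(covariates$sex == "female"),
    child_age_months = covariates$child_age_months,
    birth_weight_kg = covariates$birth_weight_kg,
    education_level = as.numeric(covariates$maternal_education) - 1,
    ses_score = as.numeric(covariates$ses_score)
  )
}

# Target means of the default covariate generator; covariate effects in a
# mixture_truth act on values centered at these, so the truth intercept
# controls the baseline log-odds directly.
default_covariate_centers <- function() {
  c(sex_female = 0.473, child_age_months = 43.9, birth_weight_kg = 3.1,
    education_level = 1.109, ses_score = 9.32)
}

#' Generative truth for a synthetic mixture outcome
#'
#' Holds the parameters of the logistic data-generating model on the
#' quantized-exposure scale: intercept `b0` (log-odds at score 0 for every
#' chemical and covariates at their centering values), per-chemical
#' coefficients `beta` (log-odds per quantile), covariate coefficients, and
#' the number of quantiles `q`. The joint effect is
#' `psi = sum(beta)`; directional weights are the per-sign-class
#' normalized coefficient shares.
#'
#' `beta` can be given directly, or constructed from `psi` and
#' non-negative `weights` summing to 1 (all coefficients then share the
#' sign of `psi`), or from `psi_pos`/`psi_neg` plus signed `weights` for a
#' mixed-direction truth (within each sign class the absolute weights must
#' sum to 1).
#'
#' @param intercept log-odds intercept `b0`.
#' @param beta named per-chemical log-odds coefficients, or NULL.
#' @param psi joint effect used with non-negative `weights`.
#' @param psi_pos,psi_neg directional joint effects used with signed
#'   `weights` (`psi_pos >= 0`, `psi_neg <= 0`).
#' @param weights named chemical weights (see Details above).
#' @param covariate_coef named covariate coefficients applied to the
#'   centered numeric covariate design (see [generate_covariates()]).
#' @param covariate_center named centering values; defaults to the
#'   generator's target means.
#' @param q number of quantiles the truth is defined on.
#' @return Object of class `"mixture_truth"` with elements `intercept`,
#'   `beta`, `psi`, `weights` (signed), `covariate_coef`,
#'   `covariate_center`, `q`.
#' @export
mixture_truth <- function(intercept, beta = NULL, psi = NULL,
                          psi_pos = NULL, psi_neg = NULL, weights = NULL,
                          covariate_coef = default_covariate_effects(),
                          covariate_center = NULL, q = 4L) {
  if (is.null(beta)) {
    if (is.null(weights)) stop("give either beta or psi + weights")
    if (is.null(names(weights))) stop("weights must be named by chemical")
    if (!is.null(psi_pos) || !is.null(psi_neg)) {
      psi_pos <- if (is.null(psi_pos)) 0 else psi_pos
      psi_neg <- if (is.null(psi_neg)) 0 else psi_neg
      if (psi_pos < 0 || psi_neg > 0) stop("need psi_pos >= 0 and psi_neg <= 0")
      wpos <- weights[weights > 0]; wneg <- weights[weights < 0]
      if (length(wpos) && abs(sum(wpos) - 1) > 1e-8) {
        stop("positive weights must sum to 1")
      }
      if (length(wneg) && abs(sum(abs(wneg)) - 1) > 1e-8) {
        stop("absolute negative weights must sum to 1")
      }
      beta <- ifelse(weights > 0, psi_pos * weights, psi_neg * abs(weights))
      names(beta) <- names(weights)
    } else {
      if (is.null(psi)) stop("give psi with weights")
      if (any(weights < 0)) {
        stop("signed weights need psi_pos/psi_neg; shares with psi must be >= 0")
      }
      if (abs(sum(weights) - 1) > 1e-8) stop("weight shares must sum to 1")
      beta <- psi * weights
    }
  }
  if (is.null(names(beta))) stop("beta must be named by chemical")
  if (is.null(covariate_center)) {
    covariate_center <- default_covariate_centers()[names(covariate_coef)]
    covariate_center[is.na(covariate_center)] <- 0
    names(covariate_center) <- names(covariate_coef)
  }
  out <- structure(list(intercept = intercept, beta = beta,
                        psi = sum(beta),
                        weights = truth_weights(beta),
                        covariate_coef = covariate_coef,
                        covariate_center = covariate_center,
                        q = as.integer(q)),
                   class = "mixture_truth")
  out
}

# Signed directional weights implied by a coefficient vector: within each
# sign class, beta_k / (class sum); magnitudes in a class sum to 1.
truth_weights <- function(beta) {
  w <- rep(NA_real_, length(beta))
  names(w) <- names(beta)
  pos <- beta > 0; neg <- beta < 0
  if (any(pos)) w[pos] <- beta[pos] / sum(beta[pos])
  if (any(neg)) w[neg] <- -beta[neg] / sum(beta[neg])  # negative magnitudes
  w[beta == 0] <- 0
  w
}

#' @export
print.mixture_truth <- function(x, ...) {
  cat("Mixture truth: psi =", signif(x$psi, 4), " (q =", x$q, ")\n")
  cat("  intercept (log-odds):", signif(x$intercept, 4), "\n")
  cat("  beta:", paste(names(x$beta), signif(x$beta, 4), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Default covariate effects of the synthetic outcome model
#'
#' Modest log-odds effects on the centered covariate design: female vs male
#' -0.5, +0.06 per month of age, -0.2 per kg birth weight, -0.25 per
#' education level, -0.07 per wealth-score point.
#'
#' @return named numeric vector.
#' @export
default_covariate_effects <- function() {
  c(sex_female = -0.5, child_age_months = 0.06, birth_weight_kg = -0.2,
    education_level = -0.25, ses_score = -0.07)
}

#' Default generative truths for the five outcome domains
#'
#' Study-shaped truths for language, gross motor, fine motor, social and
#' global impairment. Signed weights follow the adjusted mixture-model
#' weight columns of the source setting (e.g. language all-negative with
#' Pb dominant); the directional joint effects are the logs of the
#' directional partial-effect rows; the intercept is set so the realized
#' prevalence is near the observed domain prevalence (50.7, 16.2, 28.3,
#' 20.3, 23.9 percent).
#'
#' @param domain one of `"language"`, `"gross_motor"`, `"fine_motor"`,
#'   `"social"`, `"global"`.
#' @param q number of quantiles.
#' @return a [mixture_truth()] object.
#' @export
default_mixture_truth <- function(domain = c("language", "gross_motor",
                                             "fine_motor", "social",
                                             "global"),
                                  q = 4L) {
  domain <- match.arg(domain)
  # intercept = qlogis(prevalence) - mean_score * psi, mean score ~ 1.5
  mk <- function(prev, psi_pos, psi_neg, w) {
    mixture_truth(intercept = stats::qlogis(prev) - 1.5 * (psi_pos + psi_neg),
                  psi_pos = psi_pos, psi_neg = psi_neg, weights = w, q = q)
  }
  switch(domain,
    language = mk(0.283, 0, log(0.3296),
                  c(Pb = -0.610, As = -0.036, Cd = -0.131, Hg = -0.223)),
    gross_motor = mk(0.203, log(1.095), log(0.600),
                     c(Pb = -0.499, As = -0.142, Cd = 1, Hg = -0.359)),
    fine_motor = mk(0.239, log(1.182), log(0.735),
                    c(Pb = -0.459, As = -0.118, Cd = 1, Hg = -0.423)),
    social = mk(0.162, log(1.586), log(0.682),
                c(Pb = 0.395, As = -0.002, Cd = 0.605, Hg = -0.998)),
    global = mk(0.507, log(1.125), log(0.632),
                c(Pb = -0.593, As = -0.036, Cd = 1, Hg = -0.371))
  )
}

#' Simulate binary outcomes from a mixture truth
#'
#' Quantizes the exposures at `truth$q` (empirical-quantile scoring, the
#' same scoring the estimator applies), forms the linear predictor
#' `b0 + sum_j beta_j X_jq + (C - center) %*% covariate_coef`, and draws
#' Bernoulli outcomes with probability `plogis(eta)`. The Bernoulli draw
#' is the model's only noise; no additive residual exists on the latent
#' scale.
#'
#' @param exposures data frame of raw concentrations (one column per
#'   chemical in `names(truth$beta)`).
#' @param covariates covariate data frame from [generate_covariates()] (or
#'   with the same columns); may be NULL when the truth has no covariate
#'   effects.
#' @param truth a [mixture_truth()].
#' @param seed integer seed.
#' @return integer 0/1 vector with attribute `"prob"` (the generating
#'   probabilities).
#' @export
generate_outcomes <- function(exposures, covariates, truth, seed = 1L) {
  if (!inherits(truth, "mixture_truth")) stop("truth must be a mixture_truth")
  missing_chem <- setdiff(names(truth$beta), names(exposures))
  if (length(missing_chem)) {
    stop("exposure column(s) missing: ", paste(missing_chem, collapse = ", "))
  }
  qz <- quantize_exposures(exposures, names(truth$beta), truth$q)
  eta <- truth$intercept +
    as.matrix(qz$scores) %*% truth$beta
  if (length(truth$covariate_coef)) {
    if (is.null(covariates)) stop("truth names covariate effects but covariates is NULL")
    cd <- covariate_design(covariates)
    missing_cov <- setdiff(names(truth$covariate_coef), colnames(cd))
    if (length(missing_cov)) {
      stop("covariate(s) named in truth but absent: ",
           paste(missing_cov, collapse = ", "))
    }
    cc <- cd[, names(truth$covariate_coef), drop = FALSE]
    cc <- sweep(cc, 2, truth$covariate_center[names(truth$covariate_coef)])
    eta <- eta + cc %*% truth$covariate_coef
  }
  p <- stats::plogis(drop(eta))
  set.seed(seed + 2L)
  y <- stats::rbinom(length(p), 1L, p)
  attr(y, "prob") <- p
  y
}

#' Generate a complete synthetic cohort table
#'
#' Composes [generate_exposures()], [generate_covariates()] and
#' [generate_outcomes()] into one subject-level table. Identical arguments
#' and seed give an identical table.
#'
#' @param n number of subjects.
#' @param profile an [exposure_profile()].
#' @param truths named list of [mixture_truth()] objects; one binary
#'   outcome column `impaired_<name>` is generated per entry.
#' @param seed integer seed.
#' @return data frame: `id`, exposure columns, covariates, outcome columns.
#' @export
generate_cohort <- function(n, profile = default_exposure_profile(),
                            truths = list(language = default_mixture_truth("language")),
                            seed = 1L) {
  expo <- generate_exposures(n, profile, seed)
  cov <- generate_covariates(n, seed)
  out <- cbind(id = seq_len(n), expo, cov)
  for (i in seq_along(truths)) {
    y <- generate_outcomes(expo, cov, truths[[i]], seed + 1000L * i)
    out[[paste0("impaired_", names(truths)[i])]] <- as.integer(y)
  }
  out
}

#' True marginal prevalence ratio implied by a mixture truth
#'
#' The estimand of the marginal-structural-model step: for each joint
#' quantile level `s`, the standardized outcome probability is
#' `E[plogis(b0 + s * psi + covariate terms)]` over the covariate
#' distribution; the true marginal log-PR is the least-squares slope of
#' `log p_s` on `s`, and the PR is its exponential. Computed on a large
#' reference covariate draw (deterministic given `n_ref` and `seed`).
#'
#' This differs from `exp(psi)` whenever the outcome is non-rare: `psi` is
#' a conditional log-odds, the PR a marginal log-risk slope.
#'
#' @param truth a [mixture_truth()].
#' @param covariates optional covariate data frame to standardize over;
#'   when NULL a reference draw of `n_ref` subjects is generated.
#' @param n_ref reference-draw size.
#' @param seed seed for the reference draw.
#' @return list with `pr`, `psi_marginal`, and `curve` (data frame of
#'   level and standardized probability).
#' @export
true_marginal_pr <- function(truth, covariates = NULL, n_ref = 2e5,
                             seed = 1L) {
  if (is.null(covariates) && length(truth$covariate_coef)) {
    covariates <- generate_covariates(n_ref, seed)
  }
  covterm <- 0
  if (length(truth$covariate_coef)) {
    cd <- covariate_design(covariates)[, names(truth$covariate_coef),
                                       drop = FALSE]
    cd <- sweep(cd, 2, truth$covariate_center[names(truth$covariate_coef)])
    covterm <- drop(cd %*% truth$covariate_coef)
  }
  s <- 0:(truth$q - 1L)
  p_s <- vapply(s, function(lev) {
    mean(stats::plogis(truth$intercept + lev * truth$psi + covterm))
  }, numeric(1))
  slope <- stats::cov(s, log(p_s)) / stats::var(s)
  list(pr = exp(slope), psi_marginal = slope,
       curve = data.frame(level = s, std_prob = p_s))
}
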