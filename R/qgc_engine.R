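#' Build the quantile g-computation design for a cohort
#'
#' Complete-case filters the columns in use, scores each chemical into
#' `q` quantile categories, and assembles the logistic design matrix
#' (intercept, one integer score column per chemical, covariate columns
#' with factors expanded).
#'
#' @param data cohort data frame.
#' @param outcome name of the binary outcome column.
#' @param chemicals chemical column names forming the mixture.
#' @param covariates covariate column names (NULL for the crude model).
#' @param q number of quantiles.
#' @return list with `x` (design matrix), `y` (0/1 vector), `q`,
#'   `chemicals`, `cutpoints`, `n`, `n_dropped`.
#' @export
qgc_design <- function(data, outcome, chemicals, covariates = NULL,
                       q = 4L) {
  if (!outcome %in% names(data)) {
    stop("outcome column not in cohort: ", outcome)
  }
  used <- c(outcome, chemicals, covariates)
  dd <- complete_cases(data, used)
  y <- dd[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1: ", outcome)
  qz <- quantize_exposures(dd, chemicals, q)
  mf <- qz$scores
  if (length(covariates)) mf <- cbind(mf, dd[, covariates, drop = FALSE])
  x <- stats::model.matrix(~ ., mf)
  list(x = x, y = as.integer(y), q = as.integer(q), chemicals = chemicals,
       cutpoints = qz$cutpoints, n = nrow(dd),
       n_dropped = attr(dd, "n_dropped"))
}

#' Maximum-likelihood logistic fit on a design matrix
#'
#' Thin wrapper around the iteratively reweighted least squares fitter of
#' a binomial GLM (`stats::glm.fit`). Aliased (rank-deficient) columns are
#' detected beforehand and dropped with a record. The fit is flagged
#' non-converged when IRLS fails to converge or a coefficient runs away
#' (|coef| >= 15 on the log-odds scale, the practical signature of
#' separation); non-converged fits are excluded downstream.
#'
#' @param x design matrix including the intercept column.
#' @param y binary 0/1 outcome vector.
#' @return object of class `"qgc_glm"`: `coefficients` (named; aliased
#'   columns removed), `deviance`, `null_deviance`, `aic`, `converged`,
#'   `dropped` (aliased column names), `n`.
#' @export
fit_glm_logistic <- function(x, y) {
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  qrx <- qr(x)
  dropped <- character(0)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(x)[-keep]
    x <- x[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  coefs <- fit$coefficients
  converged <- isTRUE(fit$converged) && all(is.finite(coefs)) &&
    max(abs(coefs)) < 15
  structure(list(coefficients = coefs,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 aic = fit$aic,
                 converged = converged,
                 dropped = dropped,
                 n = length(y)),
            class = "qgc_glm")
}

#' @export
print.qgc_glm <- function(x, ...) {
  cat("Logistic fit (n = ", x$n, "): deviance ", signif(x$deviance, 6),
      ", AIC ", signif(x$aic, 6),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

qgc_predict <- function(fit, x) {
  stats::plogis(drop(x[, names(fit$coefficients), drop = FALSE] %*%
                       fit$coefficients))
}

#' Joint effect and directional chemical weights from a fitted model
#'
#' The conditional joint effect is `psi = sum(beta_j)` over the mixture
#' members; the directional partial effects are the sums of the positive
#' and of the negative coefficients (reported exponentiated); each
#' chemical's weight is its coefficient divided by its sign-class sum, so
#' the weights within each direction sum to 1 in magnitude. Negative-class
#' weights are stored as negative numbers so the sign encodes direction.
#'
#' @param fit a [fit_glm_logistic()] result (must have converged).
#' @param members chemical coefficient names forming the mixture.
#' @return object of class `"qgc_psi"`: `psi`, `partial_pos`,
#'   `partial_neg` (log scale), `or_partial_pos`, `or_partial_neg`,
#'   `members_pos`, `members_neg`, `weights` (signed, named), `defined`.
#' @export
psi_and_weights <- function(fit, members) {
  if (!fit$converged) stop("fit did not converge; refusing to decompose")
  beta <- fit$coefficients[members]
  if (anyNA(beta)) {
    stop("mixture member(s) absent from fit: ",
         paste(members[is.na(beta)], collapse = ", "))
  }
  psi <- sum(beta)
  pos <- beta > 0; neg <- beta < 0
  defined <- any(pos) || any(neg)
  if (!defined) {
    warning("all mixture coefficients are exactly zero; weights undefined")
  }
  w <- truth_weights(beta)
  if (!defined) w[] <- NA_real_
  structure(list(
    psi = psi,
    partial_pos = sum(beta[pos]),
    partial_neg = sum(beta[neg]),
    or_partial_pos = exp(sum(beta[pos])),
    or_partial_neg = exp(sum(beta[neg])),
    members_pos = members[pos],
    members_neg = members[neg],
    weights = w,
    defined = defined
  ), class = "qgc_psi")
}

#' G-computation standardization and the marginal structural model
#'
#' For each joint quantile level `s` in `0:(q-1)`, every mixture member's
#' score column is set to `s` for all subjects and the fitted outcome
#' probabilities are averaged (marginal standardization). The marginal
#' joint effect is the least-squares slope of `log(p_s)` on `s` (the
#' log-linear marginal structural model); its anti-logarithm is the
#' prevalence ratio per simultaneous one-quantile increase.
#'
#' @param fit a converged [fit_glm_logistic()] result.
#' @param x the design matrix the model was fit on.
#' @param members names of the mixture score columns in `x`.
#' @param q number of quantile levels.
#' @return object of class `"msm_curve"`: `curve` (data frame `level`,
#'   `std_prob`, `msm_fit`), `psi_marginal`, `intercept`, `pr`.
#' @export
msm_pr <- function(fit, x, members, q) {
  if (!fit$converged) stop("fit did not converge; refusing to standardize")
  members <- intersect(members, colnames(x))
  s <- 0:(q - 1L)
  p_s <- vapply(s, function(lev) {
    xs <- x
    xs[, members] <- lev
    mean(qgc_predict(fit, xs))
  }, numeric(1))
  if (any(p_s <= 0) || any(p_s >= 1)) {
    stop("standardized probability at the boundary; log-RR undefined")
  }
  lp <- log(p_s)
  slope <- stats::cov(s, lp) / stats::var(s)
  inter <- mean(lp) - slope * mean(s)
  structure(list(
    curve = data.frame(level = s, std_prob = p_s,
                       msm_fit = exp(inter + slope * s)),
    psi_marginal = slope, intercept = inter, pr = exp(slope)
  ), class = "msm_curve")
}

#' @export
print.msm_curve <- function(x, ...) {
  cat("MSM over joint quantile levels: PR per quantile =",
      signif(x$pr, 4), "\n")
  print(transform(x$curve, std_prob = signif(std_prob, 4),
                  msm_fit = signif(msm_fit, 4)), row.names = FALSE)
  invisible(x)
}

# one complete estimation pass on a cohort: design -> fit -> psi -> msm
qgc_fit_once <- function(data, outcome, chemicals, covariates, q) {
  des <- qgc_design(data, outcome, chemicals, covariates, q)
  fit <- fit_glm_logistic(des$x, des$y)
  if (!fit$converged) return(list(converged = FALSE, fit = fit, design = des))
  pw <- psi_and_weights(fit, chemicals)
  msm <- msm_pr(fit, des$x, chemicals, q)
  list(converged = TRUE, fit = fit, design = des, pw = pw, msm = msm)
}

#' Percentile bootstrap for the mixture prevalence ratio
#'
#' Resamples subjects with replacement and refits the whole pipeline
#' (re-quantization included) on each replicate. Non-converged replicates
#' are dropped and counted; the interval is flagged unreliable when more
#' than 20% fail. Identical seeds give identical intervals.
#'
#' @param data cohort data frame.
#' @param outcome,chemicals,covariates,q model specification as in
#'   [fit_mixture_model()].
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `pr_ci` (percentile interval), `psi_ci` (conditional
#'   scale), `boot_pr` (replicate PRs), `weight_sd` (per-chemical SD of
#'   the signed weights across replicates), `n_fail`, `unreliable`.
#' @export
bootstrap_ci <- function(data, outcome, chemicals, covariates = NULL,
                         q = 4L, B = 1000L, seed = 1L, conf = 0.95) {
  if (B < 2L) stop("B must be >= 2")
  n <- nrow(data)
  set.seed(seed + 10L)
  prs <- psis <- rep(NA_real_, B)
  wts <- matrix(NA_real_, B, length(chemicals),
                dimnames = list(NULL, chemicals))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      qgc_fit_once(data[idx, , drop = FALSE], outcome, chemicals,
                   covariates, q),
      error = function(e) list(converged = FALSE))
    if (!rep_fit$converged) next
    prs[b] <- rep_fit$msm$pr
    psis[b] <- rep_fit$pw$psi
    wts[b, ] <- rep_fit$pw$weights[chemicals]
  }
  ok <- !is.na(prs)
  n_fail <- sum(!ok)
  if (!any(ok)) stop("no bootstrap replicate converged")
  alpha <- 1 - conf
  probs <- c(alpha / 2, 1 - alpha / 2)
  list(
    pr_ci = stats::quantile(prs[ok], probs, type = 7, names = FALSE),
    psi_ci = stats::quantile(psis[ok], probs, type = 7, names = FALSE),
    boot_pr = prs,
    weight_sd = apply(wts[ok, , drop = FALSE], 2, stats::sd),
    n_fail = n_fail,
    unreliable = n_fail > 0.2 * B
  )
}

#' Fit the full quantile g-computation mixture model
#'
#' Orchestrates the pipeline: quantile scoring, logistic fit, joint-effect
#' and directional-weight decomposition, g-computation standardization
#' with the log-linear marginal structural model, and the percentile
#' bootstrap interval for the prevalence ratio.
#'
#' @param data cohort data frame.
#' @param outcome binary outcome column name.
#' @param chemicals mixture member column names.
#' @param covariates covariate column names for the adjusted model; NULL
#'   gives the crude model. The conventional adjusted set is child sex,
#'   birth weight, maternal education, child age and household SES.
#' @param q number of quantiles (default 4, i.e. per-quartile effects).
#' @param B bootstrap resamples (default 1000); set `B = 0` to skip the
#'   interval.
#' @param seed integer seed controlling all resampling.
#' @param conf confidence level.
#' @param ci_type `"percentile"` (default) or `"normal"` (log-scale normal
#'   approximation using the bootstrap SD).
#' @return object of class `"mixture_fit"`; see the fields in the
#'   package vignette. `pr` is the prevalence ratio per simultaneous
#'   one-quantile increase in all mixture members.
#' @export
fit_mixture_model <- function(data, outcome,
                              chemicals = c("Pb", "Hg", "Cd", "As"),
                              covariates = NULL, q = 4L, B = 1000L,
                              seed = 1L, conf = 0.95,
                              ci_type = c("percentile", "normal")) {
  ci_type <- match.arg(ci_type)
  main <- qgc_fit_once(data, outcome, chemicals, covariates, q)
  if (!main$converged) {
    stop("mixture model did not converge on the full cohort")
  }
  # marginal-scale directional partials: standardize varying only the
  # members of one sign class
  marg_partial <- function(members) {
    if (!length(members)) return(NA_real_)
    exp(msm_pr(main$fit, main$design$x, members, q)$psi_marginal)
  }
  boot <- NULL
  pr_ci <- c(NA_real_, NA_real_)
  if (B >= 2L) {
    boot <- bootstrap_ci(data, outcome, chemicals, covariates, q, B, seed,
                         conf)
    pr_ci <- if (ci_type == "percentile") boot$pr_ci else {
      lp <- log(main$msm$pr)
      sdl <- stats::sd(log(boot$boot_pr[!is.na(boot$boot_pr)]))
      zq <- stats::qnorm(1 - (1 - conf) / 2)
      exp(c(lp - zq * sdl, lp + zq * sdl))
    }
  }
  structure(list(
    outcome = outcome, chemicals = chemicals, covariates = covariates,
    q = as.integer(q), B = as.integer(B), seed = as.integer(seed),
    conf = conf, ci_type = ci_type,
    n = main$design$n, n_dropped = main$design$n_dropped,
    glm = main$fit,
    psi_conditional = main$pw$psi,
    or_conditional = exp(main$pw$psi),
    partial_pos = main$pw$or_partial_pos,
    partial_neg = main$pw$or_partial_neg,
    partial_pos_marginal = marg_partial(main$pw$members_pos),
    partial_neg_marginal = marg_partial(main$pw$members_neg),
    members_pos = main$pw$members_pos,
    members_neg = main$pw$members_neg,
    weights = main$pw$weights,
    weights_defined = main$pw$defined,
    psi_marginal = main$msm$psi_marginal,
    pr = main$msm$pr,
    pr_ci = as.numeric(pr_ci),
    msm_curve = main$msm$curve,
    boot_n_fail = if (is.null(boot)) NA_integer_ else boot$n_fail,
    boot_unreliable = if (is.null(boot)) NA else boot$unreliable,
    weight_sd = if (is.null(boot)) NULL else boot$weight_sd
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, digits = 4, ...) {
  cat("Quantile g-computation mixture fit --", x$outcome, "\n")
  cat("  mixture:", paste(x$chemicals, collapse = " + "),
      " (q =", x$q, ", n =", x$n, ")\n")
  if (length(x$covariates)) {
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  } else cat("  unadjusted (crude)\n")
  ci <- if (all(is.finite(x$pr_ci))) {
    sprintf(" (%s CI: %.4g, %.4g)", paste0(100 * x$conf, "%"),
            x$pr_ci[1], x$pr_ci[2])
  } else ""
  cat(sprintf("  psi1: PR = %.4g%s per one-quantile increase in all members\n",
              x$pr, ci))
  cat(sprintf("  conditional psi = %.4g (OR %.4g)\n",
              x$psi_conditional, x$or_conditional))
  if (length(x$members_pos)) {
    cat(sprintf("  positive partial: %s = %.4g\n",
                paste(x$members_pos, collapse = " + "), x$partial_pos))
  }
  if (length(x$members_neg)) {
    cat(sprintf("  negative partial: %s = %.4g\n",
                paste(x$members_neg, collapse = " + "), x$partial_neg))
  }
  cat("  weights (sign = direction):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' Chemical-specific comparison model
#'
#' One chemical entered at a time, adjusted for the covariates: exactly
#' the mixture pipeline with a single-member mixture, so the reported PR
#' is per one-quantile increase in that chemical alone.
#'
#' @param chemical single chemical column name.
#' @inheritParams fit_mixture_model
#' @return a `"mixture_fit"` object with `d = 1`.
#' @export
chemical_specific_fit <- function(chemical, data, outcome,
                                  covariates = NULL, q = 4L, B = 1000L,
                                  seed = 1L, conf = 0.95,
                                  ci_type = c("percentile", "normal")) {
  if (length(chemical) != 1L) stop("chemical must be a single name")
  fit_mixture_model(data, outcome, chemicals = chemical,
                    covariates = covariates, q = q, B = B, seed = seed,
                    conf = conf, ci_type = match.arg(ci_type))
}

#' Forward-backward stepwise covariate selection
#'
#' Greedy alternating add/drop search over candidate covariates for a
#' logistic model, keeping any `fixed` terms (e.g. the mixture score
#' columns) in every model. At each step the single add or drop move that
#' most improves the criterion is taken; the search stops when no move
#' improves it. Ties are resolved deterministically by candidate order
#' (adds considered before drops). The criterion is AIC (default) or
#' deviance plus a stated penalty per parameter.
#'
#' @param data data frame.
#' @param outcome binary outcome column name.
#' @param candidates character vector of candidate covariate terms.
#' @param fixed terms always included (NULL for intercept-only base).
#' @param criterion `"AIC"` or `"deviance"`.
#' @param deviance_penalty penalty per model parameter when
#'   `criterion = "deviance"` (2 reproduces AIC).
#' @return list with `selected` (retained candidates, in selection
#'   order), `log` (one row per step: action, variable, criterion value,
#'   AIC, deviance, number of parameters), and `final` (the `stats::glm`
#'   fit of the selected model).
#' @export
stepwise_select <- function(data, outcome, candidates, fixed = NULL,
                            criterion = c("AIC", "deviance"),
                            deviance_penalty = 2) {
  criterion <- match.arg(criterion)
  if (!length(candidates)) stop("need at least one candidate")
  fit_set <- function(terms) {
    rhs <- if (length(terms)) terms else "1"
    stats::glm(stats::reformulate(rhs, response = outcome),
               family = stats::binomial(), data = data)
  }
  crit <- function(fit) {
    if (criterion == "AIC") stats::AIC(fit)
    else stats::deviance(fit) + deviance_penalty * length(stats::coef(fit))
  }
  selected <- character(0)
  cur_fit <- fit_set(fixed)
  cur <- crit(cur_fit)
  log <- data.frame(step = 0L, action = "start", variable = NA_character_,
                    criterion = cur, aic = stats::AIC(cur_fit),
                    deviance = stats::deviance(cur_fit),
                    n_par = length(stats::coef(cur_fit)))
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    moves <- list()
    for (v in setdiff(candidates, selected)) {
      moves[[length(moves) + 1L]] <- list(action = "add", variable = v,
                                          set = c(selected, v))
    }
    for (v in intersect(candidates, selected)) {
      moves[[length(moves) + 1L]] <- list(action = "drop", variable = v,
                                          set = setdiff(selected, v))
    }
    if (!length(moves)) break
    vals <- vapply(moves, function(m) crit(fit_set(c(fixed, m$set))),
                   numeric(1))
    best <- which(vals <= min(vals) + 1e-8)[1]  # first move in order wins ties
    if (vals[best] >= cur - 1e-8) break
    selected <- moves[[best]]$set
    cur_fit <- fit_set(c(fixed, selected))
    cur <- crit(cur_fit)
    log <- rbind(log, data.frame(
      step = step_i, action = moves[[best]]$action,
      variable = moves[[best]]$variable, criterion = cur,
      aic = stats::AIC(cur_fit), deviance = stats::deviance(cur_fit),
      n_par = length(stats::coef(cur_fit))))
    if (step_i > 10L * length(candidates)) break  # safety
  }
  list(selected = selected, log = log, final = cur_fit,
       criterion = criterion)
}
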