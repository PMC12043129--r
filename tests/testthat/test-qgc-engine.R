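# fabricate a converged fit object with known coefficients
fake_fit <- function(coefs) {
  structure(list(coefficients = coefs, deviance = 0, null_deviance = 1,
                 aic = 0, converged = TRUE, dropped = character(0),
                 n = 100L),
            class = "qgc_glm")
}

test_that("logistic fit recovers the closed-form log odds ratio of a 2x2 table", {
  # x = 0: 30 events / 70 non-events; x = 1: 55 / 45
  y <- c(rep(1, 30), rep(0, 70), rep(1, 55), rep(0, 45))
  x <- cbind(`(Intercept)` = 1, z = c(rep(0, 100), rep(1, 100)))
  fit <- fit_glm_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["z"]),
               log((55 / 45) / (30 / 70)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(30 / 70),
               tolerance = 1e-6)
  expect_lte(fit$deviance, fit$null_deviance)
})

test_that("fit matches stats::glm and null slopes stay within 3 SE of zero", {
  set.seed(301)
  n <- 1e4
  df <- data.frame(a = stats::rnorm(n), b = stats::rbinom(n, 1, 0.4),
                   y = stats::rbinom(n, 1, 0.3))
  ref <- stats::glm(y ~ a + b, family = stats::binomial(), data = df)
  fit <- fit_glm_logistic(stats::model.matrix(~ a + b, df), df$y)
  expect_equal(fit$coefficients, stats::coef(ref), tolerance = 1e-8)
  expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-8)
  se <- summary(ref)$coefficients[c("a", "b"), "Std. Error"]
  expect_true(all(abs(fit$coefficients[c("a", "b")]) < 3 * se))
})

test_that("aliased design columns are dropped and logged", {
  set.seed(302)
  x <- cbind(`(Intercept)` = 1, a = stats::rnorm(50), b = 0)
  x <- cbind(x, a2 = x[, "a"])  # duplicate column
  fit <- fit_glm_logistic(x, stats::rbinom(50, 1, 0.5))
  expect_setequal(fit$dropped, c("b", "a2"))
  expect_false(anyNA(fit$coefficients))
})

test_that("psi and directional weights follow the sign-partition arithmetic", {
  f1 <- fake_fit(c(`(Intercept)` = -1, Pb = 0.5))
  pw1 <- psi_and_weights(f1, "Pb")
  expect_equal(pw1$psi, 0.5)
  expect_equal(unname(pw1$weights["Pb"]), 1)

  f2 <- fake_fit(c(`(Intercept)` = 0, A = 0.2, B = -0.3, C = 0.1))
  pw2 <- psi_and_weights(f2, c("A", "B", "C"))
  expect_equal(pw2$psi, 0, tolerance = 1e-12)
  expect_equal(unname(pw2$weights[c("A", "C")]), c(2 / 3, 1 / 3))
  expect_equal(unname(pw2$weights["B"]), -1)
  expect_equal(pw2$or_partial_pos, exp(0.3))
  expect_equal(pw2$or_partial_neg, exp(-0.3))

  f0 <- fake_fit(c(`(Intercept)` = 0, A = 0, B = 0))
  expect_warning(pw0 <- psi_and_weights(f0, c("A", "B")), "undefined")
  expect_equal(pw0$psi, 0)
  expect_true(all(is.na(pw0$weights)))
})

test_that("weight sums are 1 per sign class on every converged fit", {
  for (s in 1:6) {
    co <- small_cohort(n = 400, psi = -0.25, seed = 300 + s)
    f <- fit_mixture_model(co, "impaired_y", covariates = adjusted_covariates,
                           B = 0, seed = s)
    w <- f$weights
    if (any(w > 0)) expect_equal(sum(w[w > 0]), 1, tolerance = 1e-12)
    if (any(w < 0)) expect_equal(sum(abs(w[w < 0])), 1, tolerance = 1e-12)
    expect_equal(f$psi_conditional, log(f$partial_pos) + log(f$partial_neg),
                 tolerance = 1e-12)
  }
})

test_that("g-computation standardization equals an exhaustive subject loop", {
  co <- small_cohort(n = 50, seed = 311)
  des <- qgc_design(co, "impaired_y", c("Pb", "Hg", "Cd", "As"),
                    adjusted_covariates, q = 4)
  fit <- fit_glm_logistic(des$x, des$y)
  msm <- msm_pr(fit, des$x, c("Pb", "Hg", "Cd", "As"), 4)
  cf <- fit$coefficients
  for (s in 0:3) {
    acc <- 0
    for (i in 1:50) {
      row <- des$x[i, names(cf)]
      row[c("Pb", "Hg", "Cd", "As")] <- s
      acc <- acc + 1 / (1 + exp(-sum(row * cf)))
    }
    expect_equal(msm$curve$std_prob[s + 1], acc / 50, tolerance = 1e-12)
  }
  # slope recomputed longhand from the standardized probabilities
  lp <- log(msm$curve$std_prob)
  sbar <- mean(0:3); lbar <- mean(lp)
  slope <- sum((0:3 - sbar) * (lp - lbar)) / sum((0:3 - sbar)^2)
  expect_equal(msm$psi_marginal, slope, tolerance = 1e-12)
  expect_equal(msm$pr, exp(slope))
})

test_that("a null mixture gives a flat curve and PR of exactly 1", {
  co <- small_cohort(n = 80, seed = 312)
  des <- qgc_design(co, "impaired_y", c("Pb", "Hg", "Cd", "As"),
                    adjusted_covariates, q = 4)
  fit <- fit_glm_logistic(des$x, des$y)
  fit$coefficients[c("Pb", "Hg", "Cd", "As")] <- 0
  msm <- msm_pr(fit, des$x, c("Pb", "Hg", "Cd", "As"), 4)
  expect_equal(diff(range(msm$curve$std_prob)), 0, tolerance = 1e-14)
  expect_equal(msm$pr, 1, tolerance = 1e-12)
})

test_that("the bootstrap is seed-deterministic and degrades gracefully", {
  co <- small_cohort(n = 250, seed = 321)
  b1 <- bootstrap_ci(co, "impaired_y", c("Pb", "Hg", "Cd", "As"),
                     B = 60, seed = 9)
  b2 <- bootstrap_ci(co, "impaired_y", c("Pb", "Hg", "Cd", "As"),
                     B = 60, seed = 9)
  expect_identical(b1$pr_ci, b2$pr_ci)
  expect_identical(b1$boot_pr, b2$boot_pr)
  b3 <- bootstrap_ci(co, "impaired_y", c("Pb", "Hg", "Cd", "As"),
                     B = 60, seed = 10)
  expect_false(identical(b1$pr_ci, b3$pr_ci))
  expect_error(bootstrap_ci(co, "impaired_y", "Pb", B = 1), "B must be")
})

test_that("interval width shrinks with sample size", {
  widths <- sapply(1:10, function(s) {
    co_small <- generate_cohort(500, truths = list(y = language_truth(-0.2)),
                                seed = 400 + s)
    co_big <- generate_cohort(2000, truths = list(y = language_truth(-0.2)),
                              seed = 400 + s)
    f_small <- fit_mixture_model(co_small, "impaired_y", B = 80,
                                 seed = 500 + s)
    f_big <- fit_mixture_model(co_big, "impaired_y", B = 80,
                               seed = 500 + s)
    c(small = diff(f_small$pr_ci), big = diff(f_big$pr_ci))
  })
  expect_lt(stats::median(widths["big", ]), stats::median(widths["small", ]))
})

test_that("a d = 1 mixture fit and the chemical-specific fit are identical", {
  co <- small_cohort(n = 300, seed = 331)
  fm <- fit_mixture_model(co, "impaired_y", chemicals = "Hg",
                          covariates = adjusted_covariates, B = 40, seed = 3)
  fs <- chemical_specific_fit("Hg", co, "impaired_y",
                              covariates = adjusted_covariates, B = 40,
                              seed = 3)
  expect_equal(fm[setdiff(names(fm), "chemicals")],
               fs[setdiff(names(fs), "chemicals")])
  expect_identical(fm$pr, fs$pr)
  expect_identical(fm$pr_ci, fs$pr_ci)
})

test_that("marginal and conditional joint effects agree in sign across seeds", {
  signs_ok <- vapply(1:20, function(s) {
    co <- generate_cohort(2000, truths = list(y = language_truth(-0.4)),
                          seed = 600 + s)
    f <- fit_mixture_model(co, "impaired_y", B = 0, seed = s)
    sign(f$psi_marginal) == sign(f$psi_conditional)
  }, logical(1))
  expect_true(all(signs_ok))
})

test_that("permuting the outcome centers the PR at 1", {
  co <- generate_cohort(1500, truths = list(y = language_truth(-0.3)),
                        seed = 641)
  set.seed(642)
  prs <- replicate(20, {
    co2 <- co
    co2$impaired_y <- sample(co2$impaired_y)
    fit_mixture_model(co2, "impaired_y", B = 0, seed = 1)$pr
  })
  expect_lt(abs(log(stats::median(prs))), 0.08)
})

test_that("stepwise selection keeps planted signal, drops pure noise, and is locally optimal", {
  set.seed(351)
  n <- 2000
  df <- data.frame(signal = stats::rnorm(n), n1 = stats::rnorm(n),
                   n2 = stats::rnorm(n), n3 = stats::rnorm(n))
  df$y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.8 * df$signal))
  sel <- stepwise_select(df, "y", c("signal", "n1", "n2", "n3"))
  expect_true("signal" %in% sel$selected)
  expect_equal(sel$log$action[2], "add")

  # no single add or drop from the selected set improves the AIC
  # (independent refits through stats::glm + AIC)
  cand <- c("signal", "n1", "n2", "n3")
  final_aic <- stats::AIC(sel$final)
  for (v in setdiff(cand, sel$selected)) {
    alt <- stats::glm(stats::reformulate(c(sel$selected, v), "y"),
                      stats::binomial(), data = df)
    expect_gte(stats::AIC(alt), final_aic - 1e-8)
  }
  for (v in sel$selected) {
    rhs <- setdiff(sel$selected, v)
    alt <- stats::glm(stats::reformulate(if (length(rhs)) rhs else "1", "y"),
                      stats::binomial(), data = df)
    expect_gte(stats::AIC(alt), final_aic - 1e-8)
  }
})

test_that("stepwise retains nothing when no candidate improves the criterion", {
  # candidates balanced so their in-sample association with y is exactly
  # zero: each add costs 2 AIC points and must be refused
  y <- rep(c(0L, 1L), 150)
  df <- data.frame(y = y,
                   n1 = rep(c(0, 0, 1, 1), 75),
                   n2 = rep(c(0, 1, 1, 0), 75))
  sel <- stepwise_select(df, "y", c("n1", "n2"))
  expect_length(sel$selected, 0)
  expect_equal(nrow(sel$log), 1L)  # only the start row
})

test_that("deviance criterion with penalty 2 reproduces the AIC path", {
  set.seed(353)
  df <- data.frame(a = stats::rnorm(500), b = stats::rnorm(500))
  df$y <- stats::rbinom(500, 1, stats::plogis(0.6 * df$a))
  s1 <- stepwise_select(df, "y", c("a", "b"), criterion = "AIC")
  s2 <- stepwise_select(df, "y", c("a", "b"), criterion = "deviance",
                        deviance_penalty = 2)
  expect_identical(s1$selected, s2$selected)
})

test_that("the orchestrated fit propagates contract violations", {
  co <- small_cohort(n = 100, seed = 361)
  expect_error(fit_mixture_model(co, "nope"), "outcome column")
  co$bad <- co$Pb  # continuous, not binary
  expect_error(fit_mixture_model(co, "bad"), "binary")
})
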