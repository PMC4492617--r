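test_that("the intercept-only fit recovers the logit of prevalence", {
  y <- c(rep(1, 31), rep(0, 62))  # 31 events of 93
  fit <- fit_logistic(NULL, y)
  expect_equal(fit$beta0, log(31 / 62), tolerance = 1e-8)
  expect_equal(round(fit$beta0, 3), -0.693)
  expect_equal(fit$log_likelihood, fit$null_log_likelihood, tolerance = 1e-8)
  expect_equal(fit$null_log_likelihood,
               31 * log(31 / 93) + 62 * log(62 / 93), tolerance = 1e-10)
})

test_that("coefficients, covariance and likelihood match a hand-written
           Newton-Raphson oracle", {
  prob <- random_problem(150, 4, seed = 31, beta = c(1, -0.6, 0, 0.4),
                         intercept = -0.5)
  fit <- fit_logistic(prob$x, prob$y)
  oracle <- newton_logistic(prob$x, prob$y)
  expect_equal(unname(fit$coefficients), unname(oracle$beta),
               tolerance = 1e-6)
  expect_equal(unname(fit$covariance), unname(oracle$vcov), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, oracle$loglik, tolerance = 1e-8)
  expect_gte(fit$log_likelihood, fit$null_log_likelihood)
  # covariance is symmetric positive definite
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # score equations hold at the optimum, including the intercept
  p <- ntcp_predict(fit, prob$x)
  expect_lt(max(abs(crossprod(cbind(1, prob$x), prob$y - p))), 1e-6)
})

test_that("separation and degenerate inputs raise dedicated errors", {
  x <- matrix(c(1:10), ncol = 1, dimnames = list(NULL, "sep"))
  y <- as.numeric(1:10 > 5)  # perfectly separated
  expect_error(fit_logistic(x, y), class = "srp_separation_error")
  xz <- cbind(x, const = 1)
  expect_error(fit_logistic(xz, rep(c(0, 1), 5)), "zero-variance")
  expect_error(fit_logistic(matrix(rnorm(4), 2, 2), c(0, 1)),
               "more observations")
})

test_that("odds ratios are exp(beta) with Wald intervals around them", {
  prob <- random_problem(200, 3, seed = 32, beta = c(0.8, -0.4, 0))
  fit <- fit_logistic(prob$x, prob$y)
  tab <- odds_ratios(fit)
  expect_equal(tab$or, exp(tab$beta), tolerance = 1e-12)
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
  # CI symmetric about the estimate on the log scale
  expect_equal(log(tab$ci_high) - log(tab$or), log(tab$or) - log(tab$ci_low),
               tolerance = 1e-10)
})

test_that("null Wald p-values are approximately uniform", {
  pvals <- vapply(1:200, function(s) {
    prob <- random_problem(120, 2, seed = 1000 + s,
                           beta = c(0.9, 0), intercept = -0.4)
    odds_ratios(fit_logistic(prob$x, prob$y))$p[3]  # the null column
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("NTCP prediction reproduces the published linear predictor by
           direct arithmetic", {
  model <- reference_srp_model()
  values <- c("IV20" = 40.99, "E(1)" = 0, "E(2)" = 1, "Age" = 55,
              "BMI" = 24.6, "T(1)" = 1, "T(2)" = 0)
  s_hand <- -6.868 + 40.99 * 0.183 + (-1.164) + 55 * 0.045 +
    24.6 * (-0.093) + (-0.904)
  expect_equal(ntcp_predict(model, values), plogis(s_hand),
               tolerance = 1e-12)
  # midpoint and monotone limits
  expect_equal(unname(ntcp_predict(list(beta0 = 0, betas = c(x = 1)),
                                   c(x = 0))), 0.5)
  probs <- ntcp_predict(list(beta0 = 0, betas = c(x = 1)),
                        matrix(seq(-30, -5, by = 5), ncol = 1,
                               dimnames = list(NULL, "x")))
  expect_true(all(diff(probs) > 0))
  expect_lt(probs[1], 1e-10)
  expect_error(ntcp_predict(model, values[-1]), "IV20")
})

test_that("dose-response curves invert exactly and reject flat responses", {
  curve <- dose_response_from_tolerances(46.7, 0.5, 37, 0.2)
  # the two defining tolerance points are reproduced
  expect_equal(predict(curve, 46.7), 0.5, tolerance = 1e-12)
  expect_equal(predict(curve, 37), 0.2, tolerance = 1e-12)
  expect_equal(tolerance_volume(curve, 0.5), -curve$b0 / curve$b1,
               tolerance = 1e-12)
  # forward and inverse are mutual inverses across the probability range
  for (p in seq(0.05, 0.95, by = 0.05)) {
    expect_equal(predict(curve, tolerance_volume(curve, p)), p,
                 tolerance = 1e-9)
  }
  # monotone: larger probability -> larger tolerance volume
  tv <- vapply(seq(0.05, 0.95, by = 0.05), tolerance_volume, numeric(1),
               curve = curve)
  expect_true(all(diff(tv) > 0))
  expect_error(tolerance_volume(curve, 1.2), "in \\(0, 1\\)")
  flat <- list(b0 = 0, b1 = -0.1, predictor_name = "IV20")
  class(flat) <- "dose_response_curve"
  expect_error(tolerance_volume(flat, 0.5), "no positive dose-response")
})

test_that("a fitted dose-response recovers generating tolerances", {
  # generating curve built from the published TV pair
  truth <- dose_response_from_tolerances(46.7, 0.5, 37, 0.2)
  withr::with_seed(77, {
    v <- runif(2000, 20, 60)
    y <- rbinom(2000, 1, predict(truth, v))
  })
  fit <- fit_dose_response(v, y, name = "IV20")
  expect_lt(abs(tolerance_volume(fit, 0.5) - 46.7), 1.5)
  expect_lt(abs(tolerance_volume(fit, 0.2) - 37), 1.5)
})

test_that("Wald intervals of the dose-response fit cover the generating
           parameters at roughly the nominal rate", {
  truth <- dose_response_from_tolerances(46.7, 0.5, 37, 0.2)
  hits <- vapply(1:200, function(s) {
    withr::with_seed(5000 + s, {
      v <- runif(400, 20, 60)
      y <- rbinom(400, 1, predict(truth, v))
    })
    fit <- fit_dose_response(v, y)
    ci1 <- fit$b1 + c(-1, 1) * qnorm(0.975) * fit$se[2]
    ci1[1] <= truth$b1 && truth$b1 <= ci1[2]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})
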