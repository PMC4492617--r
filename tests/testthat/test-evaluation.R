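test_that("AUC equals brute-force pair enumeration and handles ties", {
  # perfectly separating scores
  y <- rep(c(0, 1), each = 10)
  expect_equal(roc_auc(c(runif(10, 0, 0.4), runif(10, 0.6, 1)), y)$auc, 1)
  # identical scores: all pairs tie
  expect_equal(roc_auc(rep(0.3, 20), y)$auc, 0.5)
  # random instances vs exhaustive enumeration
  withr::with_seed(55, {
    for (rep in 1:20) {
      yy <- rbinom(40, 1, 0.4)
      if (sum(yy) %in% c(0, 40)) next
      s <- round(runif(40), 2)  # rounding induces ties
      expect_equal(roc_auc(s, yy)$auc, auc_brute(s, yy), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(56, {
    y <- rbinom(50, 1, 0.5)
    s <- rnorm(50)
    a0 <- roc_auc(s, y)$auc
    expect_equal(roc_auc(plogis(s), y)$auc, a0)
    expect_equal(roc_auc(exp(2 * s), y)$auc, a0)
    expect_equal(roc_auc(rank(s), y)$auc, a0)
  })
})

test_that("the Hanley-McNeil interval contains the AUC and stays in [0,1]", {
  withr::with_seed(57, {
    y <- rbinom(60, 1, 0.4)
    s <- plogis(rnorm(60) + y)
    r <- roc_auc(s, y)
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
    expect_true(r$ci[1] >= 0 && r$ci[2] <= 1)
  })
  # near-perfect discrimination truncates at 1
  y <- rep(c(0, 1), each = 15)
  r <- roc_auc(c(rnorm(15, 0), rnorm(15, 10)), y)
  expect_lte(r$ci[2], 1)
})

test_that("Nagelkerke R2 has the right limits and closed form", {
  prob <- random_problem(150, 3, seed = 58, beta = c(1.2, -0.8, 0))
  fit <- fit_logistic(prob$x, prob$y)
  n <- fit$n
  expected <- (1 - exp(2 * (fit$null_log_likelihood - fit$log_likelihood) / n)) /
    (1 - exp(2 * fit$null_log_likelihood / n))
  expect_equal(nagelkerke_r2(fit), expected, tolerance = 1e-12)
  # cross-check the likelihoods against stats::glm on the same data
  g <- glm(prob$y ~ prob$x, family = binomial())
  g0 <- glm(prob$y ~ 1, family = binomial())
  r2_glm <- (1 - exp((g$deviance - g0$deviance) / n)) /
    (1 - exp(-g0$deviance / n))
  expect_equal(nagelkerke_r2(fit), r2_glm, tolerance = 1e-8)
  # no improvement over the null -> 0; perfect prediction -> 1
  expect_equal(nagelkerke_r2(list(log_likelihood = -60,
                                  null_log_likelihood = -60, n = 100)), 0)
  expect_equal(nagelkerke_r2(list(log_likelihood = 0,
                                  null_log_likelihood = -60, n = 100)), 1)
})

test_that("the omnibus test is a likelihood-ratio chi-square", {
  prob <- random_problem(400, 3, seed = 59, beta = c(1, 0.8, -0.6))
  fit <- fit_logistic(prob$x, prob$y)
  om <- omnibus_test(fit)
  expect_equal(om$df, 3)
  expect_equal(om$statistic,
               2 * (fit$log_likelihood - fit$null_log_likelihood))
  expect_lt(om$p, 0.001)  # strong signal at n = 400
  # intercept-only model: statistic 0, p = 1
  om0 <- omnibus_test(fit_logistic(NULL, prob$y))
  expect_equal(om0$statistic, 0)
  expect_equal(om0$p, 1)
})

test_that("the Hosmer-Lemeshow statistic matches hand arithmetic on a
           two-group toy", {
  # 20 patients, two groups of 10 by construction
  scores <- c(rep(0.1, 10), rep(0.7, 10))
  y <- c(rep(0, 9), 1, rep(1, 8), 0, 0)
  # hand computation: group 1 has n=10, O=1, E=1; group 2 n=10, O=8, E=7
  e1 <- 10 * 0.1; o1 <- 1
  e2 <- 10 * 0.7; o2 <- 8
  stat_hand <- (o1 - e1)^2 / (e1 * (1 - e1 / 10)) +
    (o2 - e2)^2 / (e2 * (1 - e2 / 10))
  expect_warning(hl <- hosmer_lemeshow(scores, y, groups = 2), "degenerate")
  expect_equal(hl$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(hl$groups_used, 2)
  expect_equal(hl$df, 0)  # 2 groups - 2: degenerate, p undefined
  hl4 <- suppressWarnings(hosmer_lemeshow(scores, y, groups = 4))
  expect_equal(hl4$statistic, stat_hand, tolerance = 1e-12)  # ties collapse
})

test_that("well-calibrated fitted scores give chi-square-like HL statistics", {
  # for scores from a correctly specified *fitted* logistic model the
  # statistic is approximately chi-square with groups - 2 df; for external
  # (unfitted) calibrated probabilities it would be closer to chi-square
  # with `groups` df
  withr::with_seed(60, {
    stats <- p <- numeric(150)
    for (r in 1:150) {
      x <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("a", "b")))
      y <- rbinom(400, 1, plogis(-0.5 + x[, 1] - 0.7 * x[, 2]))
      fit <- fit_logistic(x, y)
      s <- ntcp_predict(fit, x)
      hl <- suppressWarnings(hosmer_lemeshow(s, y, groups = 10))
      stats[r] <- hl$statistic
      p[r] <- hl$p
    }
    expect_lt(abs(mean(stats) - 8), 1.5)  # mean ~ df = groups - 2
    expect_gt(stats::ks.test(p[!is.na(p)], "punif")$p.value, 0.01)
  })
})

test_that("degenerate HL groupings are merged with a warning", {
  # constant score equal to prevalence: everything collapses to one group
  y <- rep(c(0, 1), 25)
  expect_warning(hl <- hosmer_lemeshow(rep(0.5, 50), y, groups = 5),
                 "degenerate")
  expect_true(is.na(hl$p))
  # a block of zero scores with zero events must be merged, reducing df
  scores <- c(rep(0, 10), runif(40, 0.2, 0.9))
  y2 <- c(rep(0, 10), rbinom(40, 1, scores[11:50]))
  expect_warning(hl2 <- hosmer_lemeshow(scores, y2, groups = 5), "merged")
  expect_lt(hl2$df, 3)
})

test_that("the Brier score is the mean squared error of the forecast", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(rep(0.5, 5), y), 0.25)
  withr::with_seed(61, {
    s <- runif(30)
    yy <- rbinom(30, 1, 0.5)
    expect_equal(brier_score(s, yy), mean((s - yy)^2), tolerance = 1e-12)
  })
  expect_error(brier_score(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
})

test_that("the assembled battery reproduces the generator's discrimination", {
  sim <- generate_cohort(generator_config(800, seed = 62,
                                          true_model = recovery_true_model()))
  x <- encode_factors(sim$cohort, sim$metrics,
                      factors = sim$truth$true_model$factors)
  fit <- fit_logistic(x, sim$truth$event)
  rep <- performance_report(fit, x, sim$truth$event)
  # analytic AUC implied by the generating model: concordance of true probs
  auc_true <- roc_auc(sim$truth$prob, sim$truth$event)$auc
  expect_lt(abs(rep$auc - auc_true), 0.03)
  expect_true(rep$auc_lo <= rep$auc & rep$auc <= rep$auc_hi)
  expect_lt(rep$omnibus_p, 1e-10)
  expect_true(rep$brier < 0.25)  # better than the uninformative forecast
})
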