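test_that("a large enough penalty shrinks every coefficient to exactly zero", {
  prob <- random_problem(80, 5, seed = 1, beta = c(1, -1, 0, 0, 0))
  xs <- std_like_pkg(prob$x)
  lmax <- max(abs(crossprod(xs, prob$y - mean(prob$y)))) / length(prob$y)
  b <- fit_l1_logistic(prob$x, prob$y, lmax * 1.01)
  expect_true(all(b[-1] == 0))
  expect_equal(unname(b[1]), qlogis(mean(prob$y)), tolerance = 1e-6)
})

test_that("penalty zero reproduces the unpenalized maximum-likelihood fit", {
  prob <- random_problem(120, 4, seed = 2, beta = c(0.8, -0.5, 0, 0.3))
  b <- fit_l1_logistic(prob$x, prob$y, 0)
  oracle <- newton_logistic(prob$x, prob$y)
  expect_equal(unname(b), unname(oracle$beta), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("input validation rejects bad outcomes and constant columns", {
  prob <- random_problem(50, 3, seed = 3)
  expect_error(fit_l1_logistic(prob$x, prob$y * 2, 0.1), "binary")
  x <- prob$x; x[, 2] <- 7
  expect_error(fit_l1_logistic(x, prob$y, 0.1), "V2")
})

test_that("the penalized objective is never increased by a sweep and the
           solution satisfies the KKT conditions", {
  for (seed in 1:5) {
    prob <- random_problem(60, 6, seed = seed,
                           beta = c(1, -0.7, 0.4, 0, 0, 0))
    lambda <- 0.04
    b <- fit_l1_logistic(prob$x, prob$y, lambda, track_objective = TRUE)
    trace <- attr(b, "objective_trace")
    expect_true(all(diff(trace) <= 1e-12))
    # KKT: |grad_j| <= lambda where beta_j = 0, grad_j = -lambda*sign otherwise
    xs <- std_like_pkg(prob$x)
    bb <- attr(b, "std_beta")
    p <- plogis(attr(b, "std_intercept") + drop(xs %*% bb))
    grad <- drop(crossprod(xs, p - prob$y)) / length(prob$y)
    expect_lte(max(abs(grad[bb == 0])), lambda + 1e-6)
    if (any(bb != 0)) {
      expect_lt(max(abs(grad[bb != 0] + lambda * sign(bb[bb != 0]))), 1e-6)
    }
    expect_lt(abs(mean(p - prob$y)), 1e-8)  # unpenalized intercept score
  }
})

test_that("back-transformation to the original scale round-trips", {
  prob <- random_problem(100, 5, seed = 6, beta = c(1, 0, -0.5, 0, 0.2))
  x <- sweep(sweep(prob$x, 2, c(1, 2, 5, 0.5, 10), "*"), 2,
             c(10, -3, 0, 100, 2), "+")  # arbitrary units/offsets
  b <- fit_l1_logistic(x, prob$y, 0.03)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  expect_equal(unname(b[-1]), unname(attr(b, "std_beta") / scl),
               tolerance = 1e-12)
  expect_equal(unname(b[1]),
               attr(b, "std_intercept") -
                 sum(attr(b, "std_beta") * ctr / scl),
               tolerance = 1e-9)
  # predictions agree on both scales
  eta_orig <- b[1] + drop(x %*% b[-1])
  eta_std <- attr(b, "std_intercept") +
    drop(sweep(sweep(x, 2, ctr), 2, scl, "/") %*% attr(b, "std_beta"))
  expect_equal(eta_orig, eta_std, tolerance = 1e-9)
})

test_that("a single predictor enters the path at the analytic penalty", {
  prob <- random_problem(150, 1, seed = 7, beta = 1.2)
  xs <- std_like_pkg(prob$x)
  entry_analytic <- abs(sum(xs * (prob$y - mean(prob$y)))) / length(prob$y)
  path <- lasso_path(prob$x, prob$y)
  expect_equal(unname(path$penalty[1]), entry_analytic, tolerance = 1e-9)
  # zero exactly at the largest penalty, nonzero at the next grid point
  expect_equal(unname(path$beta_std[1, 1]), 0)
  expect_true(path$beta_std[1, 2] != 0)
  expect_equal(path$entry_index[["V1"]], 2L)
})

test_that("ranking orders by entry penalty with documented tie-breaking", {
  # three independent predictors with clearly different effect sizes
  prob <- random_problem(400, 3, seed = 8, beta = c(1.5, 0.7, 0))
  path <- lasso_path(prob$x, prob$y)
  ranking <- rank_factors(path)
  expect_equal(ranking$ranked_factors[1], "V1")
  expect_equal(ranking$ranked_factors[2], "V2")
  expect_true(all(sort(ranking$ranked_factors) == paste0("V", 1:3)))
  # entry penalties are non-increasing down the ranking
  ep <- ranking$entry_penalty
  ep[is.na(ep)] <- 0
  expect_true(all(diff(ep) <= 1e-12))
})

test_that("ranking is invariant to column order up to tie-breaking", {
  prob <- random_problem(300, 6, seed = 9, beta = c(1.2, -0.8, 0.5, 0, 0, 0))
  path1 <- lasso_path(prob$x, prob$y)
  perm <- c(4, 1, 6, 2, 5, 3)
  path2 <- lasso_path(prob$x[, perm], prob$y)
  r1 <- rank_factors(path1)
  r2 <- rank_factors(path2)
  # the clearly-separated active factors rank identically
  expect_equal(r1$ranked_factors[1:3], r2$ranked_factors[1:3])
})

test_that("solutions coincide with an independent penalized-logistic
           implementation", {
  prob <- random_problem(200, 8, seed = 15,
                         beta = c(1, -0.8, 0.5, 0.3, 0, 0, 0, 0))
  xs <- std_like_pkg(prob$x)
  for (lambda in c(0.1, 0.05, 0.01)) {
    b <- fit_l1_logistic(prob$x, prob$y, lambda)
    g <- glmnet::glmnet(xs, prob$y, family = "binomial", lambda = lambda,
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(attr(b, "std_beta")), as.numeric(g$beta),
                 tolerance = 1e-7)
    expect_equal(attr(b, "std_intercept"), as.numeric(g$a0),
                 tolerance = 1e-7)
  }
})

test_that("permuted outcomes produce no stable early entrant", {
  prob <- random_problem(200, 10, seed = 13, beta = c(1.5, rep(0, 9)))
  first <- withr::with_seed(14, vapply(1:12, function(i) {
    yp <- sample(prob$y)
    rank_factors(lasso_path(prob$x, yp, grid_size = 40))$ranked_factors[1]
  }, character(1)))
  # under the null the first entrant is essentially arbitrary
  expect_gte(length(unique(first)), 4)
})

test_that("cross-validation is deterministic and keeps a strong predictor", {
  prob <- random_problem(200, 5, seed = 10, beta = c(1.5, 0, 0, 0, 0))
  cv1 <- cross_validate_penalty(prob$x, prob$y, folds = 5, seed = 42,
                                grid_size = 40)
  cv2 <- cross_validate_penalty(prob$x, prob$y, folds = 5, seed = 42,
                                grid_size = 40)
  expect_identical(cv1$chosen_penalty, cv2$chosen_penalty)
  b <- fit_l1_logistic(prob$x, prob$y, cv1$chosen_penalty)
  expect_true(b["V1"] != 0)
})

test_that("pure-noise predictors drive the chosen penalty toward the top of
           the grid", {
  prob <- random_problem(200, 5, seed = 11)  # outcome independent of x
  cv <- cross_validate_penalty(prob$x, prob$y, folds = 5, seed = 1,
                               grid_size = 40)
  # chosen penalty in the top (heavier) half of the grid
  expect_lte(which(cv$penalty == cv$chosen_penalty), 20)
})

test_that("cross-validation refuses folds that cannot be stratified", {
  prob <- random_problem(40, 2, seed = 12)
  y <- c(rep(1, 3), rep(0, 37))
  expect_error(cross_validate_penalty(prob$x, y, folds = 5, seed = 1),
               "stratify")
})

test_that("model-size scan is nested, rejects calibration failures, and
           prefers smaller sizes on AUC ties", {
  sim <- generate_cohort(generator_config(300, seed = 21,
                                          true_model = recovery_true_model()))
  x <- encode_factors(sim$cohort, sim$metrics)
  y <- sim$truth$event
  ranking <- rank_factors(lasso_path(x, y))
  scan <- scan_model_size(ranking, x, y, k_max = 6)
  expect_equal(scan$scan$k, 1:6)
  # nestedness: factor set of model k is a subset of model k+1's
  sets <- strsplit(scan$scan$factors, "+", fixed = TRUE)
  for (k in 1:5) expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  expect_true(scan$chosen_k %in% 1:6)
  chosen_row <- scan$scan[scan$scan$k == scan$chosen_k, ]
  expect_gte(chosen_row$hl_p, 0.05)
  # the chosen k has the maximal rounded AUC among HL-admissible sizes,
  # and no smaller admissible k attains it
  ok <- scan$scan$hl_p >= 0.05 & scan$scan$converged
  expect_equal(round(chosen_row$auc, 2), max(round(scan$scan$auc[ok], 2)))
  smaller <- ok & scan$scan$k < scan$chosen_k
  if (any(smaller)) {
    expect_true(all(round(scan$scan$auc[smaller], 2) <
                      round(chosen_row$auc, 2)))
  }
})

test_that("a size whose Hosmer-Lemeshow p falls below the threshold is
           rejected even if its AUC does not fall", {
  # scan outcome mirroring the published performance table: the sixth factor
  # drops HL p to 0.022 without raising AUC, so size five must win
  scan <- data.frame(k = 1:6, auc = c(0.70, 0.76, 0.78, 0.78, 0.80, 0.80),
                     hl_p = c(0.228, 0.220, 0.613, 0.892, 0.201, 0.022),
                     converged = TRUE)
  expect_equal(srpNTCP:::choose_model_size(scan), 5)
  # on an AUC tie among admissible sizes the smaller k is preferred
  scan2 <- data.frame(k = 1:3, auc = c(0.79, 0.80, 0.801),
                      hl_p = c(0.5, 0.5, 0.5), converged = TRUE)
  expect_equal(srpNTCP:::choose_model_size(scan2), 2)
})
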