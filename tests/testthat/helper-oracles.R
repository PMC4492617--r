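# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms from the code under test.

# Newton-Raphson maximum-likelihood logistic regression, written out with
# explicit matrix algebra (independent of glm.fit's IRLS bookkeeping).
newton_logistic <- function(x, y, tol = 1e-12, max_iter = 200) {
  x <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    score <- crossprod(x, y - p)
    info <- crossprod(x * w, x)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = drop(beta), vcov = solve(info),
       loglik = sum(y * log(p) + (1 - y) * log(1 - p)))
}

# penalized logistic objective on standardized columns
pen_objective_r <- function(xs, y, b0, b, lambda) {
  eta <- b0 + drop(xs %*% b)
  ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  -ll / length(y) + lambda * sum(abs(b))
}

# FISTA (accelerated proximal gradient) on the same objective: a generic
# convex first-order method, algorithmically unrelated to coordinate descent.
fista_l1_logistic <- function(xs, y, lambda, max_iter = 20000, tol = 1e-12) {
  n <- nrow(xs); p <- ncol(xs)
  L <- 0.25 * (1 + max(colSums(xs^2)) / n)  # conservative Lipschitz bound
  th <- function(v) c(v[1], sign(v[-1]) * pmax(abs(v[-1]) - lambda / L, 0))
  grad <- function(v) {
    pr <- 1 / (1 + exp(-(v[1] + drop(xs %*% v[-1]))))
    c(mean(pr - y), drop(crossprod(xs, pr - y)) / n)
  }
  v <- z <- rep(0, p + 1)
  t_k <- 1
  for (it in seq_len(max_iter)) {
    v_new <- th(z - grad(z) / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- v_new + ((t_k - 1) / t_new) * (v_new - v)
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new; t_k <- t_new
  }
  list(intercept = v[1], beta = v[-1],
       objective = pen_objective_r(xs, y, v[1], v[-1], lambda))
}

# AUC by exhaustive enumeration over all case-control pairs
auc_brute <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  s <- 0
  for (a in cases) for (b in controls) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(controls))
}

# population-standardize like the package does (sd with denominator n)
std_like_pkg <- function(x) {
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  sweep(sweep(x, 2, ctr), 2, scl, "/")
}

# small random logistic test problem
random_problem <- function(n, p, seed, beta = NULL, intercept = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    if (is.null(beta)) beta <- rep(0, p)
    y <- rbinom(n, 1, plogis(intercept + drop(x %*% beta)))
    list(x = x, y = y)
  })
}

# a tiny hand-buildable cohort data frame with valid fields
toy_cohort <- function(n = 4) {
  data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = seq(40, length.out = n, by = 5),
    bmi = rep(24, n),
    lung_d = rep(3, n),
    total_d = rep(6, n),
    tumor_site = rep(c("left", "right"), length.out = n),
    chemotherapy = rep(c("no", "yes"), length.out = n),
    energy = rep(c("6MV", "10MV", "6+10MV"), length.out = n),
    imn = rep("no", n),
    scf = rep(c("no", "yes"), length.out = n),
    surgery = rep(c("PM", "MRM"), length.out = n),
    t_stage = rep(0:2, length.out = n),
    n_stage = rep(0:2, length.out = n),
    density_grade = rep(c(0L, 1L), length.out = n),
    symptom_grade = rep(c(0L, 1L, 1L), length.out = n),
    stringsAsFactors = FALSE
  )
}
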