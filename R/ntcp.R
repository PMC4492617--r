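# --- unpenalized logistic NTCP fitting --------------------------------------

#' Maximum-likelihood logistic NTCP fit
#'
#' Fits `NTCP = 1/(1 + exp(-S))`, `S = b0 + sum(b_i x_i)`, by
#' iteratively-reweighted least squares (Newton-Raphson for the canonical
#' logit link, via `stats::glm.fit`). The coefficient covariance is the
#' inverse observed information at the optimum. Complete or quasi-complete
#' separation (any coefficient exceeding 50 on the standardized scale) is
#' signalled as a dedicated error condition rather than returned as a
#' spuriously huge estimate.
#'
#' @param x Numeric matrix of predictor columns (no intercept column);
#'   `NULL` or zero columns fits the intercept-only model.
#' @param outcome Binary 0/1 vector.
#' @return Object of class `"logistic_fit"`: `beta0`, `betas` (named, original
#'   scale), `coefficients` (intercept first), `covariance`,
#'   `log_likelihood`, `null_log_likelihood`, `n`, `converged`, `columns`.
#' @export
fit_logistic <- function(x, outcome) {
  y <- check_binary_outcome(outcome)
  x <- if (is.null(x)) matrix(numeric(0), length(y), 0) else as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) && ncol(x)) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (n <= ncol(x) + 1L) {
    stop("need more observations than coefficients", call. = FALSE)
  }
  sds <- apply(x, 2, function(col) sqrt(mean((col - mean(col))^2)))
  zero <- which(sds < 1e-12)
  if (length(zero)) {
    stop("zero-variance column(s): ", paste(colnames(x)[zero], collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) == 0L) sds <- numeric(0)
  xmat <- cbind("(Intercept)" = 1, x)
  fit <- suppressWarnings(glm.fit(xmat, y, family = binomial()))
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    stop("singular information matrix: collinear columns ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "), call. = FALSE)
  }
  if ((ncol(x) && max(abs(coefs[-1] * sds)) > 50) || abs(coefs[1]) > 100) {
    separation_error("logistic fit diverged: complete or quasi-complete separation")
  }
  p <- plogis(drop(xmat %*% coefs))
  w <- p * (1 - p)
  info <- crossprod(xmat * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    stop("singular information matrix", call. = FALSE)
  })
  dimnames(cov) <- list(colnames(xmat), colnames(xmat))
  p1 <- mean(y)
  ll0 <- sum(y) * log(p1) + (n - sum(y)) * log(1 - p1)
  structure(
    list(beta0 = unname(coefs[1]), betas = coefs[-1], coefficients = coefs,
         covariance = cov, log_likelihood = binomial_loglik(y, p),
         null_log_likelihood = ll0, n = n, converged = fit$converged,
         columns = colnames(x)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic NTCP fit: n = %d, logLik = %.3f (null %.3f)\n",
              x$n, x$log_likelihood, x$null_log_likelihood))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(beta)` with `exp(beta +/- z * SE)` confidence limits and
#' two-sided Wald p-values.
#'
#' @param fit A [fit_logistic()] result.
#' @param level Confidence level, default 0.95.
#' @return Data frame with `term`, `beta`, `se`, `p`, `or`, `ci_low`,
#'   `ci_high` (intercept row included).
#' @export
odds_ratios <- function(fit, level = 0.95) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$covariance))
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(beta),
    beta = unname(beta),
    se = unname(se),
    p = unname(2 * pnorm(-abs(beta / se))),
    or = unname(exp(beta)),
    ci_low = unname(exp(beta - z * se)),
    ci_high = unname(exp(beta + z * se)),
    stringsAsFactors = FALSE
  )
}

#' Per-patient NTCP prediction
#'
#' Evaluates `NTCP = 1/(1 + exp(-S))` with `S = b0 + sum(b_i x_i)` for the
#' fit's columns. Accepts a named vector (one patient) or a matrix/data frame
#' with one row per patient; every fitted column must be supplied.
#'
#' @param fit A [fit_logistic()] result, or any list with `beta0`/`intercept`
#'   and named `betas`/`terms` (e.g. [reference_srp_model()]).
#' @param values Named numeric vector, matrix or data frame of factor values.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
ntcp_predict <- function(fit, values) {
  beta0 <- fit$beta0 %||% fit$intercept
  betas <- fit$betas %||% fit$terms
  if (is.null(beta0) || is.null(betas)) {
    stop("`fit` must carry an intercept and named coefficients", call. = FALSE)
  }
  if (is.null(dim(values))) values <- t(as.matrix(values))
  values <- as.matrix(as.data.frame(values, check.names = FALSE))
  missing <- setdiff(names(betas), colnames(values))
  if (length(missing)) {
    stop("missing factor value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- beta0 + drop(values[, names(betas), drop = FALSE] %*% betas)
  plogis(s)
}

# --- univariate dose-response and tolerance-volume inversion ----------------

#' Univariate logistic dose-response curve
#'
#' Fits `NTCP(v) = 1/(1 + exp(-(b0 + b1 v)))` for a single dose-volume
#' predictor (e.g. IV20 in % or AIV20 in cc). A non-positive slope means no
#' positive dose-response: the curve is still returned, but tolerance-volume
#' queries on it fail.
#'
#' @param predictor Numeric predictor vector.
#' @param outcome Binary 0/1 vector.
#' @param name Predictor label, e.g. `"IV20"`.
#' @return Object of class `"dose_response_curve"`: `predictor_name`, `b0`,
#'   `b1`, `se` (length 2), and the underlying `fit`.
#' @export
fit_dose_response <- function(predictor, outcome, name = "IV20") {
  x <- matrix(as.numeric(predictor), ncol = 1,
              dimnames = list(NULL, name))
  fit <- fit_logistic(x, outcome)
  structure(
    list(predictor_name = name, b0 = fit$beta0, b1 = unname(fit$betas[1]),
         se = sqrt(diag(fit$covariance)), fit = fit),
    class = "dose_response_curve"
  )
}

#' Build a dose-response curve from two tolerance points
#'
#' The logistic curve through two (volume, probability) pairs is unique:
#' `b1 = (logit(p1) - logit(p2)) / (v1 - v2)`, `b0 = logit(p1) - b1 v1`.
#' Useful to reconstruct a published curve from its reported TV50/TV20 pair.
#'
#' @param v1,p1 First tolerance point (volume, probability).
#' @param v2,p2 Second tolerance point.
#' @param name Predictor label.
#' @return A `"dose_response_curve"`.
#' @export
dose_response_from_tolerances <- function(v1, p1, v2, p2, name = "IV20") {
  if (v1 == v2) stop("tolerance volumes must differ", call. = FALSE)
  b1 <- (qlogis(p1) - qlogis(p2)) / (v1 - v2)
  b0 <- qlogis(p1) - b1 * v1
  structure(
    list(predictor_name = name, b0 = b0, b1 = b1, se = NULL, fit = NULL),
    class = "dose_response_curve"
  )
}

#' @export
predict.dose_response_curve <- function(object, newdata, ...) {
  plogis(object$b0 + object$b1 * as.numeric(newdata))
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve in %s: NTCP(v) = plogis(%.4f + %.4f v)\n",
              x$predictor_name, x$b0, x$b1))
  if (x$b1 > 0) {
    cat(sprintf("  TV50 = %.2f, TV20 = %.2f (%s units)\n",
                tolerance_volume(x, 0.5), tolerance_volume(x, 0.2),
                x$predictor_name))
  }
  invisible(x)
}

#' Tolerance volume for a target complication probability
#'
#' Inverts the dose-response curve: `TV_p = (logit(p) - b0) / b1`, the
#' predictor value at which the modelled complication probability equals `p`
#' (e.g. TV50, TV20). Defined only for a positive dose-response (`b1 > 0`).
#'
#' @param curve A `"dose_response_curve"`.
#' @param p Target probability in (0, 1).
#' @return Tolerance value in the predictor's units.
#' @export
tolerance_volume <- function(curve, p) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (curve$b1 <= 0) {
    stop("no positive dose-response (b1 <= 0): tolerance volume undefined",
         call. = FALSE)
  }
  (qlogis(p) - curve$b0) / curve$b1
}

#' Plot a dose-response curve
#'
#' Base-graphics plot of the fitted NTCP curve with TV50/TV20 reference
#' lines.
#'
#' @param x A `"dose_response_curve"`.
#' @param from,to Predictor range; defaults to the span containing TV5-TV95.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dose_response_curve <- function(x, from = NULL, to = NULL, ...) {
  if (x$b1 > 0) {
    lo <- from %||% tolerance_volume(x, 0.02)
    hi <- to %||% tolerance_volume(x, 0.98)
  } else {
    lo <- from %||% 0; hi <- to %||% 100
  }
  v <- seq(lo, hi, length.out = 200)
  graphics::plot(v, predict(x, v), type = "l", xlab = x$predictor_name,
                 ylab = "NTCP", ylim = c(0, 1), ...)
  if (x$b1 > 0) {
    graphics::abline(h = c(0.2, 0.5), lty = 3)
    graphics::abline(v = c(tolerance_volume(x, 0.2), tolerance_volume(x, 0.5)),
                     lty = 3)
  }
  invisible(x)
}
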