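# --- model performance battery ----------------------------------------------

#' ROC area under the curve with confidence interval
#'
#' AUC by the Mann-Whitney pairwise-concordance statistic (ties count 1/2),
#' computed from ranks. The default 95% CI uses the Hanley-McNeil standard
#' error, truncated to [0, 1]; DeLong is available through the pROC package.
#'
#' @param scores Predicted probabilities (any monotone score works).
#' @param outcome Binary 0/1 vector.
#' @param level Confidence level.
#' @param ci_method `"hanley-mcneil"` (default) or `"delong"` (requires
#'   pROC).
#' @return List: `auc`, `ci` (length 2), `se`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, outcome, level = 0.95,
                    ci_method = c("hanley-mcneil", "delong")) {
  ci_method <- match.arg(ci_method)
  y <- check_binary_outcome(outcome)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ci_method == "delong") {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      stop("ci_method = 'delong' requires the pROC package", call. = FALSE)
    }
    ci <- as.numeric(pROC::ci.auc(pROC::roc(y, scores, quiet = TRUE),
                                  conf.level = level, method = "delong"))
    return(list(auc = auc, ci = c(ci[1], ci[3]), se = NA_real_,
                n_cases = n1, n_controls = n0))
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  list(auc = auc, ci = ci, se = se, n_cases = n1, n_controls = n0)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `1 - exp(2(LL0 - LL1)/n)` normalized by its attainable maximum
#' `1 - exp(2 LL0 / n)`, so a perfect model scores 1.
#'
#' @param fit A [fit_logistic()] result (or a list with `log_likelihood`,
#'   `null_log_likelihood`, `n`).
#' @return Scalar in [0, 1].
#' @export
nagelkerke_r2 <- function(fit) {
  n <- fit$n
  if (is.null(n) || n == 0) stop("n must be positive", call. = FALSE)
  cox_snell <- 1 - exp(2 * (fit$null_log_likelihood - fit$log_likelihood) / n)
  cox_snell / (1 - exp(2 * fit$null_log_likelihood / n))
}

#' Omnibus likelihood-ratio test
#'
#' Tests the fitted model against the intercept-only model:
#' `2(LL1 - LL0)` against a chi-square with as many degrees of freedom as
#' non-intercept coefficients.
#'
#' @param fit A [fit_logistic()] result.
#' @return List: `statistic`, `df`, `p`.
#' @export
omnibus_test <- function(fit) {
  stat <- 2 * (fit$log_likelihood - fit$null_log_likelihood)
  if (stat < -1e-6) {
    stop("log-likelihood below the null model: failed fit", call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- length(fit$betas)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Patients are sorted by predicted risk and cut into `groups` near-equal
#' deciles of risk; tied scores stay in one group. The statistic is
#' `sum (O - E)^2 / (E (1 - E/n_g))` over groups (O observed events, E
#' expected events, n_g group size), referred to a chi-square with
#' `groups - 2` degrees of freedom. Groups with zero expected events (or
#' zero expected non-events) are merged with a neighbour with a warning,
#' reducing the degrees of freedom; if fewer than 3 groups remain the test is
#' degenerate and `p` is `NA`.
#'
#' @param scores Predicted probabilities.
#' @param outcome Binary 0/1 vector.
#' @param groups Number of risk groups (default 10).
#' @return List: `statistic`, `df`, `p`, `groups_used`, `table` (per-group
#'   n, observed, expected).
#' @export
hosmer_lemeshow <- function(scores, outcome, groups = 10L) {
  y <- check_binary_outcome(outcome)
  n <- length(y)
  if (n < 2 * groups) stop("need n >= 2 * groups", call. = FALSE)
  cuts <- unique(quantile(scores, probs = seq_len(groups - 1L) / groups,
                          type = 2, names = FALSE))
  g <- findInterval(scores, cuts, left.open = FALSE) + 1L
  # findInterval puts score == cut into the upper group; shift ties down so
  # tied scores share the group of the cut they equal
  for (k in seq_along(cuts)) g[scores == cuts[k]] <- k
  tab <- do.call(rbind, lapply(sort(unique(g)), function(k) {
    idx <- g == k
    data.frame(n = sum(idx), observed = sum(y[idx]),
               expected = sum(scores[idx]))
  }))
  # merge degenerate groups (expected events or non-events ~ 0) downwards
  merged <- FALSE
  i <- 1
  while (i <= nrow(tab)) {
    degenerate <- tab$expected[i] < 1e-12 ||
      (tab$n[i] - tab$expected[i]) < 1e-12
    if (degenerate && nrow(tab) > 1) {
      j <- if (i == 1) 2 else i - 1
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab <- tab[-i, , drop = FALSE]
      merged <- TRUE
    } else {
      i <- i + 1
    }
  }
  if (merged) {
    warning("merged risk group(s) with zero expected events; df reduced",
            call. = FALSE)
  }
  G <- nrow(tab)
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- G - 2L
  p <- if (df < 1) {
    warning("fewer than 3 risk groups: Hosmer-Lemeshow test degenerate",
            call. = FALSE)
    NA_real_
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p, groups_used = G, table = tab)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param scores Predicted probabilities in [0, 1].
#' @param outcome Binary 0/1 vector.
#' @return Scalar in [0, 1].
#' @export
brier_score <- function(scores, outcome) {
  y <- check_binary_outcome(outcome)
  if (any(scores < 0 | scores > 1)) stop("scores must be in [0, 1]",
                                         call. = FALSE)
  mean((scores - y)^2)
}

#' Full performance battery for a fitted NTCP model
#'
#' @param fit A [fit_logistic()] result.
#' @param x Predictor matrix with the fit's columns.
#' @param outcome Binary 0/1 vector.
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @return One-row data frame: `auc`, `auc_lo`, `auc_hi`, `nagelkerke`,
#'   `omnibus_p`, `hl_statistic`, `hl_df`, `hl_p`, `brier`.
#' @export
performance_report <- function(fit, x, outcome, hl_groups = 10L) {
  scores <- ntcp_predict(fit, x)
  roc <- roc_auc(scores, outcome)
  hl <- hosmer_lemeshow(scores, outcome, groups = hl_groups)
  data.frame(
    auc = roc$auc, auc_lo = roc$ci[1], auc_hi = roc$ci[2],
    nagelkerke = nagelkerke_r2(fit), omnibus_p = omnibus_test(fit)$p,
    hl_statistic = hl$statistic, hl_df = hl$df, hl_p = hl$p,
    brier = brier_score(scores, outcome)
  )
}
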