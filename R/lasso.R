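# --- L1-penalized logistic regression: standardization helpers -------------

# centre columns and scale to population sd (so sum(x^2) = n), as the
# coordinate-descent updates assume; errors on constant columns unless
# allow_constant, in which case they standardize to all-zero (and can never
# be selected) — used for within-fold standardization where a rare level may
# be absent from a training split
standardize_columns <- function(x, allow_constant = FALSE) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  zero <- which(scale < 1e-12)
  if (length(zero)) {
    if (!allow_constant) {
      nms <- colnames(x)[zero] %||% as.character(zero)
      stop("zero-variance column(s): ", paste(nms, collapse = ", "),
           call. = FALSE)
    }
    scale[zero] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  list(x = xs, center = center, scale = scale)
}

# smallest penalty at which every penalized coefficient is zero:
# max_j |<x_j, y - ybar>| / n on standardized columns
penalty_max <- function(xs, y) {
  max(abs(crossprod(xs, y - mean(y)))) / length(y)
}

#' L1-penalized logistic regression at a fixed penalty
#'
#' Minimizes `-loglik/n + penalty * sum(|beta_j|)` with an unpenalized
#' intercept by cyclic coordinate descent with soft-thresholding on
#' internally standardized columns (converged when the largest coefficient
#' change in a sweep falls below `tol`). Coefficients are returned on the
#' original factor scale; the standardized solution is kept in attributes.
#'
#' @param x Numeric matrix (e.g. a [encode_factors()] matrix), columns =
#'   candidate factor columns.
#' @param outcome Binary 0/1 vector.
#' @param penalty Non-negative penalty weight.
#' @param tol Convergence tolerance on the coefficient change per sweep.
#' @param max_sweeps Outer iteration budget (IRLS steps).
#' @param init Optional list with standardized `beta` and `intercept` warm
#'   start.
#' @param track_objective Record the penalized objective after every sweep
#'   (attribute `objective_trace`).
#' @return Named coefficient vector `(Intercept)` first, original scale, with
#'   attributes `std_beta`, `std_intercept`, `objective`, `sweeps`,
#'   `converged`.
#' @export
fit_l1_logistic <- function(x, outcome, penalty, tol = 1e-7,
                            max_sweeps = 500L, init = NULL,
                            track_objective = FALSE) {
  y <- check_binary_outcome(outcome)
  if (penalty < 0) stop("penalty must be >= 0", call. = FALSE)
  std <- standardize_columns(x)
  p <- ncol(std$x)
  beta0 <- init$beta %||% rep(0, p)
  int0 <- init$intercept %||% qlogis(mean(y))
  fit <- cd_l1_logistic(std$x, y, penalty, beta0, int0, tol,
                        as.integer(max_sweeps), track_objective)
  beta_orig <- fit$beta / std$scale
  intercept <- fit$intercept - sum(fit$beta * std$center / std$scale)
  out <- c("(Intercept)" = intercept,
           stats::setNames(beta_orig, colnames(std$x)))
  attr(out, "std_beta") <- stats::setNames(fit$beta, colnames(std$x))
  attr(out, "std_intercept") <- fit$intercept
  attr(out, "objective") <- fit$objective
  attr(out, "sweeps") <- fit$sweeps
  attr(out, "converged") <- fit$converged
  if (track_objective) attr(out, "objective_trace") <- fit$objective_trace
  out
}

# --- penalty path -----------------------------------------------------------

#' LASSO-logistic regularization path
#'
#' Warm-started coordinate-descent fits along a log-spaced decreasing penalty
#' grid from the data-derived maximal penalty (all penalized coefficients
#' zero) down to `grid_min_fraction` of it. Records, for every factor (its
#' indicator columns grouped), the largest penalty at which it first enters
#' the model.
#'
#' @param x A [encode_factors()] matrix (or plain numeric matrix, in which
#'   case every column is its own factor).
#' @param outcome Binary 0/1 vector.
#' @param grid_size Number of penalty grid points.
#' @param grid_min_fraction Smallest penalty as a fraction of the maximal one.
#' @param tol,max_sweeps Passed to the coordinate descent.
#' @return Object of class `"lasso_path"`: `penalty` (decreasing), `beta_std`
#'   (columns x grid, standardized scale), `intercept_std`, `entry_index` and
#'   `entry_penalty` per factor, `factors`, `column_factor`, scaling info.
#' @export
lasso_path <- function(x, outcome, grid_size = 100L, grid_min_fraction = 1e-3,
                       tol = 1e-7, max_sweeps = 500L) {
  y <- check_binary_outcome(outcome)
  meta <- attr(x, "column_meta")
  cols <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  column_factor <- if (!is.null(meta)) {
    stats::setNames(meta$factor, meta$column)[cols]
  } else stats::setNames(cols, cols)
  factors <- if (!is.null(attr(x, "factors"))) attr(x, "factors") else
    unique(unname(column_factor))

  std <- standardize_columns(x)
  lmax <- penalty_max(std$x, y)
  grid <- exp(seq(log(lmax), log(lmax * grid_min_fraction),
                  length.out = grid_size))
  p <- ncol(std$x)
  beta <- rep(0, p)
  intercept <- qlogis(mean(y))
  beta_mat <- matrix(0, p, grid_size, dimnames = list(cols, NULL))
  int_vec <- numeric(grid_size)
  for (k in seq_len(grid_size)) {
    fit <- cd_l1_logistic(std$x, y, grid[k], beta, intercept, tol,
                          as.integer(max_sweeps), FALSE)
    beta <- fit$beta
    intercept <- fit$intercept
    beta_mat[, k] <- beta
    int_vec[k] <- intercept
  }

  col_entry <- apply(beta_mat != 0, 1, function(nz) {
    w <- which(nz)
    if (length(w)) w[1] else NA_integer_
  })
  entry_index <- vapply(factors, function(f) {
    idx <- col_entry[column_factor == f]
    if (all(is.na(idx))) NA_integer_ else as.integer(min(idx, na.rm = TRUE))
  }, integer(1))
  entry_penalty <- ifelse(is.na(entry_index), NA_real_, grid[entry_index])
  names(entry_penalty) <- factors

  structure(
    list(penalty = grid, beta_std = beta_mat, intercept_std = int_vec,
         entry_index = entry_index, entry_penalty = entry_penalty,
         factors = factors, column_factor = column_factor,
         center = std$center, scale = std$scale, n = length(y)),
    class = "lasso_path"
  )
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("LASSO-logistic path: %d factors (%d columns), %d penalties [%.4g, %.4g]\n",
              length(x$factors), nrow(x$beta_std), length(x$penalty),
              max(x$penalty), min(x$penalty)))
  invisible(x)
}

# --- cross-validated penalty ------------------------------------------------

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    id <- integer(length(y))
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      if (length(idx) < folds) {
        stop("cannot stratify: a class has fewer members than folds",
             call. = FALSE)
      }
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
}

#' Cross-validated penalty choice
#'
#' Stratified k-fold cross-validation of the penalty grid, scoring each
#' penalty by mean out-of-fold binomial deviance per observation; the chosen
#' penalty minimizes it. Deterministic given `seed`.
#'
#' @param x Candidate-factor matrix.
#' @param outcome Binary 0/1 vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold split (mandatory for
#'   reproducibility).
#' @param grid_size,grid_min_fraction Grid configuration (shared with
#'   [lasso_path()]).
#' @return List of class `"srp_cv"`: `chosen_penalty`, `penalty`, `cvm`
#'   (mean deviance), `cvsd`, `folds`, `seed`.
#' @export
cross_validate_penalty <- function(x, outcome, folds = 10L, seed,
                                   grid_size = 100L, grid_min_fraction = 1e-3) {
  y <- check_binary_outcome(outcome)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  fold_id <- stratified_folds(y, folds, seed)
  std_all <- standardize_columns(x)
  grid <- exp(seq(log(penalty_max(std_all$x, y)),
                  log(penalty_max(std_all$x, y) * grid_min_fraction),
                  length.out = grid_size))
  dev <- matrix(NA_real_, folds, grid_size)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    std <- standardize_columns(x[tr, , drop = FALSE], allow_constant = TRUE)
    xs_te <- sweep(sweep(as.matrix(x)[te, , drop = FALSE], 2, std$center),
                   2, std$scale, "/")
    beta <- rep(0, ncol(std$x))
    intercept <- qlogis(mean(y[tr]))
    for (k in seq_along(grid)) {
      fit <- cd_l1_logistic(std$x, y[tr], grid[k], beta, intercept,
                            1e-7, 500L, FALSE)
      beta <- fit$beta
      intercept <- fit$intercept
      eta <- intercept + xs_te %*% beta
      dev[f, k] <- -2 * binomial_loglik(y[te], plogis(eta)) / sum(te)
    }
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, sd) / sqrt(folds)
  structure(
    list(chosen_penalty = grid[which.min(cvm)], penalty = grid, cvm = cvm,
         cvsd = cvsd, folds = folds, seed = seed),
    class = "srp_cv"
  )
}

# --- ranking ----------------------------------------------------------------

#' Rank candidate factors by LASSO path entry order
#'
#' Factors are ordered by the penalty at which they first enter the path
#' (largest first, i.e. strongest association); a grouped multi-level factor
#' enters with its first-entering indicator. Ties at the same grid point are
#' broken by the absolute standardized coefficient (summed over a factor's
#' columns) at the chosen cross-validation penalty (or at the smallest grid
#' penalty if none is supplied), then by candidate-list order. Factors that
#' never enter rank last in list order.
#'
#' @param path A [lasso_path()].
#' @param chosen_penalty Optional penalty from [cross_validate_penalty()]
#'   used for tie-breaking.
#' @return Object of class `"ranking_result"`: `ranked_factors`,
#'   `entry_penalty`, `chosen_penalty`.
#' @export
rank_factors <- function(path, chosen_penalty = NULL) {
  grid <- path$penalty
  ref_k <- if (is.null(chosen_penalty)) length(grid) else
    which.min(abs(grid - chosen_penalty))
  tie_coef <- vapply(path$factors, function(f) {
    sum(abs(path$beta_std[path$column_factor == f, ref_k]))
  }, numeric(1))
  entry <- path$entry_index
  entry[is.na(entry)] <- length(grid) + 1L
  ord <- order(entry, -tie_coef, seq_along(path$factors))
  structure(
    list(ranked_factors = path$factors[ord],
         entry_penalty = path$entry_penalty[ord],
         tie_coef = tie_coef[ord],
         chosen_penalty = chosen_penalty),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("Factors ranked by LASSO path entry (strongest first):\n")
  for (i in seq_along(x$ranked_factors)) {
    cat(sprintf("%3d. %-12s entry penalty %s\n", i, x$ranked_factors[i],
                ifelse(is.na(x$entry_penalty[i]), "-",
                       formatC(x$entry_penalty[i], digits = 4, format = "g"))))
  }
  invisible(x)
}

# --- model-size scan --------------------------------------------------------

#' Scan nested model sizes and choose the factor count
#'
#' For each k = 1..`k_max`, refits an *unpenalized* logistic model on the
#' top-k ranked factors and records AUC (with 95% CI), Nagelkerke R-squared,
#' the omnibus likelihood-ratio p, the Hosmer-Lemeshow p and the Brier score.
#' The chosen size maximizes AUC (rounded to `auc_digits`) among models whose
#' Hosmer-Lemeshow p is at least `hl_alpha`, preferring the smaller k on
#' ties — so an extra factor that destroys calibration is rejected even if
#' discrimination does not fall. Sizes whose refit fails (separation) are
#' recorded as non-converged and skipped with a warning.
#'
#' @param ranking A [rank_factors()] result.
#' @param x The [encode_factors()] matrix used for ranking.
#' @param outcome Binary 0/1 vector.
#' @param k_max Largest model size to scan.
#' @param hl_alpha Hosmer-Lemeshow admissibility level.
#' @param hl_groups Number of risk groups for the Hosmer-Lemeshow test.
#' @param auc_digits Rounding used when comparing AUCs.
#' @return Object of class `"model_size_scan"`: data frame `scan` (one row
#'   per k) and `chosen_k`.
#' @export
scan_model_size <- function(ranking, x, outcome, k_max = 6L,
                            hl_alpha = 0.05, hl_groups = 10L,
                            auc_digits = 2L) {
  y <- check_binary_outcome(outcome)
  if (k_max > length(ranking$ranked_factors)) {
    stop("k_max exceeds the number of ranked factors", call. = FALSE)
  }
  rows <- vector("list", k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fac <- ranking$ranked_factors[seq_len(k)]
    cols <- columns_for_factors(x, fac)
    row <- data.frame(k = k, factors = paste(fac, collapse = "+"),
                      n_columns = length(cols), auc = NA_real_,
                      auc_lo = NA_real_, auc_hi = NA_real_,
                      nagelkerke = NA_real_, omnibus_p = NA_real_,
                      hl_p = NA_real_, brier = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE)
    fit <- tryCatch(fit_logistic(x[, cols, drop = FALSE], y),
                    srp_separation_error = function(e) e,
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("model size k=%d skipped: %s", k, conditionMessage(fit)),
              call. = FALSE)
    } else {
      scores <- ntcp_predict(fit, x[, cols, drop = FALSE])
      roc <- roc_auc(scores, y)
      hl <- suppressWarnings(hosmer_lemeshow(scores, y, groups = hl_groups))
      row$auc <- roc$auc; row$auc_lo <- roc$ci[1]; row$auc_hi <- roc$ci[2]
      row$nagelkerke <- nagelkerke_r2(fit)
      row$omnibus_p <- omnibus_test(fit)$p
      row$hl_p <- hl$p
      row$brier <- brier_score(scores, y)
      row$converged <- TRUE
      fits[[k]] <- fit
    }
    rows[[k]] <- row
  }
  scan <- do.call(rbind, rows)
  chosen_k <- choose_model_size(scan, hl_alpha, auc_digits)
  structure(
    list(scan = scan, chosen_k = chosen_k,
         chosen_factors = ranking$ranked_factors[seq_len(chosen_k)],
         fits = fits, hl_alpha = hl_alpha, auc_digits = auc_digits),
    class = "model_size_scan"
  )
}

# selection rule: maximal AUC (rounded) among calibrated sizes, smallest k
# on ties; sizes failing the Hosmer-Lemeshow threshold are inadmissible
choose_model_size <- function(scan, hl_alpha = 0.05, auc_digits = 2L) {
  ok <- scan$converged & !is.na(scan$hl_p) & scan$hl_p >= hl_alpha
  idx <- if (any(ok)) {
    cand <- which(ok)
    cand[which.max(round(scan$auc, auc_digits)[cand])]  # first = smallest k
  } else {
    warning("no model size passes the Hosmer-Lemeshow criterion; ",
            "falling back to the best-AUC converged size", call. = FALSE)
    conv <- which(scan$converged)
    if (!length(conv)) stop("no model size converged", call. = FALSE)
    conv[which.max(round(scan$auc[conv], auc_digits))]
  }
  scan$k[idx]
}

#' @export
print.model_size_scan <- function(x, ...) {
  cat("Model size scan (unpenalized refits on top-k ranked factors):\n")
  print(x$scan[, c("k", "auc", "auc_lo", "auc_hi", "nagelkerke",
                   "omnibus_p", "hl_p", "brier")], row.names = FALSE,
        digits = 3)
  cat(sprintf("chosen k = %d (%s)\n", x$chosen_k,
              paste(x$chosen_factors, collapse = ", ")))
  invisible(x)
}
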