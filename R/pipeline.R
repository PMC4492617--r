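# --- end-to-end analysis pipeline --------------------------------------------

#' Pipeline run configuration
#'
#' Either point `cohort_csv`/`dvh_manifest` at input files, or set `fixture`
#' to a [generator_config()] to run on a synthetic cohort.
#'
#' @param cohort_csv Cohort CSV path (see [read_cohort()]).
#' @param dvh_manifest DVH manifest CSV path (see [read_dvh_manifest()]);
#'   optional if the cohort CSV already carries the dosimetric columns.
#' @param fixture Optional [generator_config()]; overrides the file inputs.
#' @param factors Candidate factor list.
#' @param folds,seed,grid_size,grid_min_fraction Selection settings (see
#'   [cross_validate_penalty()] and [lasso_path()]).
#' @param k_max,hl_alpha,hl_groups,auc_digits Model-size scan settings.
#' @param dose_response_predictor Univariate dose-response predictor
#'   (`"IV20"` or `"AIV20"`).
#' @param constraints Named vector of strict upper limits checked per patient;
#'   defaults to the published planning constraint IV20 < 37% and
#'   AIV20 < 310 cc.
#' @param output_dir Directory for report CSVs; `NULL` to skip writing.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(cohort_csv = NULL, dvh_manifest = NULL, fixture = NULL,
                       factors = candidate_factor_names(),
                       folds = 10L, seed = 1L, grid_size = 100L,
                       grid_min_fraction = 1e-3, k_max = 6L,
                       hl_alpha = 0.05, hl_groups = 10L, auc_digits = 2L,
                       dose_response_predictor = "IV20",
                       constraints = c(IV20 = 37, AIV20 = 310),
                       output_dir = NULL) {
  structure(
    list(cohort_csv = cohort_csv, dvh_manifest = dvh_manifest,
         fixture = fixture, factors = factors, folds = folds, seed = seed,
         grid_size = grid_size, grid_min_fraction = grid_min_fraction,
         k_max = k_max, hl_alpha = hl_alpha, hl_groups = hl_groups,
         auc_digits = auc_digits,
         dose_response_predictor = dose_response_predictor,
         constraints = constraints, output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys mirror the [run_config()] arguments; a
#'   `fixture` object is passed to [generator_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  if (!is.null(raw$fixture)) {
    raw$fixture <- do.call(generator_config, raw$fixture)
  }
  if (!is.null(raw$constraints)) raw$constraints <- unlist(raw$constraints)
  do.call(run_config, raw)
}

#' Per-patient dose-volume constraint compliance
#'
#' Checks each configured limit per patient. The published constraint is a
#' strict "<": a value exactly at the limit is reported as a failure.
#'
#' @param metrics Per-patient metrics table ([metrics_table()]).
#' @param limits Named numeric vector of strict upper limits, names matching
#'   metric columns (e.g. `c(IV20 = 37, AIV20 = 310)`).
#' @return Data frame with one row per patient and limit: `patient_id`,
#'   `metric`, `value`, `limit`, `pass`, `margin`; the per-limit violation
#'   fractions are attached as attribute `"summary"`.
#' @export
constraint_report <- function(metrics, limits = c(IV20 = 37, AIV20 = 310)) {
  missing <- setdiff(names(limits), names(metrics))
  if (length(missing)) {
    stop("metrics table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(limits), function(metric) {
    value <- metrics[[metric]]
    data.frame(patient_id = metrics$patient_id, metric = metric,
               value = value, limit = unname(limits[metric]),
               pass = value < limits[metric],
               margin = unname(limits[metric]) - value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(limits), function(metric) {
    sub <- out[out$metric == metric, ]
    data.frame(metric = metric, limit = unname(limits[metric]),
               n = nrow(sub), n_fail = sum(!sub$pass),
               fail_fraction = mean(!sub$pass), stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summary
  out
}

#' Run the full NTCP model-building pipeline
#'
#' Read (or generate) the cohort and DVHs; compute dosimetric metrics; apply
#' the complete-case filter; derive the SRP endpoint; rank candidate factors
#' on the LASSO path with a cross-validated penalty; scan nested model sizes;
#' refit the chosen model unpenalized and report odds ratios and the
#' performance battery; fit the univariate dose-response curve and invert it
#' to TV50/TV20; and check the dose-volume constraints. All randomness is
#' controlled by `config$seed`, so repeated runs produce identical report
#' files.
#'
#' @param config A [run_config()].
#' @return Invisible list with all artifacts: `cohort`, `metrics`, `srp`,
#'   `ranking`, `cv`, `scan`, `final_fit`, `odds_ratios`, `performance`,
#'   `dose_response` (curve, `tv50`, `tv20`), `constraints`, `rejected`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(config$fixture)) {
    sim <- stage("simulate", generate_cohort(config$fixture))
    cohort <- sim$cohort
    metrics <- sim$metrics
  } else {
    if (is.null(config$cohort_csv)) {
      stop("pipeline stage 'input' failed: no cohort source configured",
           call. = FALSE)
    }
    cohort <- stage("read_cohort", read_cohort(config$cohort_csv))
    if (!is.null(config$dvh_manifest)) {
      dvhs <- stage("read_dvh", read_dvh_manifest(config$dvh_manifest))
      metrics <- stage("metrics", metrics_table(dvhs))
    } else {
      dosi_cols <- setdiff(factor_columns(
        candidate_factors()$name[candidate_factors()$source == "dosimetric"]),
        names(cohort))
      if (length(dosi_cols)) {
        stop("pipeline stage 'metrics' failed: no DVH manifest and cohort ",
             "lacks dosimetric columns: ", paste(dosi_cols, collapse = ", "),
             call. = FALSE)
      }
      metrics <- cohort[, c("patient_id",
                            factor_columns(candidate_factors()$name[
                              candidate_factors()$source == "dosimetric"]))]
    }
  }

  cc <- stage("complete_cases", complete_cases(cohort))
  cohort <- cc$kept
  metrics <- metrics[metrics$patient_id %in% cohort$patient_id, , drop = FALSE]

  srp <- stage("derive_srp", derive_srp(cohort))
  x <- stage("encode_factors", encode_factors(cohort, metrics, config$factors))
  x <- stage("encode_factors", drop_zero_variance(x))

  path <- stage("lasso_path",
                lasso_path(x, srp, grid_size = config$grid_size,
                           grid_min_fraction = config$grid_min_fraction))
  cv <- stage("cross_validation",
              cross_validate_penalty(x, srp, folds = config$folds,
                                     seed = config$seed,
                                     grid_size = config$grid_size,
                                     grid_min_fraction = config$grid_min_fraction))
  ranking <- stage("ranking", rank_factors(path, cv$chosen_penalty))
  scan <- stage("model_size_scan",
                scan_model_size(ranking, x, srp, k_max = config$k_max,
                                hl_alpha = config$hl_alpha,
                                hl_groups = config$hl_groups,
                                auc_digits = config$auc_digits))
  final_cols <- columns_for_factors(x, scan$chosen_factors)
  final_fit <- stage("final_model",
                     fit_logistic(x[, final_cols, drop = FALSE], srp))
  ors <- stage("odds_ratios", odds_ratios(final_fit))
  perf <- stage("performance",
                performance_report(final_fit, x[, final_cols, drop = FALSE],
                                   srp, hl_groups = config$hl_groups))

  pred_name <- config$dose_response_predictor
  dr <- stage("dose_response", {
    curve <- fit_dose_response(metrics[[pred_name]], srp, name = pred_name)
    tv <- if (curve$b1 > 0) {
      c(tv50 = tolerance_volume(curve, 0.5), tv20 = tolerance_volume(curve, 0.2))
    } else c(tv50 = NA_real_, tv20 = NA_real_)
    list(curve = curve, tv50 = unname(tv["tv50"]), tv20 = unname(tv["tv20"]))
  })
  constraints <- stage("constraints",
                       constraint_report(metrics, config$constraints))

  artifacts <- list(cohort = cohort, metrics = metrics, srp = srp,
                    ranking = ranking, cv = cv, scan = scan,
                    final_fit = final_fit, odds_ratios = ors,
                    performance = perf, dose_response = dr,
                    constraints = constraints, rejected = cc$rejected,
                    config = config)
  if (!is.null(config$output_dir)) {
    stage("write_reports", write_pipeline_reports(artifacts,
                                                  config$output_dir))
  }
  invisible(artifacts)
}

write_pipeline_reports <- function(a, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE,
                                   quote = FALSE)
  wcsv(data.frame(rank = seq_along(a$ranking$ranked_factors),
                  factor = a$ranking$ranked_factors,
                  entry_penalty = unname(a$ranking$entry_penalty)),
       "ranking.csv")
  wcsv(a$scan$scan, "model_scan.csv")
  wcsv(a$odds_ratios, "model_report.csv")
  wcsv(a$performance, "performance.csv")
  curve <- a$dose_response$curve
  grid <- if (curve$b1 > 0) {
    seq(tolerance_volume(curve, 0.02), tolerance_volume(curve, 0.98),
        length.out = 101)
  } else seq(min(a$metrics[[curve$predictor_name]]),
             max(a$metrics[[curve$predictor_name]]), length.out = 101)
  wcsv(data.frame(predictor = curve$predictor_name, value = grid,
                  ntcp = predict(curve, grid)), "dose_response.csv")
  wcsv(data.frame(quantity = c("b0", "b1", "tv50", "tv20"),
                  value = c(curve$b0, curve$b1, a$dose_response$tv50,
                            a$dose_response$tv20)),
       "dose_response_parameters.csv")
  wcsv(a$constraints, "constraints.csv")
  wcsv(attr(a$constraints, "summary"), "constraint_summary.csv")
  if (nrow(a$rejected)) {
    writeLines(sprintf("%s: %s", a$rejected$patient_id, a$rejected$reason),
               file.path(dir, "rejections.txt"))
  }
  writeLines(c(
    sprintf("srpNTCP %s", as.character(utils::packageVersion("srpNTCP"))),
    sprintf("seed: %d", a$config$seed),
    sprintf("folds: %d", a$config$folds),
    sprintf("penalty grid: %d points, min fraction %g", a$config$grid_size,
            a$config$grid_min_fraction),
    sprintf("chosen penalty: %.8g", a$cv$chosen_penalty),
    sprintf("chosen k: %d (%s)", a$scan$chosen_k,
            paste(a$scan$chosen_factors, collapse = ", ")),
    "constraint rule: strict '<'; a value at the limit fails"
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}
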