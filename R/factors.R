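#' Dose thresholds for the volume metrics
#'
#' The nine dose levels (Gy) at which relative (IV) and absolute (AIV)
#' ipsilateral-lung volumes are evaluated.
#'
#' @return Integer vector of threshold doses in Gy.
#' @export
iv_thresholds <- function() c(5L, 10L, 13L, 15L, 20L, 25L, 30L, 40L, 50L)

#' Registry of the 31 candidate risk factors
#'
#' The candidate set comprises 19 dosimetric factors (MLD plus IV/AIV at the
#' nine thresholds of [iv_thresholds()]) and 12 clinical factors. Binary
#' clinical factors are coded 0/1 (reference listed first); the three-level
#' factors Energy, T stage and N stage are expanded to two reference-coded
#' indicator columns each, so the 31 factors span 34 numeric columns.
#'
#' @return A data frame with one row per factor: `name`, `kind`
#'   (`"continuous"`, `"binary"` or `"multilevel"`), `source`
#'   (`"dosimetric"`/`"clinical"`), `units`, and the encoded `columns`
#'   (comma-separated).
#' @export
candidate_factors <- function() {
  thr <- iv_thresholds()
  dosi <- data.frame(
    name = c("MLD", paste0("IV", thr), paste0("AIV", thr)),
    kind = "continuous",
    source = "dosimetric",
    units = c("Gy", rep("%", 9L), rep("cc", 9L)),
    stringsAsFactors = FALSE
  )
  clin <- data.frame(
    name = c("Age", "BMI", "Lung_d", "Total_d", "Tumor_site", "Chemotherapy",
             "Energy", "IMN", "SCF", "Surgery", "T_stage", "N_stage"),
    kind = c("continuous", "continuous", "continuous", "continuous",
             "binary", "binary", "multilevel", "binary", "binary", "binary",
             "multilevel", "multilevel"),
    source = "clinical",
    units = c("years", "kg/m2", "cm", "cm", "0=left,1=right", "0=no,1=yes",
              "ref 6MV", "0=no,1=yes", "0=no,1=yes", "0=PM,1=MRM",
              "ref T0/T1", "ref N0"),
    stringsAsFactors = FALSE
  )
  reg <- rbind(dosi, clin)
  cols <- list(
    Energy = c("E(1)", "E(2)"), T_stage = c("T(1)", "T(2)"),
    N_stage = c("N(1)", "N(2)")
  )
  reg$columns <- vapply(reg$name, function(nm) {
    paste(cols[[nm]] %||% nm, collapse = ",")
  }, character(1))
  reg
}

#' @rdname candidate_factors
#' @export
candidate_factor_names <- function() candidate_factors()$name

factor_columns <- function(factors) {
  reg <- candidate_factors()
  unknown <- setdiff(factors, reg$name)
  if (length(unknown)) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unlist(lapply(factors, function(nm) {
    strsplit(reg$columns[reg$name == nm], ",", fixed = TRUE)[[1]]
  }), use.names = FALSE)
}

# map an encoded column name back to its factor name
column_factor_map <- function() {
  reg <- candidate_factors()
  out <- character(0)
  for (i in seq_len(nrow(reg))) {
    cols <- strsplit(reg$columns[i], ",", fixed = TRUE)[[1]]
    out[cols] <- reg$name[i]
  }
  out
}

#' Encode a cohort into the candidate-factor design matrix
#'
#' Builds the numeric design matrix used by the selection and NTCP modules.
#' Continuous factors enter in their natural units; binary factors are coded
#' 0/1 (left/right, no/yes, PM/MRM); Energy expands to `E(1)` (10MV) and
#' `E(2)` (6+10MV) against a 6MV reference; T and N stage expand analogously
#' against T0/T1 and N0 references. Records with missing values for any
#' requested factor are rejected with an error (complete-case policy).
#'
#' @param cohort Cohort data frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param metrics Per-patient dosimetric metrics data frame with a
#'   `patient_id` column plus `MLD`, `IV*` and `AIV*` columns (see
#'   [metrics_table()]). May be `NULL` when no dosimetric factor is requested.
#' @param factors Character vector of factor names to encode, default all 31.
#' @return A numeric matrix of class `"factor_matrix"`, one row per patient
#'   (rownames = `patient_id`), with a `column_meta` attribute describing each
#'   column (factor, type, level, reference, units).
#' @export
encode_factors <- function(cohort, metrics = NULL,
                           factors = candidate_factor_names()) {
  reg <- candidate_factors()
  reg <- reg[match(factors, reg$name), , drop = FALSE]
  n <- nrow(cohort)
  need_dosi <- any(reg$source == "dosimetric")
  if (need_dosi) {
    if (is.null(metrics)) {
      stop("dosimetric factors requested but `metrics` is NULL", call. = FALSE)
    }
    idx <- match(cohort$patient_id, metrics$patient_id)
    if (anyNA(idx)) {
      stop("missing dosimetric metrics for patient(s): ",
           paste(cohort$patient_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    metrics <- metrics[idx, , drop = FALSE]
  }

  cols <- list()
  meta <- list()
  add <- function(values, column, fac, type, level, reference, units) {
    if (anyNA(values)) {
      bad <- cohort$patient_id[is.na(values)]
      stop(sprintf("missing values for factor '%s' in patient(s): %s",
                   fac, paste(bad, collapse = ", ")), call. = FALSE)
    }
    cols[[column]] <<- as.numeric(values)
    meta[[column]] <<- data.frame(
      column = column, factor = fac, type = type, level = level,
      reference = reference, units = units, stringsAsFactors = FALSE
    )
  }
  indicator <- function(x, level) as.numeric(x == level)

  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    units <- reg$units[i]
    switch(nm,
      Age = add(cohort$age, "Age", nm, "continuous", NA, NA, units),
      BMI = add(cohort$bmi, "BMI", nm, "continuous", NA, NA, units),
      Lung_d = add(cohort$lung_d, "Lung_d", nm, "continuous", NA, NA, units),
      Total_d = add(cohort$total_d, "Total_d", nm, "continuous", NA, NA, units),
      Tumor_site = add(indicator(cohort$tumor_site, "right"), "Tumor_site",
                       nm, "indicator", "right", "left", units),
      Chemotherapy = add(indicator(cohort$chemotherapy, "yes"), "Chemotherapy",
                         nm, "indicator", "yes", "no", units),
      IMN = add(indicator(cohort$imn, "yes"), "IMN", nm, "indicator",
                "yes", "no", units),
      SCF = add(indicator(cohort$scf, "yes"), "SCF", nm, "indicator",
                "yes", "no", units),
      Surgery = add(indicator(cohort$surgery, "MRM"), "Surgery", nm,
                    "indicator", "MRM", "PM", units),
      Energy = {
        add(indicator(cohort$energy, "10MV"), "E(1)", nm, "indicator",
            "10MV", "6MV", units)
        add(indicator(cohort$energy, "6+10MV"), "E(2)", nm, "indicator",
            "6+10MV", "6MV", units)
      },
      T_stage = {
        add(indicator(cohort$t_stage, 1L), "T(1)", nm, "indicator",
            "T2", "T0/T1", units)
        add(indicator(cohort$t_stage, 2L), "T(2)", nm, "indicator",
            "T3/T4", "T0/T1", units)
      },
      N_stage = {
        add(indicator(cohort$n_stage, 1L), "N(1)", nm, "indicator",
            "N1", "N0", units)
        add(indicator(cohort$n_stage, 2L), "N(2)", nm, "indicator",
            "N2/N3", "N0", units)
      },
      # dosimetric factors: column of the same name in the metrics table
      {
        if (!nm %in% names(metrics)) {
          stop(sprintf("metrics table lacks column '%s'", nm), call. = FALSE)
        }
        add(metrics[[nm]], nm, nm, "continuous", NA, NA, units)
      }
    )
  }

  x <- do.call(cbind, cols)
  rownames(x) <- cohort$patient_id
  attr(x, "column_meta") <- do.call(rbind, meta)
  attr(x, "factors") <- factors
  class(x) <- c("factor_matrix", class(x))
  x
}

# remove zero-variance columns (e.g. indicator levels absent from a small
# cohort), keeping the column metadata in step; factors whose every column
# drops are removed from the factor list
drop_zero_variance <- function(x) {
  meta <- attr(x, "column_meta")
  factors <- attr(x, "factors")
  sds <- apply(x, 2, function(col) sqrt(mean((col - mean(col))^2)))
  keep <- sds > 1e-12
  if (all(keep)) return(x)
  dropped <- colnames(x)[!keep]
  out <- unclass(x)[, keep, drop = FALSE]
  meta <- meta[meta$column %in% colnames(out), , drop = FALSE]
  attr(out, "column_meta") <- meta
  attr(out, "factors") <- factors[factors %in% meta$factor]
  attr(out, "dropped_columns") <- dropped
  class(out) <- c("factor_matrix", class(out))
  warning("dropped zero-variance column(s): ",
          paste(dropped, collapse = ", "), call. = FALSE)
  out
}

# columns of a factor_matrix belonging to the given factor names, in order
columns_for_factors <- function(x, factors) {
  meta <- attr(x, "column_meta")
  if (is.null(meta)) stop("not a factor_matrix: no column_meta", call. = FALSE)
  unlist(lapply(factors, function(f) meta$column[meta$factor == f]),
         use.names = FALSE)
}
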