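cohort_fields <- function() {
  c("patient_id", "age", "bmi", "lung_d", "total_d", "tumor_site",
    "chemotherapy", "energy", "imn", "scf", "surgery", "t_stage", "n_stage",
    "density_grade", "symptom_grade")
}

#' CSV dialect for cohort files
#'
#' Controls how [read_cohort()] maps file headers onto the patient-record
#' fields and which plausibility bounds are enforced.
#'
#' @param sep Field separator.
#' @param columns Named character vector mapping record fields to file
#'   headers; defaults to identity.
#' @param age_range Plausible age bounds (years); ages outside raise a
#'   validation warning, not an error.
#' @return A list of class `"cohort_dialect"`.
#' @export
cohort_dialect <- function(sep = ",", columns = NULL, age_range = c(18, 110)) {
  fields <- cohort_fields()
  map <- stats::setNames(fields, fields)
  if (!is.null(columns)) map[names(columns)] <- columns
  structure(list(sep = sep, columns = map, age_range = age_range),
            class = "cohort_dialect")
}

enum_levels <- list(
  tumor_site = c("left", "right"),
  chemotherapy = c("no", "yes"),
  imn = c("no", "yes"),
  scf = c("no", "yes"),
  surgery = c("PM", "MRM"),
  energy = c("6MV", "10MV", "6+10MV")
)

normalize_enum <- function(x, field) {
  lev <- enum_levels[[field]]
  raw <- gsub("[[:space:]]", "", as.character(x))
  key <- toupper(raw)
  tab <- stats::setNames(lev, toupper(lev))
  # numeric codings per the published footnotes (0 = first level, ...)
  tab[as.character(seq_along(lev) - 1L)] <- lev
  if (identical(field, "energy")) tab[["6MV+10MV"]] <- "6+10MV"
  out <- unname(tab[key])
  bad <- which(is.na(out) | !nzchar(raw))
  attr(out, "bad_rows") <- bad
  out
}

#' Read a patient cohort from CSV
#'
#' One row per patient. Categorical fields are normalized case-insensitively
#' and also accept the published 0/1(/2) numeric codings. Grades and stage
#' groups must be within their enumerations; violations are hard errors that
#' name the offending column and row.
#'
#' @param path CSV file path.
#' @param dialect A [cohort_dialect()].
#' @return A cohort data frame (one row per patient) with normalized fields.
#' @export
read_cohort <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  map <- dialect$columns
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- stats::setNames(raw[, map, drop = FALSE], names(map))
  as_cohort(cohort, age_range = dialect$age_range)
}

# validate and normalize an in-memory cohort data frame
as_cohort <- function(cohort, age_range = c(18, 110)) {
  cohort$patient_id <- as.character(cohort$patient_id)
  for (f in names(enum_levels)) {
    v <- normalize_enum(cohort[[f]], f)
    bad <- attr(v, "bad_rows")
    if (length(bad)) {
      stop(sprintf("invalid value '%s' for '%s' at row %d", cohort[[f]][bad[1]],
                   f, bad[1]), call. = FALSE)
    }
    cohort[[f]] <- as.vector(v)
  }
  int_fields <- list(t_stage = 0:2, n_stage = 0:2,
                     density_grade = 0:3, symptom_grade = 0:2)
  for (f in names(int_fields)) {
    v <- suppressWarnings(as.integer(cohort[[f]]))
    bad <- which(is.na(v) | !v %in% int_fields[[f]])
    if (length(bad)) {
      stop(sprintf("invalid value '%s' for '%s' at row %d", cohort[[f]][bad[1]],
                   f, bad[1]), call. = FALSE)
    }
    cohort[[f]] <- v
  }
  for (f in c("age", "bmi", "lung_d", "total_d")) {
    cohort[[f]] <- as.numeric(cohort[[f]])
  }
  out_of_range <- !is.na(cohort$age) &
    (cohort$age < age_range[1] | cohort$age > age_range[2])
  if (any(out_of_range)) {
    warning(sprintf("%d patient(s) with age outside [%g, %g]: %s",
                    sum(out_of_range), age_range[1], age_range[2],
                    paste(cohort$patient_id[out_of_range], collapse = ", ")),
            call. = FALSE)
  }
  rownames(cohort) <- NULL
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] under the default dialect; output is
#' deterministic for a given cohort.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort[, intersect(cohort_fields(), names(cohort)), drop = FALSE],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive the SRP endpoint from outcome grades
#'
#' A patient is an SRP case (endpoint 1) if and only if the CT density-change
#' grade is >= 1 *and* the symptomatic pneumonitis grade is >= 1; an
#' asymptomatic density change or symptoms without a density change do not
#' qualify.
#'
#' @param density_grade Integer vector of density-change grades (0-3), or a
#'   cohort data frame containing `density_grade` and `symptom_grade`.
#' @param symptom_grade Integer vector of symptom grades (0-2); ignored when
#'   `density_grade` is a data frame.
#' @return Integer 0/1 vector, one value per patient.
#' @export
derive_srp <- function(density_grade, symptom_grade = NULL) {
  if (is.data.frame(density_grade)) {
    symptom_grade <- density_grade$symptom_grade
    density_grade <- density_grade$density_grade
  }
  if (anyNA(density_grade) || anyNA(symptom_grade)) {
    stop("outcome grades must not be missing", call. = FALSE)
  }
  as.integer(density_grade >= 1 & symptom_grade >= 1)
}

#' Complete-case filter with a rejection report
#'
#' Drops patients with missing values in any of the listed fields and reports
#' who was dropped and why. The modelling stages assume complete cases.
#'
#' @param cohort Cohort data frame.
#' @param fields Fields to check; defaults to all record fields.
#' @return List with `kept` (filtered cohort) and `rejected` (data frame of
#'   `patient_id`, `reason`).
#' @export
complete_cases <- function(cohort, fields = setdiff(cohort_fields(), "patient_id")) {
  fields <- intersect(fields, names(cohort))
  reasons <- vapply(seq_len(nrow(cohort)), function(i) {
    miss <- fields[vapply(fields, function(f) is.na(cohort[[f]][i]), logical(1))]
    if (length(miss)) paste("missing:", paste(miss, collapse = ", ")) else ""
  }, character(1))
  drop <- nzchar(reasons)
  list(
    kept = cohort[!drop, , drop = FALSE],
    rejected = data.frame(patient_id = cohort$patient_id[drop],
                          reason = reasons[drop], stringsAsFactors = FALSE)
  )
}
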