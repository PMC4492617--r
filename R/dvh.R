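#' Cumulative dose-volume histogram
#'
#' Container for a cumulative DVH: for each dose edge `d` (Gy), the organ
#' volume (cc) receiving at least `d`. Edges must start at 0 and be equally
#' spaced at `bin_width` (default 0.01 Gy, the planning-system export
#' resolution); the volume column must be non-increasing and non-negative.
#'
#' @param dose Numeric vector of dose edges in Gy.
#' @param volume_cc Numeric vector of cumulative volumes in cc, same length.
#' @param organ Organ label.
#' @return Object of class `"cumulative_dvh"`.
#' @export
cumulative_dvh <- function(dose, volume_cc, organ = "ipsilateral lung") {
  dose <- as.numeric(dose)
  volume_cc <- as.numeric(volume_cc)
  if (length(dose) < 2L || length(dose) != length(volume_cc)) {
    stop("dose and volume_cc must be equal-length vectors (>= 2 points)",
         call. = FALSE)
  }
  if (abs(dose[1]) > 1e-9) stop("dose edges must start at 0 Gy", call. = FALSE)
  steps <- diff(dose)
  bin_width <- steps[1]
  if (bin_width <= 0 || any(abs(steps - bin_width) > 1e-9)) {
    stop("dose edges must be strictly increasing and equally spaced",
         call. = FALSE)
  }
  neg <- which(volume_cc < 0)
  if (length(neg)) {
    stop("negative volume at row ", neg[1], call. = FALSE)
  }
  up <- which(diff(volume_cc) > 1e-9)
  if (length(up)) {
    stop("cumulative volume increases at row ", up[1] + 1L, call. = FALSE)
  }
  structure(
    list(dose = dose, volume_cc = volume_cc, bin_width = bin_width,
         total_volume = volume_cc[1], organ = organ),
    class = "cumulative_dvh"
  )
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH (%s): %d edges, bin %g Gy, total %.2f cc, max %.2f Gy\n",
              x$organ, length(x$dose), x$bin_width, x$total_volume,
              max(x$dose)))
  invisible(x)
}

#' Read a cumulative DVH from CSV
#'
#' Expects two columns, dose (Gy) and cumulative volume (cc), one file per
#' patient. Validation errors cite the first offending row.
#'
#' @param path CSV path.
#' @param header Whether the file has a header row.
#' @param organ Organ label to attach.
#' @return A [cumulative_dvh()].
#' @export
read_dvh <- function(path, header = TRUE, organ = "ipsilateral lung") {
  if (!file.exists(path)) stop("DVH file not found: ", path, call. = FALSE)
  d <- read.csv(path, header = header, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("DVH file must have two columns (dose, volume)",
                         call. = FALSE)
  cumulative_dvh(d[[1]], d[[2]], organ = organ)
}

#' Write a cumulative DVH to CSV
#'
#' @param dvh A [cumulative_dvh()].
#' @param path Output path.
#' @export
write_dvh <- function(dvh, path) {
  lines <- c("dose_gy,cumulative_volume_cc",
             sprintf("%.6f,%.6f", dvh$dose, dvh$volume_cc))
  writeLines(lines, path)
  invisible(path)
}

#' Volume receiving at least a threshold dose
#'
#' Evaluates the cumulative DVH at an arbitrary threshold by linear
#' interpolation between the bracketing dose edges; thresholds beyond the
#' last edge return 0.
#'
#' @param dvh A [cumulative_dvh()].
#' @param threshold Dose threshold in Gy (>= 0).
#' @param mode `"percent"` of total organ volume or `"absolute"` (cc).
#' @return Scalar volume in % or cc.
#' @export
v_dose <- function(dvh, threshold, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  v <- approx(dvh$dose, dvh$volume_cc, xout = threshold,
              yleft = dvh$total_volume, yright = 0, ties = "ordered")$y
  if (mode == "absolute") return(v)
  if (dvh$total_volume <= 0) stop("zero total volume", call. = FALSE)
  100 * v / dvh$total_volume
}

#' Mean dose to the organ
#'
#' Volume-weighted mean dose computed from the differential DVH (successive
#' differences of the cumulative curve), placing each bin's volume at the bin
#' midpoint. Any volume still present at the last edge is treated as a point
#' mass at that dose.
#'
#' @param dvh A [cumulative_dvh()].
#' @return Mean dose in Gy.
#' @export
mean_lung_dose <- function(dvh) {
  if (dvh$total_volume <= 0) stop("zero total volume", call. = FALSE)
  dv <- -diff(dvh$volume_cc)
  mid <- (dvh$dose[-1] + dvh$dose[-length(dvh$dose)]) / 2
  tail_v <- dvh$volume_cc[length(dvh$volume_cc)]
  (sum(mid * dv) + tail_v * dvh$dose[length(dvh$dose)]) / dvh$total_volume
}

#' Dosimetric factor set of one DVH
#'
#' Mean lung dose plus relative (IV, %) and absolute (AIV, cc) volumes at the
#' nine standard thresholds.
#'
#' @param dvh A [cumulative_dvh()].
#' @param thresholds Dose thresholds in Gy.
#' @return Object of class `"dose_volume_metrics"`: list with `mld`, named
#'   vectors `iv` and `aiv`, `total_volume` and `thresholds`.
#' @export
compute_metrics <- function(dvh, thresholds = iv_thresholds()) {
  iv <- vapply(thresholds, function(t) v_dose(dvh, t, "percent"), numeric(1))
  aiv <- vapply(thresholds, function(t) v_dose(dvh, t, "absolute"), numeric(1))
  names(iv) <- names(aiv) <- as.character(thresholds)
  structure(
    list(mld = mean_lung_dose(dvh), iv = iv, aiv = aiv,
         total_volume = dvh$total_volume, thresholds = thresholds),
    class = "dose_volume_metrics"
  )
}

#' @export
print.dose_volume_metrics <- function(x, ...) {
  cat(sprintf("MLD %.2f Gy; IV20 %.1f%%; AIV20 %.1f cc; total %.1f cc\n",
              x$mld, x$iv[["20"]], x$aiv[["20"]], x$total_volume))
  invisible(x)
}

metrics_row <- function(m) {
  thr <- m$thresholds
  vals <- c(m$mld, m$iv, m$aiv)
  names(vals) <- c("MLD", paste0("IV", thr), paste0("AIV", thr))
  vals
}

#' Per-patient dosimetric metrics table
#'
#' @param dvhs Named list of [cumulative_dvh()] objects keyed by patient id.
#' @return Data frame with `patient_id` and one column per dosimetric factor
#'   (`MLD`, `IV5`..`IV50`, `AIV5`..`AIV50`).
#' @export
metrics_table <- function(dvhs) {
  rows <- lapply(dvhs, function(d) metrics_row(compute_metrics(d)))
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(patient_id = names(dvhs), stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Read a DVH manifest and all referenced DVH files
#'
#' The manifest is a CSV with columns `patient_id` and `path` (relative to
#' the manifest's directory unless absolute).
#'
#' @param path Manifest CSV path.
#' @return Named list of [cumulative_dvh()] objects keyed by patient id.
#' @export
read_dvh_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "path") %in% names(man))) {
    stop("manifest must have columns patient_id, path", call. = FALSE)
  }
  base <- dirname(path)
  dvhs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_dvh(p)
  })
  names(dvhs) <- man$patient_id
  dvhs
}
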