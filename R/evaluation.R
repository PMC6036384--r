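# Accuracy and repeatability reports over sets of detections.

is_detection <- function(x) inherits(x, "fiducial_detection")

#' Detection rate over a list of segmentation outcomes
#'
#' @param results List whose elements are `fiducial_detection` objects for
#'   successes and anything else (error conditions, `NULL`, `try-error`) for
#'   failures.
#' @return List with `rate` (successes / attempts), `n`, `successes`, and a
#'   per-sequence breakdown when sequence names are available.
#' @export
detection_rate <- function(results) {
  if (length(results) == 0) stop("no results")
  ok <- vapply(results, is_detection, logical(1))
  seqs <- vapply(seq_along(results), function(i) {
    nm <- if (ok[i]) results[[i]]$meta$sequence else attr(results[[i]], "sequence")
    if (is.null(nm)) names(results)[i] %||% NA_character_ else nm
  }, character(1))
  by_seq <- NULL
  if (!all(is.na(seqs))) {
    by_seq <- stats::aggregate(ok, by = list(sequence = seqs),
                               FUN = function(x) sum(x) / length(x))
    names(by_seq)[2] <- "rate"
  }
  list(rate = sum(ok) / length(ok), n = length(ok), successes = sum(ok),
       by_sequence = by_seq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inter-marker spacing accuracy report
#'
#' For every detection, the six measured pairwise center-of-mass distances
#' are compared, label pair by label pair, with the true template
#' separations. Signed differences are aggregated per (sequence, pair) as
#' mean +/- SD; the global summary is the mean +/- SD of the absolute
#' differences pooled over all detections and pairs.
#'
#' @param detections List of `fiducial_detection` (failures allowed; they
#'   only lower the detection rate).
#' @param template A `fiducial_template`.
#' @return An object of class `spacing_report`: `per_pair` data.frame
#'   (sequence, pair, true_mm, mean_diff_mm, sd_diff_mm, n),
#'   `differences` (raw per-detection signed differences),
#'   `global_mean_abs_mm`, `global_sd_abs_mm`, `detection_rate`.
#' @export
spacing_accuracy <- function(detections, template) {
  stopifnot(inherits(template, "fiducial_template"))
  ok <- vapply(detections, is_detection, logical(1))
  if (!any(ok)) stop("no successful detections")
  true_d <- pair_distances(template$points)
  rows <- do.call(rbind, lapply(which(ok), function(i) {
    det <- detections[[i]]
    meas <- pair_distances(det$marker_coms)
    data.frame(detection = i,
               sequence = det$meta$sequence %||% "unknown",
               pair = names(true_d),
               true_mm = as.numeric(true_d),
               measured_mm = as.numeric(meas),
               diff_mm = as.numeric(meas - true_d))
  }))
  per_pair <- stats::aggregate(diff_mm ~ sequence + pair + true_mm, rows,
                               function(x) c(mean = mean(x), sd = stats::sd(x),
                                             n = length(x)))
  per_pair <- data.frame(per_pair[1:3],
                         mean_diff_mm = per_pair$diff_mm[, "mean"],
                         sd_diff_mm = per_pair$diff_mm[, "sd"],
                         n = per_pair$diff_mm[, "n"])
  structure(list(per_pair = per_pair,
                 differences = rows,
                 global_mean_abs_mm = mean(abs(rows$diff_mm)),
                 global_sd_abs_mm = stats::sd(abs(rows$diff_mm)),
                 detection_rate = sum(ok) / length(ok)),
            class = "spacing_report")
}

#' @export
print.spacing_report <- function(x, ...) {
  cat("<spacing_report>\n")
  cat(sprintf("  detections: %d pair measurements, detection rate %.2f\n",
              nrow(x$differences), x$detection_rate))
  cat(sprintf("  global |measured - true|: %.3f +/- %.3f mm\n",
              x$global_mean_abs_mm, x$global_sd_abs_mm))
  invisible(x)
}

#' Repeatability report against a baseline detection
#'
#' Differences of each detection's device center-of-mass (per axis and
#' Euclidean norm, after removing the commanded shift recorded for that
#' acquisition) and orientation angles versus a baseline detection.
#'
#' @param detections Named list of `fiducial_detection`.
#' @param baseline The baseline `fiducial_detection`.
#' @param commanded_shifts Optional list (same names/length as `detections`)
#'   of commanded translations; defaults to each detection's
#'   `meta$commanded_shift` (zero when absent).
#' @return An object of class `repeatability_report`: `table` data.frame
#'   with dX/dY/dZ/dCOM (mm) and dTheta/dPhi (degrees) per acquisition, and
#'   `max_com_mm`, `max_angle_deg`, `mean_com_mm` summaries.
#' @export
repeatability <- function(detections, baseline, commanded_shifts = NULL) {
  stopifnot(is_detection(baseline))
  ok <- vapply(detections, is_detection, logical(1))
  rows <- do.call(rbind, lapply(which(ok), function(i) {
    det <- detections[[i]]
    shift <- if (!is.null(commanded_shifts)) commanded_shifts[[i]]
             else det$meta$commanded_shift %||% c(0, 0, 0)
    pd <- pose_difference(baseline, det, commanded_shift = as.numeric(shift))
    data.frame(acquisition = names(detections)[i] %||% as.character(i),
               dX = pd$delta_com[1], dY = pd$delta_com[2],
               dZ = pd$delta_com[3], dCOM = pd$delta_com_norm,
               dTheta = pd$delta_theta, dPhi = pd$delta_phi)
  }))
  structure(list(table = rows,
                 baseline_com = baseline$device_com,
                 baseline_angles = c(theta = baseline$theta,
                                     phi = baseline$phi),
                 max_com_mm = max(rows$dCOM),
                 mean_com_mm = mean(rows$dCOM),
                 max_angle_deg = max(abs(c(rows$dTheta, rows$dPhi))),
                 n_failed = sum(!ok)),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("<repeatability_report>\n")
  print(transform(x$table,
                  dX = round(dX, 2), dY = round(dY, 2), dZ = round(dZ, 2),
                  dCOM = round(dCOM, 2), dTheta = round(dTheta, 3),
                  dPhi = round(dPhi, 3)), row.names = FALSE)
  cat(sprintf("  max |dCOM| = %.2f mm (mean %.2f), max |dAngle| = %.3f deg\n",
              x$max_com_mm, x$mean_com_mm, x$max_angle_deg))
  if (x$n_failed > 0)
    cat("  failed detections:", x$n_failed, "\n")
  invisible(x)
}

#' Write a report to JSON or CSV
#'
#' JSON serializes the full report; CSV writes the tabular part (`per_pair`
#' for spacing reports, `table` for repeatability reports). Either format
#' round-trips the tabular content losslessly.
#'
#' @param report A `spacing_report` or `repeatability_report`.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- if (inherits(report, "spacing_report")) report$per_pair
           else report$table
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  invisible(path)
}
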