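#' Methods for fiducial detections
#'
#' A `fiducial_detection` (returned by [segment_fiducial()]) behaves like a
#' fitted-model object: `print` gives a one-screen report, `summary` adds the
#' stage diagnostics, `coef` returns the four labeled marker
#' centers-of-mass, `residuals` the per-marker residual vectors of the rigid
#' template fit, and `plot` draws the matched constellation in two world
#' projections.
#'
#' @param x,object A `fiducial_detection`.
#' @param ... Unused.
#' @name fiducial_detection-methods
NULL

#' @rdname fiducial_detection-methods
#' @export
print.fiducial_detection <- function(x, ...) {
  cat("<fiducial_detection>\n")
  if (!is.null(x$meta$sequence))
    cat("  sequence:", x$meta$sequence, "\n")
  cat(sprintf("  device COM (LPS mm): (%.2f, %.2f, %.2f)\n",
              x$device_com[1], x$device_com[2], x$device_com[3]))
  cat(sprintf("  orientation: theta = %.2f deg, phi = %.2f deg%s\n",
              x$theta, x$phi,
              if (isTRUE(x$phi_degenerate)) " (azimuth degenerate at pole)" else ""))
  cat(sprintf("  matched at tolerance %.0f mm, RMS separation error %.3f mm\n",
              x$match_tolerance, x$rigid_fit$rms))
  invisible(x)
}

#' @rdname fiducial_detection-methods
#' @export
summary.fiducial_detection <- function(object, ...) {
  structure(list(detection = object), class = "summary.fiducial_detection")
}

#' @export
print.summary.fiducial_detection <- function(x, ...) {
  d <- x$detection
  print(d)
  cat("  marker centers-of-mass (LPS mm):\n")
  print(round(d$marker_coms, 3))
  dg <- d$diagnostics
  cat(sprintf("  noise threshold N_T = %d (histogram peak at %d)\n",
              dg$noise_threshold, dg$histogram_peak))
  cat(sprintf("  reference threshold R_T = %.1f\n", dg$reference_threshold))
  cat(sprintf("  candidates: %d connected sets at N_T, %d after iterations, %d after shape gate\n",
              dg$n_reference_sets, dg$n_candidates, dg$n_after_shape))
  if (any(dg$boundary_markers))
    cat("  warning: matched marker(s) touch the volume boundary\n")
  invisible(x)
}

#' @rdname fiducial_detection-methods
#' @export
coef.fiducial_detection <- function(object, ...) object$marker_coms

#' @rdname fiducial_detection-methods
#' @export
residuals.fiducial_detection <- function(object, ...) object$rigid_fit$residuals

#' @rdname fiducial_detection-methods
#' @export
plot.fiducial_detection <- function(x, ...) {
  p <- x$marker_coms
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lab <- rownames(p)
  for (axes in list(c(1, 2), c(1, 3))) {
    nm <- c("x (L)", "y (P)", "z (S)")[axes]
    graphics::plot(p[, axes[1]], p[, axes[2]], pch = 19, asp = 1,
                   xlab = paste(nm[1], "[mm]"), ylab = paste(nm[2], "[mm]"),
                   main = paste(nm[1], "vs", nm[2]), ...)
    graphics::text(p[, axes[1]], p[, axes[2]], lab, pos = 3)
    for (pr in list(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4)))
      graphics::segments(p[pr[1], axes[1]], p[pr[1], axes[2]],
                         p[pr[2], axes[1]], p[pr[2], axes[2]], col = "grey60")
    cm <- colMeans(p)
    graphics::points(cm[axes[1]], cm[axes[2]], pch = 3, col = "red")
  }
  invisible(x)
}

#' Write a detection to JSON
#'
#' Serializes marker and device coordinates, orientation, matching
#' tolerance, and diagnostics to a JSON file that round-trips through
#' [read_detection()].
#'
#' @param det A `fiducial_detection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detection <- function(det, path) {
  stopifnot(inherits(det, "fiducial_detection"))
  out <- list(
    marker_coms = as.data.frame(det$marker_coms),
    device_com = det$device_com,
    normal = det$normal,
    theta = det$theta,
    phi = det$phi,
    phi_degenerate = det$phi_degenerate,
    match_tolerance = det$match_tolerance,
    rigid = list(rotation = det$rigid_fit$rotation,
                 translation = det$rigid_fit$translation,
                 rms = det$rigid_fit$rms),
    diagnostics = det$diagnostics[c("noise_threshold", "reference_threshold",
                                    "n_candidates", "n_after_shape",
                                    "match_rms")],
    meta = det$meta[intersect(names(det$meta),
                              c("sequence", "plane", "commanded_shift",
                                "slice_thickness", "slice_gap", "seed"))]
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a detection written by [write_detection()]
#'
#' @param path JSON file path.
#' @return A `fiducial_detection` (geometry fields only; voxel-level members
#'   are not serialized).
#' @export
read_detection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mc <- as.matrix(j$marker_coms)
  rownames(mc) <- c("A", "B", "C", "D")
  colnames(mc) <- c("x", "y", "z")
  structure(list(
    marker_coms = mc,
    device_com = as.numeric(j$device_com),
    normal = as.numeric(j$normal),
    theta = j$theta, phi = j$phi, phi_degenerate = j$phi_degenerate,
    match_tolerance = j$match_tolerance,
    rigid_fit = list(rotation = matrix(unlist(j$rigid$rotation), 3, 3),
                     translation = as.numeric(j$rigid$translation),
                     rms = j$rigid$rms,
                     residuals = NULL),
    diagnostics = j$diagnostics,
    meta = j$meta
  ), class = "fiducial_detection")
}
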