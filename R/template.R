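#' Ideal fiducial device constellation
#'
#' Builds the four-marker device template from its manufactured dimensions:
#' three cylindrical markers at the vertices of a scalene base triangle plus a
#' fourth marker on the line through the base centroid, perpendicular to the
#' base. The scalene design makes all six pairwise separations distinct, so a
#' matched constellation can be labeled unambiguously.
#'
#' Canonical placement: the base lies in the z = 0 plane with vertex A at the
#' origin, B on the +x axis, and C at positive y; the apex D is on +z. Vertex
#' labels are fixed by opposite-side ordering: the side opposite A is the
#' shortest base side, opposite B the middle, opposite C the longest.
#'
#' @param base_sides Three base-triangle side lengths in mm
#'   (default `c(50.7, 69.2, 88.9)`). Order is irrelevant; they are sorted.
#' @param apex_height Height of the apex marker above the base centroid, mm.
#' @param marker_diameter Inner diameter of a marker cylinder, mm.
#' @param marker_depth Depth of a marker cylinder, mm.
#' @param v_marker Optional override of the nominal marker signal volume in
#'   mm^3; by default `pi * (marker_diameter/2)^2 * marker_depth`. The
#'   segmentation size windows scale from this value.
#' @return An object of class `fiducial_template` with fields `points`
#'   (4 x 3 matrix, rows A, B, C, D), `separations` (six pairwise distances,
#'   sorted decreasing), `v_marker`, `longest_dim`
#'   (`sqrt(marker_diameter^2 + marker_depth^2)`), and the input dimensions.
#' @examples
#' t <- fiducial_template()
#' template_distances(t)
#' @export
fiducial_template <- function(base_sides = c(50.7, 69.2, 88.9),
                              apex_height = 12.7,
                              marker_diameter = 12.7,
                              marker_depth = 12.7,
                              v_marker = NULL) {
  if (length(base_sides) != 3 || any(base_sides <= 0))
    stop("`base_sides` must be three positive lengths")
  if (apex_height < 0 || marker_diameter <= 0 || marker_depth <= 0)
    stop("marker dimensions must be positive (apex_height >= 0)")
  s <- sort(base_sides)                     # shortest, middle, longest
  # side opposite A = s[1], opposite B = s[2], opposite C = s[3]
  a <- s[1]; b <- s[2]; cl <- s[3]
  for (tri in list(c(a, b, cl), c(b, cl, a), c(cl, a, b))) {
    if (tri[1] + tri[2] <= tri[3])
      stop(sprintf("degenerate triangle: %g + %g <= %g", tri[1], tri[2], tri[3]))
  }
  # |AB| = side opposite C = longest; |AC| = side opposite B = middle;
  # |BC| = side opposite A = shortest.
  A <- c(0, 0, 0)
  B <- c(cl, 0, 0)
  cx <- (cl^2 + b^2 - a^2) / (2 * cl)
  C <- c(cx, sqrt(b^2 - cx^2), 0)
  D <- (A + B + C) / 3 + c(0, 0, apex_height)
  points <- rbind(A = A, B = B, C = C, D = D)
  colnames(points) <- c("x", "y", "z")
  if (is.null(v_marker))
    v_marker <- pi * (marker_diameter / 2)^2 * marker_depth
  structure(list(
    points = points,
    base_sides = s,
    apex_height = apex_height,
    marker_diameter = marker_diameter,
    marker_depth = marker_depth,
    v_marker = v_marker,
    longest_dim = sqrt(marker_diameter^2 + marker_depth^2),
    separations = sort(pair_distances(points), decreasing = TRUE)
  ), class = "fiducial_template")
}

# six pairwise distances of a 4 x 3 point matrix, canonical pair order
# AB, AC, AD, BC, BD, CD
pair_distances <- function(points) {
  pairs <- utils::combn(4, 2)
  d <- apply(pairs, 2, function(p)
    sqrt(sum((points[p[1], ] - points[p[2], ])^2)))
  names(d) <- apply(pairs, 2, function(p)
    paste0(rownames(points)[p[1]], rownames(points)[p[2]]))
  d
}

#' Six pairwise marker separations
#'
#' The matching signature of the device: the six inter-marker distances,
#' sorted in decreasing order.
#'
#' @param t A `fiducial_template`.
#' @return Numeric vector of six distances (mm), decreasing.
#' @export
template_distances <- function(t) {
  stopifnot(inherits(t, "fiducial_template"))
  sort(pair_distances(t$points), decreasing = TRUE)
}

#' @export
print.fiducial_template <- function(x, ...) {
  cat("<fiducial_template>\n")
  cat(sprintf("  base sides: %.1f / %.1f / %.1f mm, apex %.1f mm above centroid\n",
              x$base_sides[1], x$base_sides[2], x$base_sides[3], x$apex_height))
  cat(sprintf("  marker: %.1f mm diameter x %.1f mm depth (V = %.1f mm^3, diagonal %.2f mm)\n",
              x$marker_diameter, x$marker_depth, x$v_marker, x$longest_dim))
  cat("  separations (mm):", paste(sprintf("%.1f", x$separations), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a template to a config list
#'
#' @param t A `fiducial_template`.
#' @return A named list suitable for the `device:` block of a YAML config.
#' @export
template_to_config <- function(t) {
  stopifnot(inherits(t, "fiducial_template"))
  list(base_sides = as.numeric(t$base_sides),
       apex_height = t$apex_height,
       marker_diameter = t$marker_diameter,
       marker_depth = t$marker_depth,
       v_marker = t$v_marker)
}

#' Build a template from a config list
#'
#' @param cfg Named list as produced by [template_to_config()]; missing
#'   entries fall back to the defaults of [fiducial_template()].
#' @return A `fiducial_template`.
#' @export
template_from_config <- function(cfg) {
  args <- cfg[intersect(names(cfg), names(formals(fiducial_template)))]
  do.call(fiducial_template, args)
}
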