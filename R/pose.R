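# Device pose: group center-of-mass, base-plane normal, spherical angles,
# and the rigid transform from the template frame.

unit <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}

#' Device pose from four labeled marker positions
#'
#' The device location is the unweighted mean of the four marker
#' centers-of-mass (the markers are physically identical, so intensity
#' weighting across markers would make the pose sequence-dependent). The
#' orientation is the unit normal of the base plane,
#' `unit((B - A) x (C - A))`, sign-corrected to point from the base toward
#' the apex D so that the reported angles do not depend on how the base
#' vertices are labeled. The normal is reported through its spherical angles
#' in the LPS frame: polar angle `theta = acos(n_z)` from +z (Superior), in
#' `[0, 180]` degrees, and azimuth `phi = atan2(n_y, n_x)` from +x (Left)
#' toward +y (Posterior), in `(-180, 180]` degrees. At the poles
#' (`theta = 0` or `180`) the azimuth is undefined and reported as 0 with
#' `phi_degenerate = TRUE`.
#'
#' @param marker_coms 4 x 3 matrix of world points with rows A, B, C, D.
#' @return List with `device_com`, `normal`, `theta`, `phi`,
#'   `phi_degenerate`.
#' @export
device_pose <- function(marker_coms) {
  stopifnot(is.matrix(marker_coms), all(dim(marker_coms) == c(4, 3)))
  A <- marker_coms[1, ]; B <- marker_coms[2, ]
  C <- marker_coms[3, ]; D <- marker_coms[4, ]
  u <- B - A; w <- C - A
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  if (sqrt(sum(n^2)) < 1e-9 * max(1, sqrt(sum(u^2)) * sqrt(sum(w^2))))
    fid_stop("device_pose", "base markers are collinear; normal undefined")
  n <- unit(n)
  if (sum(n * (D - (A + B + C) / 3)) < 0) n <- -n
  theta <- acos(max(-1, min(1, n[3]))) * 180 / pi
  degenerate <- sqrt(n[1]^2 + n[2]^2) < 1e-12
  phi <- if (degenerate) 0 else atan2(n[2], n[1]) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  list(device_com = colMeans(marker_coms), normal = n,
       theta = theta, phi = phi, phi_degenerate = degenerate)
}

#' Least-squares rigid alignment of the template to detected markers
#'
#' Solves the orthogonal Procrustes problem for labeled correspondences
#' (template points A-D to detected centers-of-mass A-D) with a proper
#' rotation (det = +1), via the SVD of the cross-covariance.
#'
#' @param template A `fiducial_template`.
#' @param marker_coms 4 x 3 labeled matrix of detected marker positions.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rms`
#'   residual in mm, and `residuals` (4 x 3 per-marker residual vectors).
#' @export
rigid_fit <- function(template, marker_coms) {
  stopifnot(inherits(template, "fiducial_template"),
            is.matrix(marker_coms), all(dim(marker_coms) == c(4, 3)))
  P <- template$points
  Q <- marker_coms
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2, pc)) %*% sweep(Q, 2, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0)
    fid_stop("rigid_fit", "degenerate point configuration")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (det(R) < 0)
    fid_stop("rigid_fit", "rigid fit yields a reflection; check marker labels")
  tr <- unname(qc - as.vector(R %*% pc))
  fitted <- t(R %*% t(P)) + matrix(tr, 4, 3, byrow = TRUE)
  res <- Q - fitted
  list(rotation = R, translation = tr,
       rms = sqrt(mean(rowSums(res^2))), residuals = res)
}

#' Pose difference between two detections
#'
#' Componentwise world differences of the device centers-of-mass (after
#' removing a known commanded translation, e.g. a table shift), the
#' Euclidean distance between them, and the differences of the orientation
#' angles.
#'
#' @param a,b `fiducial_detection` objects (difference is `b - a`).
#' @param commanded_shift Known translation applied to `b` relative to `a`
#'   (mm); subtracted before differencing.
#' @return List with `delta_com` (per axis, mm), `delta_com_norm` (mm),
#'   `delta_theta`, `delta_phi` (degrees).
#' @export
pose_difference <- function(a, b, commanded_shift = c(0, 0, 0)) {
  stopifnot(inherits(a, "fiducial_detection"),
            inherits(b, "fiducial_detection"))
  d <- b$device_com - a$device_com - commanded_shift
  dphi <- b$phi - a$phi
  if (dphi > 180) dphi <- dphi - 360
  if (dphi <= -180) dphi <- dphi + 360
  list(delta_com = d, delta_com_norm = sqrt(sum(d^2)),
       delta_theta = b$theta - a$theta, delta_phi = dphi)
}
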