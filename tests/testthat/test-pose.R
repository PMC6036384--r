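flat_coronal_points <- function(tpl = fiducial_template(),
                                shift = c(20, 21, 18)) {
  R <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  t(R %*% t(tpl$points)) + matrix(shift, 4, 3, byrow = TRUE)
}

test_that("a flat coronal base reports orientation angles (90, -90)", {
  p <- flat_coronal_points()
  pose <- device_pose(p)
  expect_equal(pose$theta, 90, tolerance = 1e-9)
  expect_equal(pose$phi, -90, tolerance = 1e-9)
  expect_equal(pose$normal, c(0, -1, 0), tolerance = 1e-12)
  expect_equal(pose$device_com, colMeans(p))
})

test_that("the pole reports a zero azimuth with a degeneracy flag", {
  pose <- device_pose(fiducial_template()$points)   # apex straight up +z
  expect_equal(pose$theta, 0, tolerance = 1e-9)
  expect_equal(pose$phi, 0)
  expect_true(pose$phi_degenerate)
})

test_that("the normal transforms covariantly under rigid rotations", {
  set.seed(17)
  p0 <- flat_coronal_points()
  n0 <- device_pose(p0)$normal
  for (rep in 1:15) {
    R <- random_rotation()
    n1 <- device_pose(t(R %*% t(p0)))$normal
    expect_lt(max(abs(n1 - as.vector(R %*% n0))), 1e-9)
  }
})

test_that("orientation angles do not depend on base vertex labeling", {
  p <- flat_coronal_points()
  base_perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3),
                     c(1, 3, 2), c(3, 2, 1))
  ref <- device_pose(p)
  for (bp in base_perms) {
    q <- p[c(bp, 4), ]
    rownames(q) <- c("A", "B", "C", "D")
    pose <- device_pose(q)
    expect_equal(pose$theta, ref$theta, tolerance = 1e-9)
    expect_equal(pose$phi, ref$phi, tolerance = 1e-9)
  }
})

test_that("collinear base markers are rejected", {
  p <- rbind(A = c(0, 0, 0), B = c(10, 0, 0), C = c(20, 0, 0),
             D = c(0, 0, 10))
  expect_error(device_pose(p), "collinear")
})

test_that("rigid fit recovers constructed transforms exactly", {
  tpl <- fiducial_template()
  f0 <- rigid_fit(tpl, tpl$points)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(f0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f0$rms, 0, tolerance = 1e-12)

  R <- rbind(c(cos(pi / 6), -sin(pi / 6), 0),
             c(sin(pi / 6), cos(pi / 6), 0),
             c(0, 0, 1))
  tr <- c(10, -5, 3)
  Q <- t(R %*% t(tpl$points)) + matrix(tr, 4, 3, byrow = TRUE)
  f <- rigid_fit(tpl, Q)
  expect_lt(max(abs(f$rotation - R)), 1e-9)
  expect_lt(max(abs(f$translation - tr)), 1e-9)
  expect_lt(f$rms, 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("noisy rigid fit is optimal against a rotation-sampling oracle", {
  tpl <- fiducial_template()
  set.seed(23)
  Q <- tpl$points + matrix(rnorm(12, sd = 0.3), 4, 3)
  f <- rigid_fit(tpl, Q)
  expect_lte(f$rms, 0.6)
  grid_rms <- quaternion_grid_rms(tpl$points, Q)
  expect_lte(f$rms, grid_rms + 1e-12)          # SVD solution is optimal
  expect_lt(grid_rms - f$rms, 0.1 * grid_rms)  # grid confirms within 10%
  # residuals reproduce the fit
  fitted <- t(f$rotation %*% t(tpl$points)) +
    matrix(f$translation, 4, 3, byrow = TRUE)
  expect_equal(unname(Q - fitted), unname(f$residuals), tolerance = 1e-12)
})

test_that("pose differences remove commanded shifts and self-compare to zero", {
  a <- fake_detection(flat_coronal_points())
  expect_equal(pose_difference(a, a)$delta_com_norm, 0)
  expect_equal(pose_difference(a, a)$delta_theta, 0)

  b <- fake_detection(flat_coronal_points(shift = c(20, 21, 48)))
  pd <- pose_difference(a, b, commanded_shift = c(0, 0, 30))
  expect_equal(pd$delta_com, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(pd$delta_com_norm, 0, tolerance = 1e-12)
  # and without compensation the difference is the shift itself
  expect_equal(pose_difference(a, b)$delta_com, c(0, 0, 30), tolerance = 1e-12)
})

test_that("pose differences match direct recomputation from marker sets", {
  set.seed(29)
  p1 <- flat_coronal_points() + matrix(rnorm(12, sd = 0.2), 4, 3)
  p2 <- flat_coronal_points() + matrix(rnorm(12, sd = 0.2), 4, 3)
  a <- fake_detection(p1); b <- fake_detection(p2)
  pd <- pose_difference(a, b)
  expect_equal(pd$delta_com, colMeans(p2) - colMeans(p1))
  expect_equal(pd$delta_theta, device_pose(p2)$theta - device_pose(p1)$theta)
})
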