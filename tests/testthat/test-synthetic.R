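test_that("acquisition presets carry the protocol geometry", {
  expect_length(acquisition_preset_names(), 8)
  lava <- acquisition_spec("lava")
  expect_equal(lava$in_plane_mm, c(0.7, 0.7))
  expect_equal(lava$slice_thickness_mm + lava$slice_gap_mm, 1.7)
  frfse <- acquisition_spec("frfse")
  expect_equal(frfse$slice_thickness_mm + frfse$slice_gap_mm, 7 + 1)
  expect_equal(acquisition_spec("ssfse")$scan_plane, "coronal")
  expect_error(acquisition_spec("nope"), "unknown preset")
  expect_error(acquisition_spec(signal_levels = c(air = 10, tissue = 5,
                                                  marker = 400)),
               "marker > tissue > air")
})

test_that("rasterized volumes expose the preset voxel geometry", {
  tpl <- fiducial_template()
  pose <- scene_pose(seed = 1)
  v <- rasterize_scene(tpl, pose, acquisition_spec("frfse", noise_sigma = 0),
                       seed = NULL)
  expect_equal(spacing(v), c(0.7, 0.7, 8), tolerance = 1e-9)
  expect_equal(v$meta$slice_gap, 1)
  vc <- rasterize_scene(tpl, pose, acquisition_spec("ssfse", noise_sigma = 0),
                        seed = NULL)
  expect_equal(spacing(vc), c(0.9, 0.9, 7), tolerance = 1e-9)
  # coronal: third grid axis runs along world y
  expect_equal(abs(vc$affine[1:3, 3]), c(0, 7, 0), tolerance = 1e-9)
})

test_that("rasterized marker volume approximates the analytic cylinder", {
  tpl <- fiducial_template()
  v <- rasterize_scene(tpl, tiny_full_size_pose(), lava_like_spec(),
                       seed = NULL)
  measured <- sum(v$data >= 200) * voxel_volume(v)  # half-maximum footprint
  expect_lt(abs(measured - 4 * tpl$v_marker), 0.15 * 4 * tpl$v_marker)
  # integrated signal is an even tighter estimate
  integral <- sum(as.numeric(v$data)) * voxel_volume(v) / 400
  expect_lt(abs(integral - 4 * tpl$v_marker), 0.05 * 4 * tpl$v_marker)
})

test_that("an empty scene rasterizes to an all-zero volume", {
  tpl <- fiducial_template()
  pose <- scene_pose(body_semiaxes = NULL, n_blobs = 0)
  spec <- acquisition_spec("custom", in_plane_mm = c(2, 2),
                           slice_thickness_mm = 5, slice_gap_mm = 0,
                           noise_sigma = 0)
  v <- rasterize_scene(tpl, pose, spec, seed = NULL, include_device = FALSE)
  expect_true(all(v$data == 0L))
})

test_that("volumes are bit-identical for a fixed seed", {
  tpl <- tiny_template()
  v1 <- rasterize_scene(tpl, tiny_pose(), tiny_spec(), seed = 42)
  v2 <- rasterize_scene(tpl, tiny_pose(), tiny_spec(), seed = 42)
  expect_identical(v1$data, v2$data)
  v3 <- rasterize_scene(tpl, tiny_pose(), tiny_spec(), seed = 43)
  expect_false(identical(v1$data, v3$data))
})

test_that("noise seeds change only the noise, not the recovered geometry", {
  tpl <- fiducial_template()
  pose <- scene_pose(seed = 1)
  spec <- acquisition_spec("spgr")
  d1 <- segment_fiducial(rasterize_scene(tpl, pose, spec, seed = 101), tpl)
  d2 <- segment_fiducial(rasterize_scene(tpl, pose, spec, seed = 202), tpl)
  # within one voxel (largest dimension: 5 mm slice + 1 mm gap)
  expect_lt(max(abs(coef(d1) - coef(d2))), 6)
})

test_that("slice gaps strictly remove sampled marker signal", {
  tpl <- fiducial_template()
  pose <- scene_pose(body_semiaxes = NULL, n_blobs = 0)
  # collected signal integrated over the sensitive volume only (the gap
  # contributes nothing, so dz in the voxel volume is the slice thickness)
  signal <- sapply(c(0, 2, 4), function(gap) {
    spec <- acquisition_spec("custom", in_plane_mm = c(1, 1),
                             slice_thickness_mm = 4, slice_gap_mm = gap,
                             noise_sigma = 0)
    v <- rasterize_scene(tpl, pose, spec, seed = NULL)
    sum(as.numeric(v$data)) * prod(c(1, 1, 4))
  })
  expect_true(all(diff(signal) < 0))
})

test_that("total marker signal is consistent across scan-plane rotations", {
  tpl <- fiducial_template()
  pose <- scene_pose(body_semiaxes = NULL, n_blobs = 0)
  planes <- list("axial", "coronal", rot_oblique <- {
    a <- 15 * pi / 180
    cbind(c(1, 0, 0), c(0, cos(a), sin(a)), c(0, -sin(a), cos(a)))
  })
  signal <- sapply(planes, function(pl) {
    spec <- acquisition_spec("custom", in_plane_mm = c(1, 1),
                             slice_thickness_mm = 4, slice_gap_mm = 0,
                             scan_plane = pl, noise_sigma = 0)
    v <- rasterize_scene(tpl, pose, spec, seed = NULL)
    sum(as.numeric(v$data)) * voxel_volume(v)
  })
  expect_lt(max(signal) / min(signal) - 1, 0.1)
})

test_that("the protocol suite emits 8 deterministic volumes", {
  tpl <- tiny_template()
  # coarse, small-FOV variant of the suite mechanics: just check identity
  # and coverage of the real generator on two presets
  pose <- scene_pose(seed = 1)
  v1 <- rasterize_scene(fiducial_template(), pose, acquisition_spec("ssfse"),
                        seed = 5)
  v2 <- rasterize_scene(fiducial_template(), pose, acquisition_spec("ssfse"),
                        seed = 5)
  expect_identical(v1$data, v2$data)
})

test_that("the repeatability suite records planes and commanded shifts", {
  tpl <- fiducial_template()
  vols <- repeatability_suite(tpl, scene_pose(seed = 1), seed = 1,
                              spec = acquisition_spec("spgr"))
  expect_named(vols, c("axial", "oblique1", "oblique2", "axial_shift",
                       "oblique1_shift", "oblique2_shift"))
  expect_equal(vols$axial$meta$commanded_shift, c(0, 0, 0))
  expect_equal(vols$oblique2_shift$meta$commanded_shift, c(0, 0, 30))
  expect_equal(vols$oblique1_shift$meta$plane, "oblique1")
})
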