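test_that("noise threshold finds the valley of a frozen histogram", {
  # counts for I = 0..9; peak at I = 2, descent -20, -8, -1, then flat at I = 5
  v <- volume_from_histogram(c(0, 10, 30, 10, 2, 1, 1, 5, 9, 4))
  nt <- noise_threshold(v)
  expect_identical(as.integer(nt), 5L)
  expect_identical(attr(nt, "peak"), 2L)
})

test_that("noise threshold lands in the empty valley of a two-valued volume", {
  counts <- integer(101)
  counts[10 + 1] <- 900
  counts[100 + 1] <- 100
  v <- volume_from_histogram(counts)
  nt <- as.integer(noise_threshold(v))
  expect_gt(nt, 10)
  expect_lte(nt, 100)
  expect_equal(sum(v$data[v$data >= nt] == 100), 100)  # all signal survives
})

test_that("degenerate histograms raise a classed failure", {
  v <- volume3d(array(7L, dim = c(3, 3, 3)))
  expect_error(noise_threshold(v), class = "fidseg_error")
  # monotone descent with no signal mode
  v2 <- volume_from_histogram(c(100, 50, 20, 5, 1))
  expect_error(noise_threshold(v2), "no noise/signal separation")
})

test_that("noise threshold equals an exhaustive scan on random histograms", {
  set.seed(31)
  for (rep in 1:25) {
    noise <- round(500 * exp(-(0:30) / runif(1, 2, 8))) +
      rpois(31, lambda = 3)
    gap <- integer(sample(10:40, 1))
    signal <- rpois(sample(5:20, 1), lambda = 40)
    counts <- c(noise, gap, signal)
    v <- volume_from_histogram(counts)
    ok <- !inherits(try(naive_noise_threshold(v$data), silent = TRUE),
                    "try-error")
    if (!ok) next
    expect_identical(as.integer(noise_threshold(v)),
                     as.integer(naive_noise_threshold(v$data)))
  }
})

test_that("26-connected labeling honours face, edge and corner adjacency", {
  a <- array(0L, dim = c(6, 6, 6))
  a[2:4, 2:4, 2:4] <- 10L
  sets <- connected_sets(volume3d(a), 1)
  expect_length(sets, 1)
  expect_equal(nrow(sets[[1]]$voxels), 27)

  b <- array(0L, dim = c(4, 4, 4))
  b[1, 1, 1] <- 5L
  b[2, 2, 2] <- 5L   # touches only at a corner
  expect_length(connected_sets(volume3d(b), 1), 1)
})

test_that("labeling of a random sparse volume matches a flood-fill oracle", {
  set.seed(5)
  a <- array(as.integer(runif(20^3) < 0.1), dim = c(20, 20, 20))
  sets <- connected_sets(volume3d(a), 1)
  labels <- naive_cc_labels(a == 1L)
  oracle <- label_partition(labels)
  got <- lapply(sets, function(s)
    unname(sort(s$voxels[, 1] + 1L + s$voxels[, 2] * 20L +
                  s$voxels[, 3] * 400L)))
  got <- got[order(vapply(got, min, numeric(1)))]
  expect_equal(length(got), length(oracle))
  expect_equal(got, lapply(oracle, as.integer))
})

test_that("candidate statistics are intensity-weighted and in world mm", {
  a <- array(0L, dim = c(5, 5, 5))
  a[2, 2, 2] <- 100L
  a[3, 2, 2] <- 300L
  v <- volume3d(a, spacing = c(1, 2, 3))
  s <- connected_sets(v, 1)[[1]]
  expect_equal(s$volume_mm3, 2 * 6)
  # COM: weighted i index = (100*1 + 300*2)/400 = 1.75 (0-based), x = 1.75 mm
  expect_equal(s$com_world, c(1.75, 1 * 2, 1 * 3))
  expect_equal(s$extents_mm, c(2 * 1, 1 * 2, 1 * 3))
})

test_that("reference threshold averages only marker-sized sets", {
  tpl <- fiducial_template(v_marker = 160)  # window (80, 480) mm^3
  cfg <- seg_config(tpl)
  a <- array(0L, dim = c(30, 30, 10))
  a[1:8, 1:5, 1] <- 200L              # 40 voxels: below window
  a[1:10, 1:10, 3] <- 200L            # 100 voxels at I = 200
  a[1:20, 1:15, 5:6] <- 100L          # 600 voxels: above window
  v <- volume3d(a)
  sets <- connected_sets(v, 1)
  expect_equal(reference_threshold(sets, cfg), 200)

  a2 <- array(0L, dim = c(30, 30, 10))
  a2[1:10, 1:10, 3] <- 100L           # 100 voxels at I = 100
  a2[1:15, 1:20, 6] <- 200L           # 300 voxels at I = 200
  sets2 <- connected_sets(volume3d(a2), 1)
  expect_equal(reference_threshold(sets2, cfg),
               (100 * 100 + 300 * 200) / 400)   # 175, voxel-weighted
})

test_that("size windows are strict at their boundaries", {
  tpl <- fiducial_template(v_marker = 160)
  cfg <- seg_config(tpl)
  a <- array(0L, dim = c(30, 30, 10))
  a[1:10, 1:8, 1] <- 150L             # exactly 80 mm^3 = 0.5 v_marker
  expect_error(reference_threshold(connected_sets(volume3d(a), 1), cfg),
               "no marker-sized object")
  # exactly the candidate upper bound 1.3 v_marker = 208 voxels is excluded
  b <- array(0L, dim = c(30, 30, 10))
  b[1:13, 1:16, 5] <- 400L
  expect_error(iterative_signal_size(volume3d(b), 400, cfg, n_t = 1),
               "no candidates")
})

test_that("iterative thresholds recover faint objects at the final iteration", {
  tpl <- fiducial_template(v_marker = 100)  # candidate window (35, 130) mm^3
  cfg <- seg_config(tpl)
  a <- array(0L, dim = c(20, 20, 6))
  a[3:12, 3:12, 3] <- 120L            # 100 voxels at 0.6 * R_T
  v <- volume3d(a)
  r_t <- 200
  sets <- iterative_signal_size(v, r_t, cfg, n_t = 1)
  expect_length(sets, 1)
  expect_equal(nrow(sets[[1]]$voxels), 100)
  expect_equal(sets[[1]]$provenance, 2L)   # only ST_2 = 0.5 R_T captures it
})

test_that("composite growth past the window is rejected, keeping the core", {
  tpl <- fiducial_template(v_marker = 10)   # window (3.5, 13) mm^3
  cfg <- seg_config(tpl)
  a <- array(0L, dim = c(12, 12, 5))
  a[5:7, 5:7, 3] <- 400L              # 9-voxel core, captured at ST_7
  a[4, 4:8, 3] <- 250L                # halo joins at ST_2; union 22 > 1.3 V
  a[8, 4:8, 3] <- 250L
  a[5:7, 4, 3] <- 250L
  v <- volume3d(a)
  sets <- iterative_signal_size(v, 400, cfg, n_t = 1)
  expect_length(sets, 1)
  expect_equal(nrow(sets[[1]]$voxels), 9)   # n = 7 extent, never grown
  expect_equal(max(sets[[1]]$intensities), 400L)
})

test_that("shape gate keeps extents up to and including the limit", {
  cfg <- seg_config(fiducial_template())   # limit 1.5 * sqrt(2) * 12.7
  lim <- cfg$shape_max_mm
  keep <- fake_set(extents_mm = c(lim, 12.7, 12.7))
  drop1 <- fake_set(extents_mm = c(27.5, 12.7, 12.7))
  out <- shape_filter(list(keep, drop1), cfg)
  expect_length(out, 1)
  expect_equal(out[[1]]$extents_mm[1], lim)
})

test_that("a rasterized default cylinder passes the shape gate at any tilt", {
  tpl <- fiducial_template()
  cfg <- seg_config(tpl)
  set.seed(13)
  for (rep in 1:5) {
    rot <- random_rotation()
    cen <- as.vector(rot %*% colMeans(tpl$points))
    pose <- scene_pose(device_position = c(75, 60, 55) - cen,
                       device_rotation = rot,
                       body_semiaxes = NULL, n_blobs = 0)
    spec <- acquisition_spec(in_plane_mm = c(1, 1), slice_thickness_mm = 2,
                             slice_gap_mm = 0, fov_mm = c(150, 120, 110),
                             noise_sigma = 0)
    v <- suppressWarnings(rasterize_scene(tpl, pose, spec, seed = NULL))
    sets <- connected_sets(v, 200)
    expect_gte(length(sets), 4)
    for (s in sets) expect_true(all(s$extents_mm <= cfg$shape_max_mm))
  }
})

test_that("constellation matching rejects decoys and labels markers", {
  tpl <- fiducial_template()
  pts <- tpl$points
  decoys <- rbind(c(200, 200, 200), c(-80, 40, 10), c(60, -90, 70))
  coms <- rbind(pts[c(3, 1, 4, 2), ], decoys)   # scrambled order + decoys
  sets <- lapply(seq_len(nrow(coms)), function(i)
    fake_set(com_world = coms[i, ]))
  cfg <- seg_config(tpl)
  m <- match_device(sets, tpl, cfg)
  expect_equal(m$tolerance, 1)
  expect_equal(unname(m$marker_coms), unname(pts), tolerance = 1e-12)
  # agrees with the brute-force oracle
  oracle <- naive_match(coms, tpl)
  expect_equal(unname(coms[oracle$idx, ]), unname(m$marker_coms))
})

test_that("perturbations within 0.4 mm stay matchable at the 1 mm tolerance", {
  tpl <- fiducial_template()
  cfg <- seg_config(tpl)
  set.seed(21)
  for (rep in 1:10) {
    u <- matrix(rnorm(12), 4, 3)
    u <- u / sqrt(rowSums(u^2)) * runif(4, 0, 0.4)
    sets <- lapply(1:4, function(i) fake_set(com_world = tpl$points[i, ] + u[i, ]))
    m <- match_device(sets, tpl, cfg)
    expect_equal(m$tolerance, 1)
    expect_equal(rownames(m$marker_coms), c("A", "B", "C", "D"))
    expect_lt(max(abs(m$marker_coms - (tpl$points + u))), 1e-12)
  }
})

test_that("matching fails cleanly when fewer than four markers exist", {
  tpl <- fiducial_template()
  sets <- lapply(1:3, function(i) fake_set(com_world = tpl$points[i, ]))
  expect_error(match_device(sets, tpl, seg_config(tpl)),
               class = "fidseg_match_device_error")
})

test_that("far decoy objects never change the matched quadruple", {
  tpl <- fiducial_template()
  cfg <- seg_config(tpl)
  base <- lapply(1:4, function(i) fake_set(com_world = tpl$points[i, ]))
  m0 <- match_device(base, tpl, cfg)
  set.seed(3)
  decoys <- lapply(1:6, function(i)
    fake_set(com_world = runif(3, 120, 400)))   # > 50 mm from the device
  m1 <- match_device(c(base, decoys), tpl, cfg)
  expect_equal(m1$marker_coms, m0$marker_coms)
  expect_equal(m1$tolerance, m0$tolerance)
})

test_that("full pipeline detects a synthetic device and rejects empty scenes", {
  tpl <- tiny_template()
  pose <- tiny_pose()
  spec <- tiny_spec(noise_sigma = 0)
  v <- rasterize_scene(tpl, pose, spec, seed = NULL)
  det <- segment_fiducial(v, tpl)
  truth <- t(pose$device_rotation %*% t(tpl$points)) +
    matrix(pose$device_position, 4, 3, byrow = TRUE)
  expect_lt(max(abs(coef(det) - truth)), max(spacing(v)) / 2)
  # background-only volume: some stage must fail, never a phantom pose
  v0 <- rasterize_scene(tpl, scene_pose(seed = 2), acquisition_spec(
    "custom", in_plane_mm = c(2, 2), slice_thickness_mm = 4, slice_gap_mm = 0,
    fov_mm = c(130, 100, 80)), seed = 5, include_device = FALSE)
  expect_error(segment_fiducial(v0, tpl), class = "fidseg_error")
})
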