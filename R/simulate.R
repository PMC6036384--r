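# Synthetic MR acquisition generator: rasterizes a continuous scene (device
# cylinders over an ellipsoidal body with internal blob structures) onto
# acquisition grids with realistic slice thickness, slice gap, scan-plane
# rotation and quantized noise.

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

plane_rotation <- function(scan_plane) {
  if (is.matrix(scan_plane)) {
    stopifnot(all(dim(scan_plane) == c(3, 3)))
    return(scan_plane)
  }
  switch(scan_plane,
    axial = diag(3),
    # in-plane L-R and S-I, slices along A-P
    coronal = cbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0)),
    # in-plane A-P and S-I, slices along L-R
    sagittal = cbind(c(0, 1, 0), c(0, 0, -1), c(-1, 0, 0)),
    stop("unknown scan plane: ", scan_plane))
}

# Geometry presets mirroring a clinical abdominal protocol: in-plane
# resolution, slice thickness, slice gap (mm) and scan plane per sequence.
# The in/opposed-phase acquisition contributes two echoes with identical
# geometry; the 3-plane localizer is represented by its axial plane.
acq_presets <- list(
  loc3plane = list(in_plane_mm = c(1.9, 1.9), slice_thickness_mm = 10,
                   slice_gap_mm = 0, scan_plane = "axial"),
  ssfse     = list(in_plane_mm = c(0.9, 0.9), slice_thickness_mm = 6,
                   slice_gap_mm = 1, scan_plane = "coronal"),
  ip        = list(in_plane_mm = c(0.7, 0.7), slice_thickness_mm = 6,
                   slice_gap_mm = 1, scan_plane = "axial"),
  op        = list(in_plane_mm = c(0.7, 0.7), slice_thickness_mm = 6,
                   slice_gap_mm = 1, scan_plane = "axial"),
  lava      = list(in_plane_mm = c(0.7, 0.7), slice_thickness_mm = 1.7,
                   slice_gap_mm = 0, scan_plane = "axial"),
  fiesta    = list(in_plane_mm = c(0.7, 0.7), slice_thickness_mm = 4,
                   slice_gap_mm = 2, scan_plane = "axial"),
  spgr      = list(in_plane_mm = c(0.7, 0.7), slice_thickness_mm = 5,
                   slice_gap_mm = 1, scan_plane = "axial"),
  frfse     = list(in_plane_mm = c(0.7, 0.7), slice_thickness_mm = 7,
                   slice_gap_mm = 1, scan_plane = "axial")
)

#' Synthetic acquisition recipe
#'
#' Describes one synthetic scan: voxel sizes, slice gap, scan-plane rotation,
#' table shift, field of view, noise level and signal levels. Named presets
#' mirror the geometry of a clinical abdominal protocol (localizer, SS-FSE,
#' in/opposed-phase, LAVA, FIESTA, SPGR, FR-FSE); see
#' [acquisition_preset_names()].
#'
#' @param name Preset id or `"custom"`.
#' @param in_plane_mm In-plane voxel size (dx, dy), mm.
#' @param slice_thickness_mm Excited slice thickness, mm.
#' @param slice_gap_mm Unsampled gap between slices, mm (>= 0). The
#'   reconstructed inter-slice spacing is thickness + gap.
#' @param scan_plane `"axial"`, `"coronal"`, `"sagittal"`, or a 3x3 rotation
#'   matrix whose columns are the world directions of the grid axes.
#' @param table_shift_mm Commanded table translation (mm); shifts the imaged
#'   field of view (the scene must be shifted separately, see
#'   [repeatability_suite()]).
#' @param fov_mm Field-of-view extents (mm).
#' @param noise_sigma Gaussian noise standard deviation (intensity units);
#'   applied on a magnitude floor, `|signal + noise|`, an adequate stand-in
#'   for Rician magnitude noise at these signal-to-noise ratios.
#' @param signal_levels Named vector with `air`, `tissue`, `marker` mean
#'   levels; must satisfy marker > tissue > air >= 0.
#' @param intensity_max Quantization ceiling.
#' @param supersample Point samples per voxel axis used to integrate the
#'   scene over the voxel-sensitive volume.
#' @param seed Default RNG seed used by [rasterize_scene()] when none is
#'   passed there.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(name = "custom",
                             in_plane_mm = c(0.7, 0.7),
                             slice_thickness_mm = 5,
                             slice_gap_mm = 1,
                             scan_plane = "axial",
                             table_shift_mm = c(0, 0, 0),
                             fov_mm = c(130, 100, 80),
                             noise_sigma = 10,
                             signal_levels = c(air = 0, tissue = 120, marker = 400),
                             intensity_max = 4095,
                             supersample = 4,
                             seed = NULL) {
  if (name != "custom") {
    if (!name %in% names(acq_presets)) stop("unknown preset: ", name)
    p <- acq_presets[[name]]
    if (missing(in_plane_mm)) in_plane_mm <- p$in_plane_mm
    if (missing(slice_thickness_mm)) slice_thickness_mm <- p$slice_thickness_mm
    if (missing(slice_gap_mm)) slice_gap_mm <- p$slice_gap_mm
    if (missing(scan_plane)) scan_plane <- p$scan_plane
  }
  stopifnot(all(in_plane_mm > 0), slice_thickness_mm > 0, slice_gap_mm >= 0,
            all(fov_mm > 0), noise_sigma >= 0, supersample >= 1)
  sl <- signal_levels
  if (!(sl["marker"] > sl["tissue"] && sl["tissue"] > sl["air"] && sl["air"] >= 0))
    stop("signal levels must satisfy marker > tissue > air >= 0")
  structure(list(name = name,
                 in_plane_mm = in_plane_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 slice_gap_mm = slice_gap_mm,
                 scan_plane = scan_plane,
                 table_shift_mm = table_shift_mm,
                 fov_mm = fov_mm,
                 noise_sigma = noise_sigma,
                 signal_levels = sl,
                 intensity_max = intensity_max,
                 supersample = as.integer(supersample),
                 seed = seed),
            class = "acquisition_spec")
}

#' Names of the built-in acquisition presets
#' @return Character vector of the 8 preset ids.
#' @export
acquisition_preset_names <- function() names(acq_presets)

#' Scene description: device pose and body-like background
#'
#' Places the device in world space and generates a body-like background: a
#' large ellipsoid of soft-tissue signal containing seeded ellipsoidal blob
#' structures spanning a range of marker-like volumes and intensities — the
#' confusers that exercise the size, shape and constellation gates. The
#' default pose lays the device base flat in the coronal plane on the
#' anterior body surface (base normal pointing Anterior), the nominal
#' clinical placement.
#'
#' @param device_position World translation of the device (mm), applied after
#'   `device_rotation`.
#' @param device_rotation 3x3 rotation applied to the canonical template
#'   frame. The default maps the template base plane (z = 0) into a coronal
#'   plane with the apex pointing Anterior (-y).
#' @param body_center,body_semiaxes Ellipsoid of tissue signal (mm); set
#'   `body_semiaxes = NULL` for no background body.
#' @param n_blobs Number of internal blob structures.
#' @param blob_volume_mm3 Range of blob volumes (mm^3); the default spans
#'   0.2-4 times the default marker volume.
#' @param blob_intensity_frac Range of blob intensity as a fraction of the
#'   tissue level.
#' @param seed RNG seed for blob placement.
#' @return An object of class `scene_pose`.
#' @export
scene_pose <- function(device_position = c(20, 21, 18),
                       device_rotation = cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
                       body_center = c(65, 60, 40),
                       body_semiaxes = c(60, 30, 38),
                       n_blobs = 30,
                       blob_volume_mm3 = c(0.2, 4) * pi * 6.35^2 * 12.7,
                       blob_intensity_frac = c(0.5, 1.5),
                       seed = 1) {
  blobs <- NULL
  if (!is.null(body_semiaxes) && n_blobs > 0) {
    set.seed(seed)
    centers <- matrix(NA_real_, n_blobs, 3)
    filled <- 0
    while (filled < n_blobs) {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) <= 1) {
        filled <- filled + 1
        centers[filled, ] <- body_center + u * body_semiaxes * 0.65
      }
    }
    vols <- stats::runif(n_blobs, blob_volume_mm3[1], blob_volume_mm3[2])
    shape <- matrix(stats::runif(3 * n_blobs, 0.6, 1.6), n_blobs, 3)
    r0 <- (3 * vols / (4 * pi * apply(shape, 1, prod)))^(1 / 3)
    semi <- shape * r0
    frac <- stats::runif(n_blobs, blob_intensity_frac[1], blob_intensity_frac[2])
    blobs <- cbind(centers, semi, frac)
    colnames(blobs) <- c("cx", "cy", "cz", "sx", "sy", "sz", "intensity_frac")
  }
  structure(list(device_position = device_position,
                 device_rotation = device_rotation,
                 body_center = body_center,
                 body_semiaxes = body_semiaxes,
                 blobs = blobs,
                 seed = seed),
            class = "scene_pose")
}

# World positions of the posed marker centers.
posed_points <- function(template, pose) {
  p <- t(pose$device_rotation %*% t(template$points))
  sweep(p, 2, pose$device_position, `+`)
}

#' Rasterize a scene into a synthetic MR volume
#'
#' Integrates the continuous scene over each voxel's sensitive volume (full
#' in-plane footprint; through-plane only the excited slice thickness, so the
#' slice-gap region contributes nothing) with `supersample` point samples per
#' axis, adds Gaussian noise on a magnitude floor, and quantizes to integers
#' in `[0, intensity_max]`. Deterministic for a fixed seed.
#'
#' @param template A `fiducial_template`.
#' @param pose A `scene_pose`.
#' @param spec An `acquisition_spec`.
#' @param seed RNG seed for the noise; defaults to `spec$seed`. `NULL` leaves
#'   the RNG state untouched.
#' @param include_device Render the marker cylinders; set `FALSE` for a
#'   background-only (device-absent) volume.
#' @return A `volume3d` with acquisition metadata in `meta`.
#' @export
rasterize_scene <- function(template, pose, spec, seed = spec$seed,
                            include_device = TRUE) {
  stopifnot(inherits(template, "fiducial_template"),
            inherits(pose, "scene_pose"),
            inherits(spec, "acquisition_spec"))
  Rp <- plane_rotation(spec$scan_plane)
  dz <- spec$slice_thickness_mm + spec$slice_gap_mm
  sp <- c(spec$in_plane_mm, dz)
  fov_center <- spec$fov_mm / 2 + spec$table_shift_mm
  ext <- as.vector(t(abs(Rp)) %*% spec$fov_mm)
  dims <- pmax(2L, as.integer(ceiling(ext / sp)))
  origin <- fov_center - as.vector(Rp %*% (sp * (dims - 1) / 2))
  affine <- diag(4)
  affine[1:3, 1:3] <- Rp %*% diag(sp)
  affine[1:3, 4] <- origin

  pts <- posed_points(template, pose)
  lo <- spec$table_shift_mm
  hi <- spec$table_shift_mm + spec$fov_mm
  inside <- pts >= matrix(lo, 4, 3, byrow = TRUE) &
            pts <= matrix(hi, 4, 3, byrow = TRUE)
  if (include_device && !any(rowSums(inside) == 3))
    fid_stop("rasterize_scene", "device fully outside the field of view")
  axis0 <- as.vector(pose$device_rotation %*% c(0, 0, 1))
  # per-axis reach of a marker cylinder from its center
  reach <- abs(axis0) * template$marker_depth / 2 +
    template$marker_diameter / 2 * sqrt(pmax(0, 1 - axis0^2))
  clipped <- any(pts < matrix(lo + reach, 4, 3, byrow = TRUE) |
                 pts > matrix(hi - reach, 4, 3, byrow = TRUE))
  if (include_device && clipped)
    warning("device markers may be clipped at the field-of-view boundary")

  axis <- as.vector(pose$device_rotation %*% c(0, 0, 1))
  sl <- spec$signal_levels
  cylinders <- cbind(pts,
                     matrix(axis, 4, 3, byrow = TRUE),
                     template$marker_diameter / 2,
                     template$marker_depth / 2,
                     sl[["marker"]])
  if (!include_device) cylinders <- cylinders[0, , drop = FALSE]
  body <- if (is.null(pose$body_semiaxes)) numeric(0) else
    c(pose$body_center, pose$body_semiaxes, sl[["tissue"]])
  blobs <- if (is.null(pose$blobs)) matrix(0, 0, 7) else
    cbind(pose$blobs[, 1:6, drop = FALSE],
          pose$blobs[, 7] * sl[["tissue"]])

  arr <- .rasterize_scene(dims, affine, spec$supersample,
                          spec$slice_thickness_mm / dz,
                          cylinders, body, blobs)
  if (sl[["air"]] > 0) {
    # air level fills everything the scene left at zero
    arr[arr == 0] <- sl[["air"]]
  }
  if (!is.null(seed)) set.seed(seed)
  if (spec$noise_sigma > 0)
    arr <- abs(arr + stats::rnorm(length(arr), 0, spec$noise_sigma))
  arr <- pmin(round(arr), spec$intensity_max)
  dim(arr) <- dims
  volume3d(arr, affine = affine,
           meta = list(sequence = spec$name,
                       plane = if (is.matrix(spec$scan_plane)) "oblique"
                               else spec$scan_plane,
                       slice_thickness = spec$slice_thickness_mm,
                       slice_gap = spec$slice_gap_mm,
                       commanded_shift = spec$table_shift_mm,
                       noise_sigma = spec$noise_sigma,
                       seed = seed))
}

derive_seed <- function(seed, i) as.integer((seed %% 1000003L) * 1031L + i)

#' Generate the 8-sequence protocol suite
#'
#' One synthetic volume per acquisition preset (the in/opposed-phase pair
#' counts as two echoes with identical geometry and independent noise), all
#' of the same scene. Per-volume noise seeds are derived deterministically
#' from `seed`.
#'
#' @param template A `fiducial_template`.
#' @param pose A `scene_pose`.
#' @param seed Integer master seed.
#' @param noise_sigma,fov_mm Passed to every [acquisition_spec()].
#' @return Named list of 8 `volume3d` objects.
#' @export
table1_suite <- function(template = fiducial_template(),
                         pose = scene_pose(),
                         seed = 1,
                         noise_sigma = 10,
                         fov_mm = c(130, 100, 80)) {
  nm <- acquisition_preset_names()
  out <- vector("list", length(nm))
  names(out) <- nm
  for (i in seq_along(nm)) {
    spec <- acquisition_spec(nm[i], noise_sigma = noise_sigma, fov_mm = fov_mm)
    out[[i]] <- rasterize_scene(template, pose, spec,
                                seed = derive_seed(seed, i))
  }
  out
}

#' Generate the repeatability suite
#'
#' Six volumes of one scene: axial plus two oblique scan planes, each at the
#' baseline table position and after a commanded table shift (the device and
#' the imaged field of view both move). The commanded shift and plane are
#' recorded in each volume's metadata.
#'
#' @param template A `fiducial_template`.
#' @param base_pose A `scene_pose` for the baseline position.
#' @param seed Integer master seed.
#' @param spec An `acquisition_spec` giving the sequence geometry; its
#'   scan plane and table shift are overridden per volume.
#' @param oblique_angles Two angles (degrees): the first oblique tilts about
#'   the world x axis, the second about the world y axis.
#' @param shift_mm Commanded table translation for the shifted volumes.
#' @return Named list of 6 `volume3d` objects
#'   (`axial`, `oblique1`, `oblique2`, then `*_shift`).
#' @export
repeatability_suite <- function(template = fiducial_template(),
                                base_pose = scene_pose(),
                                seed = 1,
                                spec = acquisition_spec("spgr"),
                                oblique_angles = c(10, 20),
                                shift_mm = c(0, 0, 30)) {
  planes <- list(axial = diag(3),
                 oblique1 = rot_x(oblique_angles[1]),
                 oblique2 = rot_y(oblique_angles[2]))
  out <- list()
  i <- 0
  for (shifted in c(FALSE, TRUE)) {
    pose <- base_pose
    shift <- if (shifted) shift_mm else c(0, 0, 0)
    pose$device_position <- base_pose$device_position + shift
    for (pn in names(planes)) {
      i <- i + 1
      s <- spec
      s$scan_plane <- planes[[pn]]
      s$table_shift_mm <- shift
      nm <- if (shifted) paste0(pn, "_shift") else pn
      vol <- rasterize_scene(template, pose, s, seed = derive_seed(seed, i))
      vol$meta$plane <- pn
      vol$meta$volume_name <- nm
      out[[nm]] <- vol
    }
  }
  out
}
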