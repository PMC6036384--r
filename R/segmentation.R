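# Detection pipeline: noise thresholding, 26-connected component analysis
# with marker-volume gates, iterative multi-threshold segmentation, shape
# discrimination, and constellation matching.

fid_stop <- function(stage, ...) {
  cond <- structure(
    class = c(paste0("fidseg_", stage, "_error"), "fidseg_error",
              "error", "condition"),
    list(message = paste0("[", stage, "] ", paste0(..., collapse = "")),
         call = sys.call(-1), stage = stage))
  stop(cond)
}

#' Segmentation configuration
#'
#' Collects the tunable parameters of the detection pipeline. All size
#' windows are expressed as multiples of the nominal marker signal volume
#' `v_marker` and compared strictly (`low * v_marker < V < high * v_marker`);
#' all volumes are in mm^3 (voxel count times dx*dy*dz), so that acquisitions
#' whose voxel volumes differ by more than an order of magnitude are treated
#' uniformly.
#'
#' @param template A `fiducial_template`; supplies `v_marker` and the shape
#'   gate `1.5 * longest_dim`.
#' @param size_window_ref Size window (multiples of `v_marker`) for the
#'   marker-sized sets that define the reference signal threshold.
#' @param size_window_candidate Size window for candidate markers in the
#'   iterative signal/size step.
#' @param st_fractions Decreasing fractions of the reference threshold used
#'   as the iterative signal thresholds.
#' @param shape_max_mm Maximum allowed per-axis candidate extent, mm.
#' @param match_tol_start,match_tol_step,match_tol_max Constellation matching
#'   tolerance schedule, mm. Matching starts at `match_tol_start` and grows in
#'   `match_tol_step` increments until a match is found or `match_tol_max` is
#'   exceeded. The 10 mm default cap is of the order of the coarsest slice
#'   spacing in the supported protocols: through-plane center-of-mass
#'   quantization on thick-slice acquisitions can displace a marker by up to
#'   half the slice spacing, so genuine matches must remain reachable, while
#'   an unbounded search would eventually accept arbitrary clutter.
#' @param smooth_histogram Apply a 3-bin moving average to the intensity
#'   histogram before locating the noise threshold (for ragged histograms;
#'   off by default).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(template = fiducial_template(),
                       size_window_ref = c(0.5, 3.0),
                       size_window_candidate = c(0.35, 1.3),
                       st_fractions = c(7, 6, 5, 4, 3, 2) / 4,
                       shape_max_mm = 1.5 * template$longest_dim,
                       match_tol_start = 1,
                       match_tol_step = 1,
                       match_tol_max = 10,
                       smooth_histogram = FALSE) {
  stopifnot(inherits(template, "fiducial_template"))
  if (size_window_ref[1] >= size_window_ref[2] ||
      size_window_candidate[1] >= size_window_candidate[2])
    stop("size windows must satisfy low < high")
  if (any(diff(st_fractions) >= 0))
    stop("`st_fractions` must be strictly decreasing")
  if (match_tol_start <= 0 || match_tol_step <= 0 || match_tol_max <= 0 ||
      shape_max_mm <= 0)
    stop("tolerances must be positive")
  structure(list(
    v_marker = template$v_marker,
    size_window_ref = size_window_ref,
    size_window_candidate = size_window_candidate,
    st_fractions = st_fractions,
    shape_max_mm = shape_max_mm,
    match_tol_start = match_tol_start,
    match_tol_step = match_tol_step,
    match_tol_max = match_tol_max,
    smooth_histogram = smooth_histogram
  ), class = "seg_config")
}

#' Histogram-based noise threshold
#'
#' Builds the voxel intensity histogram with bin width 1 over `0..max(I)`,
#' locates the first peak (the global maximum of the lower half of the
#' occupied intensity range, excluding the I = 0 bin, where air background
#' dominates), and returns the intensity of the histogram valley above that
#' peak: the first bin attaining the minimum count between the noise peak
#' and the onset of the next signal mode. The signal onset is detected as
#' the first bin whose count at least doubles the running minimum (any
#' occupied bin, once an empty valley bin has been seen); requiring a
#' doubling keeps counting fluctuations of the decaying noise mode from
#' triggering a false onset. The valley bin is where the discrete
#' derivative of the histogram changes sign from non-positive to
#' non-negative, between the low-intensity noise mode and the first signal
#' mode; on an idealized unimodal descent it coincides with the first
#' non-negative forward difference. Voxels below the returned threshold are
#' treated as background by the downstream steps.
#'
#' @param v A `volume3d` with at least two distinct intensity values.
#' @param smooth Apply a 3-bin moving average before the search.
#' @return Integer noise threshold, with the located peak intensity attached
#'   as attribute `"peak"`.
#' @export
noise_threshold <- function(v, smooth = FALSE) {
  stopifnot(inherits(v, "volume3d"))
  counts <- tabulate(as.vector(v$data) + 1L, nbins = max(v$data) + 1L)
  occ <- which(counts > 0L) - 1L
  if (length(occ) < 2L)
    fid_stop("noise_threshold",
             "volume has fewer than two distinct intensity values")
  h <- as.numeric(counts)
  if (smooth) {
    sm <- stats::filter(h, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- h[is.na(sm)]
    h <- as.numeric(sm)
  }
  lo <- min(occ); hi <- max(occ)
  half_hi <- lo + (hi - lo) / 2
  cand <- occ[occ >= max(lo, 1L) & occ <= half_hi]
  peak <- if (length(cand) == 0L) lo else cand[which.max(h[cand + 1L])]
  if (peak + 1L > hi)
    fid_stop("noise_threshold",
             "no noise/signal separation: no occupied bins above the ",
             "background peak")
  run_min <- Inf; i0 <- NA_integer_; onset <- NA_integer_
  for (i in (peak + 1L):hi) {
    if (h[i + 1L] < run_min) {
      run_min <- h[i + 1L]
      i0 <- i
    } else if (h[i + 1L] > 0 && h[i + 1L] >= 2 * run_min) {
      onset <- i
      break
    }
  }
  if (is.na(onset) || h[i0 + 1L] > h[peak + 1L])
    fid_stop("noise_threshold",
             "no noise/signal separation: histogram does not rise again ",
             "above its descent from the background peak")
  structure(as.integer(i0), peak = as.integer(peak),
            signal_onset = as.integer(onset))
}

# Per-component statistics from a label vector. Returns a data.frame ordered
# deterministically by (voxel count, first linear voxel index).
# com/ext columns are matrices; keep them so even for a single component.
cc_stats <- function(labels, v) {
  dims <- dim(v$data)
  nz <- which(labels != 0L)
  if (length(nz) == 0L)
    return(data.frame(label = integer(0)))
  lab <- labels[nz]
  coords <- arrayInd(nz, dims)            # 1-based
  ints <- as.numeric(v$data[nz])
  agg <- rowsum(cbind(n = 1, sumI = ints,
                      wi = ints * (coords[, 1] - 1),
                      wj = ints * (coords[, 2] - 1),
                      wk = ints * (coords[, 3] - 1)), lab)
  labs <- as.integer(rownames(agg))
  mins <- vapply(1:3, function(a) as.numeric(tapply(coords[, a], lab, min)),
                 numeric(length(labs)))
  maxs <- vapply(1:3, function(a) as.numeric(tapply(coords[, a], lab, max)),
                 numeric(length(labs)))
  if (length(labs) == 1L) {
    mins <- matrix(mins, nrow = 1)
    maxs <- matrix(maxs, nrow = 1)
  }
  first <- tapply(nz, lab, min)
  sp <- spacing(v)
  vv <- voxel_volume(v)
  com_vox <- agg[, c("wi", "wj", "wk"), drop = FALSE] / agg[, "sumI"]
  com_world <- voxel_to_world(v, com_vox)
  df <- data.frame(label = labs, n = as.integer(agg[, "n"]),
                   volume_mm3 = agg[, "n"] * vv,
                   sumI = agg[, "sumI"], first = as.integer(first))
  df$com <- unname(rbind(com_world))
  df$ext <- unname(sweep(maxs - mins + 1, 2, sp, `*`))
  df$touches_boundary <- rowSums(mins == 1) > 0 |
    rowSums(sweep(maxs, 2, dims, `==`)) > 0
  df[order(df$n, df$first), , drop = FALSE]
}

# Build candidate-set objects (voxel lists and stats) for the given labels.
build_sets <- function(labels, v, stats = NULL, provenance = NULL) {
  if (is.null(stats)) stats <- cc_stats(labels, v)
  if (nrow(stats) == 0L) return(list())
  dims <- dim(v$data)
  nz <- which(labels != 0L)
  vox_by_label <- split(nz, labels[nz])
  lapply(seq_len(nrow(stats)), function(r) {
    lin <- sort(vox_by_label[[as.character(stats$label[r])]])
    coords <- arrayInd(lin, dims) - 1L   # 0-based indices
    colnames(coords) <- c("i", "j", "k")
    prov <- if (is.null(provenance)) NA_integer_ else
      sort(unique(provenance[lin]), decreasing = TRUE)
    structure(list(
      voxels = coords,
      intensities = as.integer(v$data[lin]),
      volume_mm3 = stats$volume_mm3[r],
      com_world = as.numeric(stats$com[r, ]),
      extents_mm = as.numeric(stats$ext[r, ]),
      touches_boundary = stats$touches_boundary[r],
      provenance = prov
    ), class = "candidate_set")
  })
}

#' Maximal 26-connected voxel sets above a threshold
#'
#' Labels the maximal 26-connected components (voxels sharing a face, edge,
#' or corner are neighbours) of the superlevel set `intensity >= threshold`
#' and returns them as candidate sets with mm^3 volume, intensity-weighted
#' world center-of-mass, and per-axis extents `(max - min + 1) * spacing`.
#' Sets are ordered by (voxel count, first voxel in raster order) so results
#' are reproducible.
#'
#' @param v A `volume3d`.
#' @param threshold Intensity threshold (inclusive: `>=` survives).
#' @return List of `candidate_set` objects (possibly empty).
#' @export
connected_sets <- function(v, threshold) {
  stopifnot(inherits(v, "volume3d"), threshold >= 0)
  mask <- as.vector(v$data >= threshold)
  labels <- .cc_label26(mask, dim(v$data))
  build_sets(labels, v)
}

#' Reference signal threshold from marker-sized sets
#'
#' The mean original intensity over all voxels belonging to connected sets
#' whose volume lies strictly inside the reference size window
#' (`(0.5, 3) * v_marker` by default). This is the characteristic marker
#' signal level from which the iterative thresholds are scaled.
#'
#' @param sets List of `candidate_set` (typically from [connected_sets()] at
#'   the noise threshold).
#' @param config A `seg_config`.
#' @return The reference threshold R_T (numeric scalar).
#' @export
reference_threshold <- function(sets, config) {
  stopifnot(inherits(config, "seg_config"))
  win <- config$size_window_ref * config$v_marker
  keep <- vapply(sets, function(s)
    s$volume_mm3 > win[1] && s$volume_mm3 < win[2], logical(1))
  if (!any(keep))
    fid_stop("reference_threshold",
             sprintf("no marker-sized object: no connected set with volume in (%.0f, %.0f) mm^3",
                     win[1], win[2]))
  ints <- unlist(lapply(sets[keep], `[[`, "intensities"))
  mean(ints)
}

#' Iterative signal/size discrimination
#'
#' Applies progressively decreasing signal thresholds
#' `ST_n = (n/4) * R_T, n = 7..2` to the noise-masked volume. At each
#' threshold, 26-connected sets with volume strictly inside the candidate
#' window (`(0.35, 1.3) * v_marker`) are merged into a composite mask. A set
#' is merged only if its union with the overlapping/adjacent composite
#' objects does not exceed `1.3 * v_marker`; otherwise the new set is
#' discarded and the composite is left unchanged (so an object captured
#' cleanly at a high threshold is never grown past the window by lower
#' thresholds). Returns the connected sets of the final composite mask, with
#' original intensities and the contributing iteration indices recorded as
#' provenance.
#'
#' @param v A `volume3d`.
#' @param r_t Reference signal threshold (from [reference_threshold()]).
#' @param config A `seg_config`.
#' @param n_t Noise threshold; voxels below it never enter the composite.
#' @return List of `candidate_set` objects.
#' @export
iterative_signal_size <- function(v, r_t, config, n_t = 0L) {
  stopifnot(inherits(v, "volume3d"), inherits(config, "seg_config"))
  if (r_t <= 0) fid_stop("iterative_signal_size", "reference threshold must be > 0")
  dims <- dim(v$data)
  nvox <- prod(dims)
  vv <- voxel_volume(v)
  win <- config$size_window_candidate * config$v_marker
  vmax <- config$size_window_candidate[2] * config$v_marker
  dat <- as.vector(v$data)
  comp <- integer(nvox)        # composite labels
  prov <- integer(nvox)        # iteration (n of ST_n) that first added a voxel
  comp_sizes <- integer(0)
  next_id <- 0L
  # 26-neighbourhood + centre offsets applied in coordinate space
  shifts <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))

  for (f in config$st_fractions) {
    st <- f * r_t
    n_iter <- as.integer(round(f * 4))
    mask <- dat >= st & dat >= n_t
    labels <- .cc_label26(mask, dims)
    stats <- cc_stats(labels, v)
    if (nrow(stats) == 0L) next
    stats <- stats[stats$volume_mm3 > win[1] & stats$volume_mm3 < win[2], ,
                   drop = FALSE]
    if (nrow(stats) == 0L) next
    nz <- which(labels != 0L)
    vox_by_label <- split(nz, labels[nz])
    for (r in seq_len(nrow(stats))) {
      lin <- vox_by_label[[as.character(stats$label[r])]]
      coords <- arrayInd(lin, dims)
      # linear indices of the 27-neighbourhood of the set, in bounds
      nb <- lapply(seq_len(nrow(shifts)), function(s) {
        cc <- sweep(coords, 2, unlist(shifts[s, ]), `+`)
        ok <- cc[, 1] >= 1 & cc[, 1] <= dims[1] &
              cc[, 2] >= 1 & cc[, 2] <= dims[2] &
              cc[, 3] >= 1 & cc[, 3] <= dims[3]
        cc <- cc[ok, , drop = FALSE]
        cc[, 1] + (cc[, 2] - 1L) * dims[1] + (cc[, 3] - 1L) * dims[1] * dims[2]
      })
      nb <- unique(unlist(nb))
      touching <- setdiff(unique(comp[nb]), 0L)
      overlap <- sum(comp[lin] %in% touching)
      union_n <- length(lin) + sum(comp_sizes[as.character(touching)]) - overlap
      if (union_n * vv > vmax) next   # growth rejection: discard the new set
      next_id <- next_id + 1L
      new_vox <- lin[comp[lin] == 0L]
      prov[new_vox] <- n_iter
      comp[lin] <- next_id
      if (length(touching))
        comp[comp %in% touching] <- next_id
      comp_sizes <- comp_sizes[setdiff(names(comp_sizes), as.character(touching))]
      comp_sizes[as.character(next_id)] <- union_n
    }
  }
  if (!any(comp != 0L))
    fid_stop("iterative_signal_size",
             "no candidates: composite mask empty after all threshold iterations")
  final <- .cc_label26(comp != 0L, dims)
  build_sets(final, v, provenance = prov)
}

#' Shape discrimination
#'
#' Retains candidates whose per-axis extents are all at most
#' `shape_max_mm` (1.5 times the marker space diagonal, 26.9 mm for the
#' default cylinder); elongated artifacts such as vessel or skin-fold
#' segments are removed.
#'
#' @param sets List of `candidate_set`.
#' @param config A `seg_config`.
#' @return Filtered list (possibly empty).
#' @export
shape_filter <- function(sets, config) {
  stopifnot(inherits(config, "seg_config"))
  keep <- vapply(sets, function(s)
    all(s$extents_mm <= config$shape_max_mm), logical(1))
  sets[keep]
}

# all 24 permutations of 1:4
perms4 <- function() {
  p <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    p <- rbind(p, c(a, b, cc, setdiff(1:4, c(a, b, cc))))
  p
}

#' Constellation matching of candidate centers-of-mass
#'
#' Searches 4-subsets of candidate centers-of-mass for one whose six sorted
#' pairwise distances each agree with the template separations within a
#' tolerance. The tolerance starts at `match_tol_start` (1 mm) and grows by
#' `match_tol_step` until a match is found or `match_tol_max` is exceeded.
#' When several subsets match at the same tolerance, the one with minimal RMS
#' distance error is returned. Marker labels A-D are assigned by the
#' permutation minimizing the RMS error against the labeled template
#' distances — unique for the default scalene geometry.
#'
#' @param sets List of `candidate_set` (at least 4).
#' @param template A `fiducial_template`.
#' @param config A `seg_config`.
#' @return List with `marker_coms` (4 x 3 labeled matrix), `tolerance` (mm),
#'   `rms` (mm), `candidate_indices` (positions in `sets` of A-D), and
#'   `n_candidates`.
#' @export
match_device <- function(sets, template, config) {
  stopifnot(inherits(template, "fiducial_template"),
            inherits(config, "seg_config"))
  m <- length(sets)
  if (m < 4)
    fid_stop("match_device",
             sprintf("device not found: only %d candidate(s), need 4", m))
  coms <- t(vapply(sets, `[[`, numeric(3), "com_world"))
  tmpl_sorted <- template$separations
  tmpl_pair <- pair_distances(template$points)
  subsets <- utils::combn(m, 4)
  P <- perms4()
  label_rms <- function(pts) {
    best <- Inf; best_perm <- NULL
    for (r in seq_len(nrow(P))) {
      q <- pts[P[r, ], , drop = FALSE]
      rownames(q) <- c("A", "B", "C", "D")
      err <- sqrt(mean((pair_distances(q) - tmpl_pair)^2))
      if (err < best) { best <- err; best_perm <- P[r, ] }
    }
    list(rms = best, perm = best_perm)
  }
  taus <- seq(config$match_tol_start, config$match_tol_max,
              by = config$match_tol_step)
  overall_best <- Inf
  for (tau in taus) {
    best <- NULL
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      pts <- coms[idx, , drop = FALSE]
      d6 <- sort(as.vector(stats::dist(pts)), decreasing = TRUE)
      if (tau == taus[1]) {
        rms_sorted <- sqrt(mean((d6 - tmpl_sorted)^2))
        overall_best <- min(overall_best, rms_sorted)
      }
      if (all(abs(d6 - tmpl_sorted) <= tau)) {
        fit <- label_rms(pts)
        if (is.null(best) || fit$rms < best$rms)
          best <- list(rms = fit$rms, idx = idx[fit$perm])
      }
    }
    if (!is.null(best)) {
      mc <- coms[best$idx, , drop = FALSE]
      rownames(mc) <- c("A", "B", "C", "D")
      colnames(mc) <- c("x", "y", "z")
      return(list(marker_coms = mc, tolerance = tau, rms = best$rms,
                  candidate_indices = best$idx, n_candidates = m))
    }
  }
  fid_stop("match_device",
           sprintf("device not found at tolerance %.0f mm (best RMS over all 4-subsets: %.2f mm)",
                   config$match_tol_max, overall_best))
}

#' Detect the fiducial device in a volume
#'
#' Runs the full pipeline: noise thresholding, marker-sized connected-set
#' extraction and reference threshold, iterative signal/size discrimination,
#' shape discrimination, and constellation matching; then computes the device
#' pose (group center-of-mass, base normal, spherical angles) and the
#' least-squares rigid transform from the template frame.
#'
#' @param v A `volume3d`.
#' @param template A `fiducial_template`.
#' @param config A `seg_config`; defaults to `seg_config(template)`.
#' @return An object of class `fiducial_detection`; see
#'   [fiducial_detection-methods] for its methods. Stage failures raise
#'   classed conditions (class `fidseg_error`) naming the failed stage.
#' @examples
#' \donttest{
#' tpl <- fiducial_template()
#' vol <- rasterize_scene(tpl, scene_pose(seed = 1),
#'                        acquisition_spec("lava", seed = 1))
#' det <- segment_fiducial(vol, tpl)
#' det
#' }
#' @export
segment_fiducial <- function(v, template = fiducial_template(),
                             config = seg_config(template)) {
  stopifnot(inherits(v, "volume3d"))
  n_t <- noise_threshold(v, smooth = config$smooth_histogram)
  ref_sets <- connected_sets(v, n_t)
  r_t <- reference_threshold(ref_sets, config)
  candidates <- iterative_signal_size(v, r_t, config, n_t = n_t)
  shaped <- shape_filter(candidates, config)
  match <- match_device(shaped, template, config)
  pose <- device_pose(match$marker_coms)
  rigid <- rigid_fit(template, match$marker_coms)
  matched_sets <- shaped[match$candidate_indices]
  structure(list(
    marker_coms = match$marker_coms,
    device_com = pose$device_com,
    normal = pose$normal,
    theta = pose$theta,
    phi = pose$phi,
    phi_degenerate = pose$phi_degenerate,
    match_tolerance = match$tolerance,
    rigid_fit = rigid,
    marker_sets = matched_sets,
    diagnostics = list(
      noise_threshold = as.integer(n_t),
      histogram_peak = attr(n_t, "peak"),
      reference_threshold = r_t,
      n_reference_sets = length(ref_sets),
      n_candidates = length(candidates),
      n_after_shape = length(shaped),
      match_rms = match$rms,
      boundary_markers = vapply(matched_sets, `[[`, logical(1),
                                "touches_boundary")
    ),
    meta = v$meta
  ), class = "fiducial_detection")
}
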