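#' 3D MR volume with voxel-to-world geometry
#'
#' Container for a 3D grid of non-negative integer intensities together with
#' the 4x4 affine matrix mapping 0-based voxel indices (i, j, k) to world
#' coordinates in millimetres. The world frame is LPS (Left, Posterior,
#' Superior), the DICOM patient convention; NIfTI files, which use RAS, are
#' converted on load and save. Intensities must be integers because the noise
#' thresholding step works on a bin-width-1 histogram; floating-point input is
#' rounded to the nearest integer (recorded in `meta$rounded`).
#'
#' For 2D multi-slice acquisitions with a slice gap, the grid is contiguous
#' and the third voxel dimension equals slice thickness + gap (the
#' reconstructed inter-slice spacing); the information loss inside the gap is
#' a property of the acquisition, modelled by the synthetic generator, not of
#' the container.
#'
#' @param data 3D numeric or integer array of intensities, all >= 0.
#' @param affine 4x4 voxel-to-world affine (0-based indices, LPS mm). If
#'   omitted, an axis-aligned affine is built from `spacing` and `origin`.
#' @param spacing length-3 voxel spacing in mm (used when `affine` is NULL).
#' @param origin world position of voxel (0, 0, 0) (used when `affine` is NULL).
#' @param meta free-form list of acquisition metadata (sequence name, slice
#'   thickness, slice gap, commanded shift, ...).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, affine = NULL, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("`affine` is not invertible")
  storage <- data
  if (is.double(storage)) {
    rounded <- max(abs(storage - round(storage))) > 0
    storage <- round(storage)
    if (rounded) meta$rounded <- TRUE
    storage_mode_ok <- max(storage) < .Machine$integer.max
    if (storage_mode_ok) storage.mode(storage) <- "integer"
  }
  if (min(storage, na.rm = TRUE) < 0)
    stop("intensities must be >= 0")
  v <- structure(list(data = storage, affine = affine, meta = meta),
                 class = "volume3d")
  sp <- spacing(v)
  if (any(sp <= 0)) stop("voxel spacing must be strictly positive")
  v
}

#' Voxel spacing of a volume
#'
#' Column norms of the linear part of the affine: the physical distance in mm
#' between neighbouring voxels along each logical axis.
#'
#' @param v A `volume3d`.
#' @return Numeric length-3 vector (dx, dy, dz) in mm.
#' @export
spacing <- function(v) {
  stopifnot(inherits(v, "volume3d"))
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Voxel volume in cubic millimetres
#'
#' @param v A `volume3d`.
#' @return dx * dy * dz in mm^3.
#' @export
voxel_volume <- function(v) prod(spacing(v))

#' Map voxel indices to world coordinates
#'
#' Applies the volume affine to 0-based, possibly fractional, voxel indices.
#' Indices outside the grid are allowed.
#'
#' @param v A `volume3d`.
#' @param idx Numeric length-3 vector or n x 3 matrix of 0-based indices.
#' @return World coordinates (LPS mm), same shape as `idx`.
#' @export
voxel_to_world <- function(v, idx) {
  stopifnot(inherits(v, "volume3d"))
  one_row <- is.null(dim(idx))
  idx <- rbind(idx)
  out <- t(v$affine[1:3, 1:3] %*% t(idx) + v$affine[1:3, 4])
  if (one_row) drop(out) else out
}

#' Map world coordinates to fractional voxel indices
#'
#' Inverse of [voxel_to_world()]; round-trips to better than 1e-9 mm.
#'
#' @param v A `volume3d`.
#' @param pts Numeric length-3 vector or n x 3 matrix of world points (LPS mm).
#' @return 0-based fractional voxel indices.
#' @export
world_to_voxel <- function(v, pts) {
  stopifnot(inherits(v, "volume3d"))
  one_row <- is.null(dim(pts))
  pts <- rbind(pts)
  inv <- solve(v$affine)
  out <- t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
  if (one_row) drop(out) else out
}

# LPS <-> RAS: flip the first two world axes.
lps_from_ras <- function(affine) diag(c(-1, -1, 1, 1)) %*% affine

#' Load a 3D volume
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`; the RAS affine is converted to
#' LPS), a DICOM series directory (single-frame slices sharing one
#' orientation), or the internal `.rds` format written by [save_volume()].
#'
#' @param path File or directory path.
#' @param format One of `"auto"`, `"nifti"`, `"dicom_dir"`, `"internal"`.
#'   `"auto"` dispatches on the file extension / directory-ness.
#' @return A `volume3d` in LPS mm.
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_dir", "internal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
    else if (grepl("\\.rds$", path, ignore.case = TRUE)) "internal"
    else "nifti"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      affine_ras <- structure(RNifti::xform(img), dimnames = NULL)
      arr <- as.array(img)
      if (length(dim(arr)) != 3L) stop("only 3D NIfTI volumes are supported")
      meta <- list(source = path, format = "nifti")
      if (is.double(arr) && max(abs(arr - round(arr))) > 0)
        meta$rounded <- TRUE
      volume3d(arr, affine = lps_from_ras(affine_ras), meta = meta)
    },
    dicom_dir = load_dicom_dir(path),
    internal = {
      v <- readRDS(path)
      if (!inherits(v, "volume3d")) stop("not an internal volume file: ", path)
      v
    })
}

#' Save a 3D volume
#'
#' Writes NIfTI-1 (LPS affine converted back to the RAS convention of the
#' format) or the internal `.rds` format. Round-trips preserve the data
#' exactly and the affine to better than 1e-6.
#'
#' @param v A `volume3d`.
#' @param path Destination path; extension selects the format when
#'   `format = "auto"`.
#' @param format One of `"auto"`, `"nifti"`, `"internal"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path, format = c("auto", "nifti", "internal")) {
  stopifnot(inherits(v, "volume3d"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "internal" else "nifti"
  if (format == "internal") {
    saveRDS(v, path)
  } else {
    img <- RNifti::asNifti(v$data)
    img <- RNifti::`sform<-`(img, structure(lps_from_ras(v$affine), code = 2L))
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  sp <- spacing(x)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%d, %d], origin (%.1f, %.1f, %.1f) mm LPS\n",
              min(x$data), max(x$data),
              x$affine[1, 4], x$affine[2, 4], x$affine[3, 4]))
  if (!is.null(x$meta$sequence))
    cat("  sequence:", x$meta$sequence, "\n")
  invisible(x)
}
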