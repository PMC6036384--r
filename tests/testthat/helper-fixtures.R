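# Small fixtures built in code.

# Compact device + coarse grid: fast end-to-end scenes for unit tests.
tiny_template <- function() {
  fiducial_template(base_sides = c(22, 30, 38), apex_height = 9,
                    marker_diameter = 9, marker_depth = 9)
}

tiny_pose <- function() {
  scene_pose(device_position = c(8, 14, 8),
             body_semiaxes = NULL, n_blobs = 0)
}

tiny_spec <- function(noise_sigma = 5, ...) {
  acquisition_spec(in_plane_mm = c(1, 1), slice_thickness_mm = 2,
                   slice_gap_mm = 0, fov_mm = c(56, 40, 36),
                   noise_sigma = noise_sigma, ...)
}

# Full-size device floating in air (no background), and a thin-slice spec:
# used to compare rasterized marker volume against the analytic cylinder.
tiny_full_size_pose <- function() scene_pose(body_semiaxes = NULL, n_blobs = 0)
lava_like_spec <- function() acquisition_spec("lava", noise_sigma = 0)

# A volume3d whose intensity histogram is exactly `counts` (counts[i] voxels
# of intensity i - 1), geometry irrelevant.
volume_from_histogram <- function(counts, spacing = c(1, 1, 1)) {
  vals <- rep(seq_along(counts) - 1L, counts)
  volume3d(array(vals, dim = c(length(vals), 1, 1)), spacing = spacing)
}

# Minimal candidate-set stub for filters that only look at summary fields.
fake_set <- function(volume_mm3 = 1, extents_mm = c(1, 1, 1),
                     com_world = c(0, 0, 0), intensities = 1L) {
  structure(list(voxels = matrix(0L, 1, 3), intensities = intensities,
                 volume_mm3 = volume_mm3, com_world = com_world,
                 extents_mm = extents_mm, touches_boundary = FALSE,
                 provenance = NA_integer_),
            class = "candidate_set")
}

fake_detection <- function(marker_coms, sequence = "test",
                           commanded_shift = c(0, 0, 0)) {
  pose <- device_pose(marker_coms)
  structure(list(marker_coms = marker_coms,
                 device_com = pose$device_com,
                 normal = pose$normal, theta = pose$theta, phi = pose$phi,
                 phi_degenerate = pose$phi_degenerate,
                 match_tolerance = 1,
                 rigid_fit = list(rms = 0),
                 meta = list(sequence = sequence,
                             commanded_shift = commanded_shift)),
            class = "fiducial_detection")
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Write a 3-slice single-frame DICOM series with pydicom (explicit VR LE).
write_pydicom_series <- function(dir, thickness = 6, gap = 1) {
  script <- sprintf('
import pydicom, numpy as np, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
os.makedirs(r"%s", exist_ok=True)
series = generate_uid()
for k in range(3):
    ds = Dataset()
    ds.Rows, ds.Columns = 4, 5
    ds.PixelSpacing = [1.5, 0.8]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.ImagePositionPatient = [10.0, -20.0, 5.0 + %f * k]
    ds.SliceThickness = %f
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.4"
    ds.SOPInstanceUID = generate_uid()
    ds.SeriesInstanceUID = series
    arr = np.arange(20, dtype=np.uint16).reshape(4, 5) + 100 * k
    ds.PixelData = arr.tobytes()
    meta = FileMetaDataset()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    meta.MediaStorageSOPClassUID = ds.SOPClassUID
    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    ds.file_meta = meta
    ds.save_as(os.path.join(r"%s", "slice%%03d.dcm" %% k), write_like_original=False)
', dir, thickness + gap, thickness, dir)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  status <- system2("python", f, stdout = TRUE, stderr = TRUE)
  attr(dir, "status") <- status
  dir
}
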