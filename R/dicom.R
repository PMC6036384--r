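# Minimal DICOM Part-10 reader: explicit VR little endian, single-frame
# grayscale slices, geometry tags only. This exists because no DICOM reader
# is available as a package dependency; it deliberately supports just enough
# of the standard to assemble a consistent series into a volume3d.

dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elements <- list()
  transfer_syntax <- NULL
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (vr == "SQ" || len < 0)
      stop("unsupported DICOM element (sequence/undefined length) in ", path)
    value_at <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    bytes <- if (len > 0) raw[value_at:(value_at + len - 1L)] else raw(0)
    if (key == "0002,0010")
      transfer_syntax <- sub("\\x00$", "", rawToChar(bytes))
    elements[[key]] <- list(vr = vr, bytes = bytes)
    pos <- value_at + len
  }
  if (!is.null(transfer_syntax) && transfer_syntax != "1.2.840.10008.1.2.1")
    stop("unsupported DICOM transfer syntax (explicit VR little endian only): ",
         transfer_syntax)
  elements
}

dcm_ds <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) stop("missing DICOM tag (", key, ")")
  as.numeric(strsplit(trimws(rawToChar(e$bytes)), "\\\\")[[1]])
}

dcm_us <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) stop("missing DICOM tag (", key, ")")
  readBin(e$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

dcm_pixels <- function(el, rows, cols) {
  e <- el[["7fe0,0010"]]
  if (is.null(e)) stop("missing DICOM pixel data")
  bits <- dcm_us(el, "0028,0100")
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  v <- readBin(e$bytes, "integer", n = rows * cols, size = 2,
               endian = "little", signed = dcm_us(el, "0028,0103") == 1L)
  # row-major pixel order -> array indexed [column, row]
  matrix(v, nrow = cols, ncol = rows)
}

# Assemble one orientation-consistent series into a volume3d (LPS mm).
load_dicom_dir <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("empty DICOM directory: ", path)
  slices <- lapply(files, function(f) {
    el <- dcm_read_file(f)
    rows <- dcm_us(el, "0028,0010"); cols <- dcm_us(el, "0028,0011")
    list(iop = dcm_ds(el, "0020,0037"),
         ipp = dcm_ds(el, "0020,0032"),
         ps = dcm_ds(el, "0028,0030"),
         pix = dcm_pixels(el, rows, cols))
  })
  iop <- slices[[1]]$iop
  ps <- slices[[1]]$ps
  for (s in slices) {
    if (max(abs(s$iop - iop)) > 1e-4 || max(abs(s$ps - ps)) > 1e-6)
      stop("inconsistent DICOM series: mixed orientations or pixel spacings")
    if (!all(dim(s$pix) == dim(slices[[1]]$pix)))
      stop("inconsistent DICOM series: mixed matrix sizes")
  }
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  z <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(slices) > 1) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-3)
      stop("inconsistent DICOM series: non-uniform inter-slice spacing")
    dz <- mean(dz)
  } else dz <- 1
  data <- array(0L, dim = c(dim(slices[[1]]$pix), length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$pix
  affine <- diag(4)
  affine[1:3, 1] <- row_dir * ps[2]   # column index step
  affine[1:3, 2] <- col_dir * ps[1]   # row index step
  affine[1:3, 3] <- normal * dz
  affine[1:3, 4] <- slices[[1]]$ipp
  volume3d(data, affine = affine,
           meta = list(source = path, format = "dicom",
                       slice_spacing = dz, n_slices = length(slices)))
}
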