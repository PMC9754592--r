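## Volume containers and standard-format I/O.
##
## NIfTI-1 support is implemented directly (no R NIfTI package is available
## in the target environment): single-file .nii / .nii.gz, float32 data,
## 3-D dims, sform identity scaled by the voxel spacing. Slices go to 8-bit
## grayscale PNG via the png package.

#' MR volume container
#'
#' @param voxels 3-D numeric array `(height, width, depth)` with intensities
#'   in `[0, 1]`
#' @param spacing optional numeric length-3 physical voxel size (mm)
#' @param source_id identifier string
#' @return object of class `volume_record`
#' @export
volume_record <- function(voxels, spacing = c(1, 1, 1), source_id = "") {
  stopifnot(length(dim(voxels)) == 3L)
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("volume_record: intensities must be in [0,1]; use normalize_01()")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 source_id = as.character(source_id)),
            class = "volume_record")
}

#' Min-max normalisation to [0, 1]
#'
#' Constant inputs map to all zeros (zero-range guard).
#' @param x numeric array
#' @export
normalize_01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(x) %||% length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- NIfTI-1 --------------------------------------------------------------

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1 (float32)
#'
#' @param vol a [volume_record()] or 3-D array
#' @param path output path ending in `.nii` or `.nii.gz`
#' @export
write_nifti <- function(vol, path) {
  rec <- if (inherits(vol, "volume_record")) vol else
    volume_record(vol)
  d <- dim(rec$voxels)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0L, 4); wi(0L, 2)             # extents, session_error
  writeBin(charToRaw("r"), con)    # regular
  writeBin(as.raw(0L), con)        # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1..3, intent_code
  wi(16L, 2); wi(32L, 2)           # datatype float32, bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, rec$spacing, 1, 1, 1, 1))  # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0L, 2)                        # slice_end
  writeBin(as.raw(c(0L, 2L)), con) # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc(substr(rec$source_id, 1, 79), 80) # descrip
  wc("", 24)                       # aux_file
  wi(c(0L, 1L), 2)                 # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b/c/d, qoffset x/y/z
  wf(c(rec$spacing[1], 0, 0, 0))   # srow_x
  wf(c(0, rec$spacing[2], 0, 0))   # srow_y
  wf(c(0, 0, rec$spacing[3], 0))   # srow_z
  wc("", 16)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  writeBin(raw(4), con)            # extension flag
  writeBin(as.numeric(rec$voxels), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed and gzipped single-file NIfTI with scalar data
#' types; returns a [volume_record()] with intensities min-max normalised
#' to `[0, 1]`.
#'
#' @param path `.nii` / `.nii.gz` file
#' @param normalize min-max normalise (default TRUE)
#' @export
read_nifti <- function(path, normalize = TRUE) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header in ", path)
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = "little")
  }
  if (ri(0L, 4L) != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  dm <- ri(40L, 2L, 8L)
  ndim <- dm[1]
  if (ndim < 3L) stop("read_nifti: expected a 3-D volume")
  d <- dm[2:4]
  datatype <- ri(70L, 2L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  spacing <- rf(80L, 3L)
  reader <- switch(as.character(datatype),
    "2" = function(n) readBin(con, "integer", n, size = 1L, signed = FALSE),
    "4" = function(n) readBin(con, "integer", n, size = 2L, endian = "little"),
    "8" = function(n) readBin(con, "integer", n, size = 4L, endian = "little"),
    "16" = function(n) readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = function(n) readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("read_nifti: unsupported datatype code ", datatype))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(d)
  vals <- reader(n_vox)
  if (length(vals) < n_vox) stop("read_nifti: truncated data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  vox <- array(as.numeric(vals), dim = d)
  if (normalize) vox <- normalize_01(vox)
  volume_record(vox, spacing = spacing, source_id = basename(path))
}

## ---- PNG slices -----------------------------------------------------------

#' Write a grayscale slice as 8-bit PNG
#' @param img matrix in `[0, 1]`
#' @param path output path
#' @export
write_slice_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a grayscale PNG slice
#' @param path input path
#' @export
read_slice_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1] # first channel of RGB(A)
  x
}

## ---- high-level volume I/O ------------------------------------------------

#' Read a volume from NIfTI or a directory of PNG slices
#'
#' Directories are read as alphabetically ordered PNG slices with identical
#' shapes; intensities are min-max normalised per volume.
#'
#' @param path `.nii`, `.nii.gz`, or a directory of `.png` files
#' @return a [volume_record()]
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("read_volume: no PNG slices in ", path)
    slices <- lapply(files, read_slice_png)
    d <- dim(slices[[1]])
    for (s in slices) {
      if (!identical(dim(s), d)) stop("read_volume: inconsistent slice shapes")
    }
    vox <- array(unlist(slices), dim = c(d, length(slices)))
    volume_record(normalize_01(vox), source_id = basename(path))
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    read_nifti(path)
  } else {
    stop("read_volume: unsupported input ", path,
         " (expected .nii/.nii.gz or a PNG directory)")
  }
}

#' Write a volume to NIfTI or a directory of PNG slices
#'
#' @param rec a [volume_record()]
#' @param path `.nii`/`.nii.gz` file or a directory (PNG slices)
#' @export
write_volume <- function(rec, path) {
  stopifnot(inherits(rec, "volume_record"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    write_nifti(rec, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(dim(rec$voxels)[3])) {
      write_slice_png(rec$voxels[, , k],
                      file.path(path, sprintf("slice_%04d.png", k)))
    }
    invisible(path)
  }
}
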