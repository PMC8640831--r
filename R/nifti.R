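# Minimal single-file NIfTI-1 (.nii / .nii.gz) I/O for 3D volumes.
# Supports the datatypes this package emits (float32, int16/32, uint8) and a
# diagonal sform built from spacing/origin; that is all the phantom and
# segmentation outputs need. Little-endian only (the NIfTI-1 default).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16` = list(what = "numeric", size = 4L, signed = TRUE),  # float32
  `64` = list(what = "numeric", size = 8L, signed = TRUE)   # float64
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol an [image_volume()] or [label_volume()]; label volumes are
#'   stored as int16, image volumes as float32.
#' @param path output path; a `.gz` suffix gzip-compresses the stream.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  if (inherits(vol, "label_volume")) {
    data <- vol$labels; datatype <- 4L; bitpix <- 16L
  } else if (inherits(vol, "image_volume")) {
    data <- vol$data; datatype <- 16L; bitpix <- 32L
  } else stop("`vol` must be an image_volume or label_volume")
  dims <- dim(data)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused data_type..dim_info
  writeBin(as.integer(c(3, dims, 1, 1, 1, 1)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                              # intent_p1..intent_code
  writeBin(as.integer(c(datatype, bitpix, 0)), con, size = 2)  # datatype,bitpix,slice_start
  writeBin(c(1, vol$spacing, rep(0, 4)), con, size = 4)        # pixdim[8]
  writeBin(c(352, 1, 0), con, size = 4)               # vox_offset, scl_slope, scl_inter
  writeBin(raw(28), con)                              # slice_end..glmin
  writeBin(raw(104), con)                             # descrip[80] + aux_file[24]
  writeBin(as.integer(c(0, 1)), con, size = 2)        # qform_code=0, sform_code=1
  writeBin(rep(0, 6), con, size = 4)                  # quatern b,c,d + qoffset x,y,z
  srow <- rbind(c(vol$spacing[1], 0, 0, vol$origin[1]),
                c(0, vol$spacing[2], 0, vol$origin[2]),
                c(0, 0, vol$spacing[3], vol$origin[3]))
  writeBin(as.numeric(t(srow)), con, size = 4)        # srow_x/y/z
  writeBin(raw(16), con)                              # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                               # magic terminator
  writeBin(raw(4), con)                               # extension flag
  if (datatype == 16L) {
    writeBin(as.numeric(data), con, size = 4)
  } else {
    writeBin(as.integer(data), con, size = 2)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as_labels return a [label_volume()] (integer codes) instead of an
#'   [image_volume()].
#' @return An [image_volume()] or [label_volume()].
#' @export
read_nifti <- function(path, as_labels = FALSE) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header")
  int_at <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  num_at <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (int_at(0, 4) != 348L) stop("not a little-endian NIfTI-1 file")
  dim8 <- int_at(40, 2, 8)
  if (dim8[1] < 3) stop("expected a 3D volume")
  dims <- dim8[2:4]
  datatype <- int_at(70, 2)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype ", datatype)
  pixdim <- num_at(76, 8)
  vox_offset <- num_at(108)
  scl_slope <- num_at(112); scl_inter <- num_at(116)
  sform <- int_at(254, 2)
  origin <- if (sform > 0) num_at(280, 12)[c(4, 8, 12)] else c(0, 0, 0)
  # skip from end of header to the data offset
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(data) < n) stop("truncated NIfTI data")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(data, dim = dims)
  spacing <- pixdim[2:4]
  if (as_labels) label_volume(arr, spacing = spacing, origin = origin)
  else image_volume(arr * 1.0, spacing = spacing, origin = origin)
}
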