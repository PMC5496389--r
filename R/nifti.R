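# Minimal NIfTI-1 I/O.
#
# No NIfTI reader is available in the dependency set, so the package carries a
# small, strict implementation of the parts of the standard it uses:
# single-file little-endian .nii, datatypes uint8 / int16 / float32 / float64,
# 3-D or 4-D volumes, scl_slope/scl_inter honoured on read. Arrays are stored
# in R with dim (row, col, slice[, volume]); the row index is the fastest
# varying on disk.

DT_UINT8 <- 2L
DT_INT16 <- 4L
DT_FLOAT32 <- 16L
DT_FLOAT64 <- 64L

#' Write a volume to a NIfTI-1 file
#'
#' @param x numeric or logical array, 3-D or 4-D.
#' @param path output path, conventionally ending in `.nii`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param datatype one of `"uint8"`, `"int16"`, `"float32"`, `"float64"`.
#'   Logical input defaults to `"uint8"`, numeric to `"float32"`.
#' @param t_step spacing of the 4th dimension (echo index / phase), written to
#'   `pixdim[4]`; purely informational.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size = c(1, 1, 1), datatype = NULL,
                        t_step = 1) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    cmrtc_stop("write_nifti() needs a 3-D or 4-D array", "cmrtc_config_error")
  }
  if (is.null(datatype)) datatype <- if (is.logical(x)) "uint8" else "float32"
  code <- switch(datatype,
    uint8 = DT_UINT8, int16 = DT_INT16,
    float32 = DT_FLOAT32, float64 = DT_FLOAT64,
    cmrtc_stop(paste0("unsupported datatype: ", datatype), "cmrtc_config_error")
  )
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, float32 = 32L, float64 = 64L)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }

  dim8 <- rep(1L, 8); dim8[1] <- length(d); dim8[seq_along(d) + 1] <- d
  pixdim8 <- c(1, voxel_size, t_step, 1, 1, 1)

  wi(348L, 4)                        # sizeof_hdr
  wc("", 10); wc("", 18)             # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)                        # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)          # intent_p1-3, intent_code
  wi(code, 2); wi(bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(pixdim8)                        # pixdim[8]
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0L, 2); wc("", 1)               # slice_end, slice_code
  writeBin(as.raw(2L), con)          # xyzt_units = mm
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                   # glmax, glmin
  wc("cmrtc", 80); wc("", 24)        # descrip, aux_file
  wi(0L, 2); wi(1L, 2)               # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))            # quatern_b/c/d, qoffset_x/y/z
  wf(c(voxel_size[1], 0, 0, 0))      # srow_x
  wf(c(0, voxel_size[2], 0, 0))      # srow_y
  wf(c(0, 0, voxel_size[3], 0))      # srow_z
  wc("", 16)                         # intent_name
  wc("n+1", 4)                       # magic
  writeBin(raw(4), con)              # no extensions

  vals <- as.vector(x)
  if (datatype %in% c("uint8", "int16")) {
    writeBin(as.integer(round(vals)), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any conforming
#' little-endian single-file .nii with a supported datatype)
#'
#' @param path file path.
#' @return list with `data` (array), `voxel_size`, `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    cmrtc_stop(paste0("no such file: ", path), "cmrtc_data_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) {
    cmrtc_stop(paste0("truncated NIfTI header in ", path), "cmrtc_data_error")
  }
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer",
      n = n, size = size, endian = "little",
      signed = size > 2 || size == 2
    )
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4, endian = "little")
  }
  if (ri(0, 4) != 348L) {
    cmrtc_stop(paste0("not a little-endian NIfTI-1 file: ", path), "cmrtc_data_error")
  }
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  if (!(ndim %in% c(2L, 3L, 4L))) {
    cmrtc_stop(paste0("unsupported dimensionality in ", path), "cmrtc_data_error")
  }
  d <- dim8[2:(ndim + 1)]
  code <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112)
  scl_inter <- rf(116)

  n <- prod(d)
  seek(con, vox_offset)
  vals <- switch(as.character(code),
    "2" = {
      v <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
      v
    },
    "4" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    cmrtc_stop(sprintf("unsupported NIfTI datatype code %d in %s", code, path),
      "cmrtc_data_error"
    )
  )
  if (length(vals) < n) {
    cmrtc_stop(paste0("truncated NIfTI data in ", path), "cmrtc_data_error")
  }
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(
    data = array(vals, dim = d),
    voxel_size = pixdim[2:4],
    datatype = switch(as.character(code),
      "2" = "uint8", "4" = "int16", "16" = "float32", "64" = "float64"
    )
  )
}
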