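#' Minimal NIfTI-1 input/output
#'
#' Thin single-file (.nii / .nii.gz) NIfTI-1 support sufficient for exchanging
#' spatially normalized GM probability and asymmetry-index volumes: float32
#' output with a diagonal RAS sform, and input of the common scalar datatypes
#' (uint8, int16, int32, float32, float64) with slope/intercept scaling.
#' No general NIfTI package is assumed; orientation handling is deliberately
#' restricted to diagonal sforms, with axis flips applied so the in-memory
#' array is always RAS (+x right). Anything fancier (oblique affines, qform
#' quaternions) is rejected loudly rather than guessed at.
#'
#' @param vol a `gm_volume`.
#' @param path output path; gzip compression inferred from a `.gz` suffix.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   `gm_volume`.
#' @name nifti_io
NULL

nifti_srow <- function(vol) {
  d <- dim(vol$data)
  v <- vol$voxel_size
  off <- (1 - (d + 1) / 2) * v   # world coord of 0-based voxel (0,0,0)
  rbind(c(v[1], 0, 0, off[1]),
        c(0, v[2], 0, off[2]),
        c(0, 0, v[3], off[3]))
}

#' @rdname nifti_io
#' @export
write_nifti <- function(vol, path) {
  if (!is_gm_volume(vol)) stop("`vol` must be a gm_volume")
  d <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                                  # sizeof_hdr
  wpad(36)                                     # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wf(c(0, 0, 0))                               # intent_p1..p3
  wi(0L, 2)                                    # intent_code
  wi(16L, 2)                                   # datatype = float32
  wi(32L, 2)                                   # bitpix
  wi(0L, 2)                                    # slice_start
  wf(c(1, vol$voxel_size, 0, 0, 0, 0))         # pixdim[8] (qfac = 1)
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0L, 2)                                    # slice_end
  wpad(2)                                      # slice_code, xyzt_units... next
  # note: slice_code (1 byte) + xyzt_units (1 byte) written as pad; units
  # default to unknown, voxel sizes carried by pixdim/srow in mm by convention
  wf(c(0, 0, 0, 0))                            # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4)                             # glmax, glmin
  wpad(80 + 24)                                # descrip, aux_file
  wi(0L, 2)                                    # qform_code
  wi(1L, 2)                                    # sform_code
  wf(c(0, 0, 0, 0, 0, 0))                      # quaterns + qoffsets
  s <- nifti_srow(vol)
  wf(t(s))                                     # srow_x, srow_y, srow_z
  wpad(16)                                     # intent_name
  writeBin(charToRaw("n+1"), con); wpad(1)     # magic
  wpad(4)                                      # extension indicator
  wf(as.numeric(vol$data))
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")   # gzfile transparently reads uncompressed too
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  skip <- function(n) invisible(readBin(con, "raw", n = n))

  if (ri(1, 4) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  skip(36)
  dims <- ri(8, 2)
  ndim <- dims[1]
  d <- dims[2:4]
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1)) {
    stop("only 3-D volumes are supported: ", path)
  }
  rf(3); ri(1, 2)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); skip(2)
  rf(4); ri(2, 4)
  skip(104)
  qform_code <- ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  skip(16)
  magic <- rawToChar(readBin(con, "raw", n = 4), multiple = FALSE)
  if (!startsWith(magic, "n+1")) stop("unsupported NIfTI magic: ", path)
  skip(as.integer(vox_offset) - 348L)

  n <- prod(d)
  dat <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2,
                              endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4,
                              endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype, ": ", path))
  if (length(dat) != n) stop("truncated NIfTI data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  arr <- array(dat, dim = d)

  if (sform_code > 0) {
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(abs(srow[, 1:3])))) {
      stop("non-diagonal sform; reorient input to RAS before loading: ", path)
    }
    vox <- abs(diag(srow[, 1:3]))
    for (ax in 1:3) {          # flip axes stored in LPS-like order back to RAS
      if (srow[ax, ax] < 0) {
        arr <- switch(ax,
          arr[rev(seq_len(d[1])), , , drop = FALSE],
          arr[, rev(seq_len(d[2])), , drop = FALSE],
          arr[, , rev(seq_len(d[3])), drop = FALSE])
      }
    }
  } else if (qform_code > 0) {
    stop("qform-only NIfTI orientation is not supported; set an sform: ", path)
  } else {
    vox <- pixdim[2:4]
  }
  gm_volume(arr, voxel_size = vox)
}
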