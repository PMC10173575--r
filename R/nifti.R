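# Minimal NIfTI-1 reader/writer.
#
# Covers exactly what the KiTS case layout needs: single-file .nii / .nii.gz,
# 3D grids, little- or big-endian headers, the common datatypes, pixdim
# spacing and an sform affine.  No pre-installed R package provides NIfTI in
# this toolchain, hence the hand-rolled (and oracle-tested) implementation.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "numeric", size = 4, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "numeric", size = 8, signed = TRUE,  bitpix = 64L),
  `512` = list(what = "integer", size = 2, signed = FALSE, bitpix = 16L)
)

#' Read a NIfTI-1 file
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an R
#' array.  Only 3D images are supported; the array keeps the on-disk axis
#' order, i.e. `dim[1]` is the fastest-varying axis (the axial slice axis in
#' the KiTS `num_slices-height-width` convention).
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return list with `data` (3D array), `spacing` (numeric length 3, mm),
#'   `affine` (4x4 voxel-to-world matrix) and `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  szh <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported: ", path)
  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  if (ndim < 3L) stop("expected a 3D NIfTI image, got ", ndim, "D: ", path)
  dims <- dim0[2:(ndim + 1)]
  if (ndim > 3L) {
    if (any(dims[4:ndim] != 1L)) stop("expected a 3D image, got extents ",
                                      paste(dims, collapse = "x"))
    dims <- dims[1:3]
  }
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), nrow = 3, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code <= 0L) affine <- diag(c(pixdim[2:4], 1))
  # skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  data <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < n_vox) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- dims
  list(data = data, spacing = abs(pixdim[2:4]), affine = affine,
       datatype = datatype)
}

#' Write a NIfTI-1 file
#'
#' @param data 3D numeric or integer array.
#' @param path output path; gzip-compressed iff it ends in `.gz`.
#' @param spacing voxel size per axis in mm.
#' @param affine 4x4 voxel-to-world matrix, written as the sform.
#' @param datatype `"float32"`, `"int16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1),
                        affine = diag(c(spacing, 1)),
                        datatype = c("float32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (length(dims) != 3L) stop("write_nifti expects a 3D array")
  code <- switch(datatype, float32 = 16L, int16 = 4L, uint8 = 2L)
  dt <- NIFTI_DTYPES[[as.character(code)]]
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    if (length(b) > 0) r[seq_along(b)] <- b
    writeBin(r, con)
  }
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  wchar("", 10); wchar("", 18)                        # data_type, db_name
  writeBin(0L, con, size = 4)                         # extents
  writeBin(0L, con, size = 2)                         # session_error
  wchar("r", 1); wchar("", 1)                         # regular, dim_info
  writeBin(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), con, size = 2)  # dim
  writeBin(numeric(3), con, size = 4)                 # intent_p1..3
  writeBin(c(0L, code, dt$bitpix, 0L), con, size = 2) # intent,datatype,bitpix,slice_start
  writeBin(c(1, spacing, 1, 1, 1, 1), con, size = 4)  # pixdim (qfac first)
  writeBin(c(352, 1, 0), con, size = 4)               # vox_offset, scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  wchar("", 1); writeBin(as.raw(10L), con)            # slice_code, xyzt_units (mm|s)
  writeBin(numeric(4), con, size = 4)                 # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4)                  # glmax, glmin
  wchar("", 80); wchar("", 24)                        # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2)                  # qform_code, sform_code
  writeBin(numeric(6), con, size = 4)                 # quatern/qoffset
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4)  # srow_x/y/z
  wchar("", 16)                                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4), con)                               # extension flag
  vals <- as.vector(data)
  if (datatype == "float32") {
    writeBin(as.numeric(vals), con, size = 4)
  } else {
    writeBin(as.integer(round(vals)), con, size = dt$size)
  }
  invisible(path)
}
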