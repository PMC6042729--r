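# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format the pipeline needs is supported: 3-D / 4-D
# volumes, datatypes uint8 / int16 / int32 / float32 / float64, scl_slope /
# scl_inter rescaling, and the sform affine (qform is ignored beyond a pixdim
# fallback). Written files always carry sform_code = 1 and vox_offset = 352.

.nifti_datatypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`). Voxel data are
#' returned as a numeric array with `scl_slope` / `scl_inter` applied; the
#' affine is taken from the sform when present, otherwise a diagonal pixdim
#' affine is used.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `img` (numeric array, 3-D or 4-D) and
#'   `affine` (4x4 voxel-to-world matrix).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)

  rb <- function(offset, what, n, size, signed = TRUE, endian) {
    readBin(hdr_raw[(offset + 1L):(offset + n * size)], what,
            n = n, size = size, signed = signed, endian = endian)
  }
  endian <- "little"
  if (rb(0L, "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (rb(0L, "integer", 1L, 4L, endian = endian) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }

  dim    <- rb(40L, "integer", 8L, 2L, endian = endian)
  dtcode <- rb(70L, "integer", 1L, 2L, endian = endian)
  pixdim <- rb(76L, "double", 8L, 4L, endian = endian)
  vox_offset <- rb(108L, "double", 1L, 4L, endian = endian)
  scl_slope  <- rb(112L, "double", 1L, 4L, endian = endian)
  scl_inter  <- rb(116L, "double", 1L, 4L, endian = endian)
  sform_code <- rb(254L, "integer", 1L, 2L, endian = endian)
  srow <- rbind(rb(280L, "double", 4L, 4L, endian = endian),
                rb(296L, "double", 4L, 4L, endian = endian),
                rb(312L, "double", 4L, 4L, endian = endian))

  ndim <- dim[1L]
  if (ndim < 3L || ndim > 4L) stop("unsupported NIfTI dimensionality: ", ndim)
  shape <- dim[2L:(1L + ndim)]

  spec <- Filter(function(d) d$code == dtcode, .nifti_datatypes)
  if (length(spec) == 0L) stop("unsupported NIfTI datatype code: ", dtcode)
  spec <- spec[[1L]]

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(shape)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2L:4L], 1))
  }
  list(img = array(as.numeric(vals), dim = shape), affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D or 4-D array as a single-file NIfTI-1 image with the given
#' voxel-to-world affine stored in the sform (`sform_code = 1`). Compression
#' is chosen from the file extension.
#'
#' @param img Numeric (or logical) 3-D / 4-D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype One of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, affine, path, datatype = "float32") {
  if (!is.array(img) || !(length(dim(img)) %in% c(3L, 4L)))
    stop("img must be a 3-D or 4-D array")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  spec <- .nifti_datatypes[[datatype]]
  if (is.null(spec)) stop("unsupported datatype: ", datatype)

  shape <- dim(img)
  ndim <- length(shape)
  dimfield <- rep(1L, 8L)
  dimfield[1L] <- ndim
  dimfield[2L:(1L + ndim)] <- as.integer(shape)
  # voxel sizes from the affine columns; time step left at 1
  pixdim <- rep(1, 8L)
  pixdim[2L:4L] <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w <- function(x, size = NA_integer_) {
    if (is.raw(x)) writeBin(x, con) else writeBin(x, con, size = size, endian = "little")
  }

  w(348L, 4L)                                  # sizeof_hdr
  w(raw(36L), 1L)                              # data_type..db_name, extents, session_error, regular, dim_info
  w(dimfield, 2L)                              # dim
  w(numeric(3L), 4L)                           # intent_p1..p3
  w(0L, 2L)                                    # intent_code
  w(spec$code, 2L)                             # datatype
  w(spec$bitpix, 2L)                           # bitpix
  w(0L, 2L)                                    # slice_start
  w(pixdim, 4L)                                # pixdim
  w(352, 4L)                                   # vox_offset
  w(1, 4L)                                     # scl_slope
  w(0, 4L)                                     # scl_inter
  w(0L, 2L)                                    # slice_end
  w(raw(2L), 1L)                               # slice_code, xyzt_units
  w(numeric(4L), 4L)                           # cal_max..slice_duration... (cal_max,cal_min,slice_duration,toffset)
  w(c(0L, 0L), 4L)                             # glmax, glmin
  w(raw(80L + 24L), 1L)                        # descrip, aux_file
  w(0L, 2L)                                    # qform_code
  w(1L, 2L)                                    # sform_code
  w(numeric(6L), 4L)                           # quatern_b..qoffset_z
  w(as.numeric(t(affine[1:3, ])), 4L)          # srow_x/y/z
  w(raw(16L), 1L)                              # intent_name
  w(c(charToRaw("n+1"), as.raw(0L)), 1L)       # magic
  w(raw(4L), 1L)                               # extension flag

  vals <- as.vector(img)
  if (spec$what == "integer") {
    w(as.integer(round(vals)), spec$size)
  } else if (datatype == "float32") {
    w(as.numeric(vals), 4L)
  } else {
    w(as.numeric(vals), 8L)
  }
  invisible(path)
}
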