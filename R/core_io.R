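# Dataset model shared by all pipeline stages, plus readers/writers for the
# on-disk formats: NIfTI-1 volumes, FSL-dialect bval/bvec text files, and the
# CSV subject manifest.

#' Construct and validate a gradient scheme
#'
#' A gradient scheme pairs each DWI measurement with its diffusion weighting
#' `b` (s/mm^2) and gradient direction `g`. Directions are interpreted in the
#' image coordinate frame (FSL bvec dialect). Vectors within 1e-3 of unit
#' norm are renormalized; larger deviations are an error. b = 0 entries may
#' carry a zero vector.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), all >= 0.
#' @param bvecs Numeric matrix, one row per measurement, 3 columns.
#' @return An object of class `gradient_scheme`: list with `bvals`, `bvecs`
#'   (n x 3), `n_measurements`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 columns")
  if (length(bvals) != nrow(bvecs))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs), ") lengths differ")
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("non-finite values in gradient table")
  if (any(bvals < 0)) stop("negative b-values")
  if (!any(bvals == 0)) stop("scheme must contain at least one b=0 measurement")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-3))
    stop("bvec norm deviates from 1 by more than 1e-3 for a b>0 measurement")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = bvals, bvecs = bvecs, n_measurements = length(bvals)),
            class = "gradient_scheme")
}

#' Read an FSL-dialect gradient table
#'
#' @param bval_path Whitespace-separated b-values, one line.
#' @param bvec_path 3 rows x N columns of gradient components.
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bvec_rows <- readLines(bvec_path)
  bvec_rows <- bvec_rows[nzchar(trimws(bvec_rows))]
  if (length(bvec_rows) != 3L) stop("bvec file must have 3 rows, found ", length(bvec_rows))
  comps <- lapply(bvec_rows, function(l) scan(text = l, what = numeric(), quiet = TRUE))
  n <- lengths(comps)
  if (length(unique(n)) != 1L) stop("ragged bvec file")
  gradient_scheme(bvals, cbind(comps[[1L]], comps[[2L]], comps[[3L]]))
}

#' Write an FSL-dialect gradient table
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Construct a DWI dataset
#'
#' @param signal 4-D array (x, y, z, measurement), finite, >= 0.
#' @param affine 4x4 voxel-to-world matrix.
#' @param scheme [gradient_scheme()] whose length matches the 4th dimension.
#' @return Object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, affine, scheme) {
  if (length(dim(signal)) != 4L) stop("signal must be a 4-D array")
  if (!inherits(scheme, "gradient_scheme")) stop("scheme must be a gradient_scheme")
  if (dim(signal)[4L] != scheme$n_measurements)
    stop("4th dimension (", dim(signal)[4L], ") does not match scheme (",
         scheme$n_measurements, " measurements)")
  if (any(!is.finite(signal))) stop("non-finite values in DWI signal")
  structure(list(signal = signal, affine = affine, scheme = scheme),
            class = "dwi_dataset")
}

#' Read a DWI dataset from NIfTI + bval/bvec
#'
#' @param image_path 4-D NIfTI volume.
#' @param bval_path,bvec_path FSL-dialect gradient table.
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  nii <- read_nifti(image_path)
  scheme <- read_gradient_table(bval_path, bvec_path)
  dwi_dataset(nii$img, nii$affine, scheme)
}

#' Write a DWI dataset (NIfTI + bval/bvec)
#' @param dwi A [dwi_dataset()].
#' @param image_path,bval_path,bvec_path Output paths.
#' @export
write_dwi <- function(dwi, image_path, bval_path, bvec_path) {
  write_nifti(dwi$signal, dwi$affine, image_path, datatype = "float64")
  write_gradient_table(dwi$scheme, bval_path, bvec_path)
  invisible(image_path)
}

#' Construct a region mask
#'
#' @param mask 3-D logical (or 0/1 numeric) array; must be nonempty.
#' @param label Region label, `"cerebrum"` or `"brainstem_cerebellum"`
#'   (other labels allowed for auxiliary masks such as `"background"`).
#' @param voxel_volume Voxel volume in mm^3.
#' @return Object of class `region_mask`.
#' @export
region_mask <- function(mask, label, voxel_volume = 1) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  m <- array(as.logical(mask != 0), dim = dim(mask))
  if (!any(m)) stop("empty region mask for label '", label, "'")
  structure(list(mask = m, label = label, voxel_volume = voxel_volume),
            class = "region_mask")
}

#' Read a region mask from NIfTI
#'
#' Any nonzero voxel becomes TRUE.
#'
#' @param path NIfTI file with integer/boolean (or 0.0/1.0 float) voxels.
#' @param label Region label.
#' @param companion_dim Optional 3-vector; error if the mask grid differs.
#' @return A [region_mask()].
#' @export
read_mask <- function(path, label, companion_dim = NULL) {
  nii <- read_nifti(path)
  if (length(dim(nii$img)) != 3L) stop("mask must be 3-D: ", path)
  if (!is.null(companion_dim) && !all(dim(nii$img) == companion_dim))
    stop("mask grid ", paste(dim(nii$img), collapse = "x"),
         " does not match companion DWI grid ", paste(companion_dim, collapse = "x"))
  vox <- abs(det(nii$affine[1:3, 1:3]))
  region_mask(nii$img, label, voxel_volume = vox)
}

#' Write a 3-D index map as NIfTI
#'
#' Diffusivities are stored unrescaled in mm^2/s, as float32.
#'
#' @param map3d Finite 3-D array; NaN/NA allowed only when `masked_fill` is
#'   given, in which case non-finite voxels are replaced by it.
#' @param affine 4x4 matrix.
#' @param path Output `.nii` / `.nii.gz`.
#' @param masked_fill Optional fill value for non-finite background voxels.
#' @export
write_index_map <- function(map3d, affine, path, masked_fill = NULL) {
  if (length(dim(map3d)) != 3L) stop("map must be 3-D")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  bad <- !is.finite(map3d)
  if (any(bad)) {
    if (is.null(masked_fill))
      stop("non-finite values in map; supply masked_fill to write them")
    map3d[bad] <- masked_fill
  }
  write_nifti(map3d, affine, path, datatype = "float32")
}

.manifest_cols <- c("subject_id", "group", "interval_years",
                    "iacrs_baseline", "iacrs_followup",
                    "icars_baseline", "icars_followup",
                    "cag_repeats", "disease_duration_years")

#' Validate a subject record
#'
#' Checks group labels, score ranges (IACRS 0-38, ICARS 0-100) and a positive
#' inter-scan interval. Clinical fields may be NA (controls).
#'
#' @param rec One-row data.frame or list with the manifest columns.
#' @return The record, as a one-row data.frame.
#' @export
subject_record <- function(rec) {
  rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  missing <- setdiff(.manifest_cols, names(rec))
  if (length(missing)) stop("missing manifest columns: ", paste(missing, collapse = ", "))
  if (!rec$group %in% c("patient", "control")) stop("group must be patient/control")
  if (!is.finite(rec$interval_years) || rec$interval_years <= 0)
    stop("interval_years must be > 0")
  chk <- function(v, lo, hi, nm) {
    if (!is.na(v) && (v < lo || v > hi)) stop(nm, " out of range [", lo, ",", hi, "]: ", v)
  }
  chk(rec$iacrs_baseline, 0, 38, "iacrs_baseline")
  chk(rec$iacrs_followup, 0, 38, "iacrs_followup")
  chk(rec$icars_baseline, 0, 100, "icars_baseline")
  chk(rec$icars_followup, 0, 100, "icars_followup")
  rec[.manifest_cols]
}

#' Read a subject manifest CSV
#' @param path CSV with one row per subject and the standard columns.
#' @return data.frame of validated subject records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) subject_record(df[i, ])))
  rownames(out) <- NULL
  out
}

#' Write a subject manifest CSV
#' @param manifest data.frame of subject records.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[.manifest_cols], path, row.names = FALSE)
  invisible(path)
}
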