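# Eigen-decomposition of the tensor field and the five rotationally
# invariant index maps: mean diffusivity MD = (l1+l2+l3)/3, axial
# diffusivity AD = l1, radial diffusivity RD = (l2+l3)/2, fractional
# anisotropy FA = sqrt(3/2) * ||l - mean(l)|| / ||l||, and mode of
# anisotropy MO = 3*sqrt(6)*det(A/||A||_F) with A the deviatoric tensor
# D - MD*I. MO runs from -1 (planar anisotropy) to +1 (linear anisotropy).

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorized over rows of
# a V x 6 component matrix (xx, yy, zz, xy, xz, yz). Trigonometric solution
# of the characteristic cubic; returns V x 3, descending.
sym3_eigenvalues <- function(d6) {
  d6 <- matrix(d6, ncol = 6L)
  a11 <- d6[, 1L]; a22 <- d6[, 2L]; a33 <- d6[, 3L]
  a12 <- d6[, 4L]; a13 <- d6[, 5L]; a23 <- d6[, 6L]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  lam <- cbind(q, q, q)
  nz <- which(p > 0 & is.finite(p))
  if (length(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detb / 2))
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    lam[nz, ] <- cbind(l1, 3 * q[nz] - l1 - l3, l3)
  }
  dimnames(lam) <- NULL
  lam
}

.tf_masked <- function(tensor_field) {
  idx <- which(tensor_field$valid)
  flat <- prod(tensor_field$grid)
  d6 <- sapply(1:6, function(k) tensor_field$d6[idx + (k - 1L) * flat])
  list(idx = idx, d6 = matrix(d6, ncol = 6L))
}

#' Eigen-decompose a tensor field
#'
#' Eigenvalues are computed in closed form (vectorized trigonometric solution
#' for symmetric 3x3 matrices) and returned in descending order, unclamped:
#' small negative eigenvalues from noisy fits are kept as-is and handled by
#' the index validity rules. Eigenvectors are computed per voxel with
#' [base::eigen()] only on request.
#'
#' @param tensor_field A `tensor_field` from one of the fitters, or a V x 6
#'   matrix of tensor components.
#' @param vectors If TRUE, also return per-voxel orthonormal eigenvectors.
#' @return An `eigen_system`: list with `values` (V x 3, descending), `idx`
#'   (voxel indices into the grid; NULL for matrix input), `grid`, and
#'   optionally `vectors` (list of 3x3 matrices, columns = eigenvectors).
#' @export
eigendecompose <- function(tensor_field, vectors = FALSE) {
  if (inherits(tensor_field, "tensor_field")) {
    mm <- .tf_masked(tensor_field)
    idx <- mm$idx; d6 <- mm$d6; grid <- tensor_field$grid
  } else {
    d6 <- matrix(tensor_field, ncol = 6L)
    idx <- NULL; grid <- NULL
  }
  if (any(!is.finite(d6))) stop("non-finite tensor components")
  vals <- sym3_eigenvalues(d6)
  vecs <- NULL
  if (vectors) {
    vecs <- lapply(seq_len(nrow(d6)), function(v) {
      e <- eigen(tensor6_to_mat(d6[v, ]), symmetric = TRUE)
      e$vectors
    })
  }
  structure(list(values = vals, vectors = vecs, d6 = d6, idx = idx, grid = grid),
            class = "eigen_system")
}

#' Compute the five DTI index maps from an eigen-system
#'
#' `MD = (l1+l2+l3)/3`; `AD = l1`; `RD = (l2+l3)/2`;
#' `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))`;
#' `MO = 3*sqrt(6) * det(A / ||A||_F)` with `A = D - MD*I` the deviatoric
#' tensor (equivalently `3*sqrt(6) * prod(l - MD) / ||l - MD||^3`).
#'
#' Validity rules: a voxel is invalid when `l1 <= 0` or the FA denominator is
#' zero (all-zero tensor). Isotropic voxels (`||A||_F < 1e-12 * MD`) get
#' `MO = 0` and are flagged in `isotropic`. Negative eigenvalues are used
#' as-is, never clamped.
#'
#' @param es An `eigen_system` from [eigendecompose()].
#' @return An `index_maps` object. For tensor-field input: list of 3-D maps
#'   `md`, `fa`, `ad`, `rd`, `mo` plus logical `valid` and `isotropic` maps.
#'   For matrix input the same fields as vectors.
#' @export
compute_indices <- function(es) {
  if (!inherits(es, "eigen_system")) stop("es must come from eigendecompose()")
  l <- es$values
  md <- rowMeans(l)
  ad <- l[, 1L]
  rd <- (l[, 2L] + l[, 3L]) / 2
  dev <- l - md
  devnorm2 <- rowSums(dev^2)
  sumsq <- rowSums(l^2)
  fa <- sqrt(1.5) * sqrt(devnorm2 / sumsq)
  devnorm <- sqrt(devnorm2)
  mo <- 3 * sqrt(6) * (dev[, 1L] * dev[, 2L] * dev[, 3L]) / devnorm^3
  iso <- devnorm < 1e-12 * abs(md)
  mo[iso | devnorm == 0] <- 0
  valid <- ad > 0 & sumsq > 0 & is.finite(md)
  fa[sumsq == 0] <- NA_real_

  if (is.null(es$idx)) {
    return(structure(list(md = md, fa = fa, ad = ad, rd = rd, mo = mo,
                          valid = valid, isotropic = iso | devnorm == 0),
                     class = "index_maps"))
  }
  grid <- es$grid
  mk <- function(v, fill = NA_real_) { a <- array(fill, dim = grid); a[es$idx] <- v; a }
  structure(list(md = mk(md), fa = mk(fa), ad = mk(ad), rd = mk(rd), mo = mk(mo),
                 valid = mk(valid, FALSE) == 1, isotropic = mk(iso, FALSE) == 1,
                 grid = grid),
            class = "index_maps")
}

#' Fit-to-maps convenience wrapper
#'
#' Eigendecomposes a tensor field and computes all five index maps.
#'
#' @param tensor_field A `tensor_field`.
#' @return An `index_maps` object (3-D maps).
#' @export
tensor_to_indices <- function(tensor_field) {
  compute_indices(eigendecompose(tensor_field))
}

#' Write index maps to a directory
#'
#' Writes `md.nii.gz`, `fa.nii.gz`, `ad.nii.gz`, `rd.nii.gz`, `mo.nii.gz`
#' and `valid.nii.gz`; background (invalid) voxels are filled with 0.
#'
#' @param maps An `index_maps` object with 3-D maps.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dir Output directory.
#' @export
write_index_maps <- function(maps, affine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("md", "fa", "ad", "rd", "mo"))
    write_index_map(maps[[nm]], affine, file.path(dir, paste0(nm, ".nii.gz")),
                    masked_fill = 0)
  write_nifti(maps$valid + 0, affine, file.path(dir, "valid.nii.gz"), datatype = "uint8")
  invisible(dir)
}
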