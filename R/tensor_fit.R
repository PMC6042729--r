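# Per-voxel diffusion tensor estimation from the log-linearized
# monoexponential model ln S = ln S0 - b g'Dg: b-matrix construction and
# rotation, ordinary and weighted least squares, and the RESTORE robust fit
# with iterative Geman-McClure reweighting and outlier exclusion.

#' Build the b-matrix / design matrix for a gradient scheme
#'
#' Each measurement contributes the row
#' `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` (cross terms doubled:
#' the classic silent-error convention, fixed here and unit-tested). The
#' regression design is `[-bmat | 1]` so that the coefficient vector is
#' `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, ln S0)`.
#'
#' @param scheme A [gradient_scheme()].
#' @return Object of class `bmatrix`: list with `bmat` (n x 6), `design`
#'   (n x 7), and the originating `scheme`.
#' @export
build_bmatrix <- function(scheme) {
  if (!inherits(scheme, "gradient_scheme")) stop("scheme must be a gradient_scheme")
  g <- scheme$bvecs
  bmat <- scheme$bvals * cbind(g[, 1L]^2, g[, 2L]^2, g[, 3L]^2,
                               2 * g[, 1L] * g[, 2L],
                               2 * g[, 1L] * g[, 3L],
                               2 * g[, 2L] * g[, 3L])
  design <- cbind(-bmat, 1)
  if (qr(design)$rank < 7L)
    stop("rank-deficient gradient scheme: directions are collinear or coplanar")
  structure(list(bmat = bmat, design = design, scheme = scheme), class = "bmatrix")
}

#' Extract the rotational part of an affine by polar decomposition
#'
#' @param affine_4x4 4x4 (or 3x3) matrix; the 3x3 block must be invertible.
#' @return 3x3 orthogonal matrix R from the polar factorization `A = R P`.
#' @export
polar_rotation <- function(affine_4x4) {
  a <- as.matrix(affine_4x4)
  a3 <- a[1:3, 1:3]
  if (any(!is.finite(a3)) || abs(det(a3)) < 1e-12)
    stop("singular 3x3 block: no rotational part")
  sv <- svd(a3)
  sv$u %*% t(sv$v)
}

#' Reorient a b-matrix by the rotational part of an affine
#'
#' Extracts the rotation R from the affine's 3x3 block via polar
#' decomposition (unique, insensitive to the scaling/shear an eddy-current
#' correction introduces), maps every gradient direction g to R g, and
#' rebuilds the rows. b-values are unchanged.
#'
#' @param bmatrix A [build_bmatrix()] result.
#' @param affine_4x4 The registration affine.
#' @return A new `bmatrix`.
#' @export
rotate_bmatrix <- function(bmatrix, affine_4x4) {
  if (!inherits(bmatrix, "bmatrix")) stop("bmatrix must come from build_bmatrix()")
  r <- polar_rotation(affine_4x4)
  sch <- bmatrix$scheme
  rotated <- gradient_scheme(sch$bvals, t(r %*% t(sch$bvecs)))
  build_bmatrix(rotated)
}

.as_mask_array <- function(mask, grid) {
  if (is.null(mask)) return(array(TRUE, dim = grid))
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  if (!all(dim(m) == grid)) stop("mask grid does not match DWI grid")
  array(as.logical(m), dim = grid)
}

# Clamp non-positive signals to half the voxel's smallest positive
# measurement (Rician floor can yield zeros at high b). Returns the clamped
# V x M matrix, a per-voxel clamp count, and a usable-voxel flag.
.clamp_signals <- function(y) {
  clamped <- integer(nrow(y))
  bad <- y <= 0
  if (any(bad)) {
    rows <- which(rowSums(bad) > 0L)
    for (v in rows) {
      pos <- y[v, y[v, ] > 0]
      if (length(pos) == 0L) next
      y[v, bad[v, ]] <- 0.5 * min(pos)
      clamped[v] <- sum(bad[v, ])
    }
  }
  usable <- rowSums(y > 0) >= 7L
  list(y = y, clamped = clamped, usable = usable)
}

.method_codes <- c(invalid = 0L, lls = 1L, wlls = 2L, restore = 3L, restore_fallback = 4L)

.new_tensor_field <- function(grid, idx, d6, log_s0, outliers, method_code,
                              valid, clamped, scheme) {
  mk3 <- function(fill = NA_real_) array(fill, dim = grid)
  d6_arr <- array(NA_real_, dim = c(grid, 6L))
  flat <- prod(grid)
  for (k in 1:6) d6_arr[idx + (k - 1L) * flat] <- d6[, k]
  ls0 <- mk3(); ls0[idx] <- log_s0
  out <- array(0L, dim = grid); out[idx] <- outliers
  met <- array(0L, dim = grid); met[idx] <- method_code
  val <- array(FALSE, dim = grid); val[idx] <- valid & rowSums(is.finite(d6)) == 6L
  clm <- array(0L, dim = grid); clm[idx] <- clamped
  structure(list(d6 = d6_arr, log_s0 = ls0, outlier_count = out,
                 method = met, method_levels = names(.method_codes),
                 valid = val, clamped = clm, grid = grid, scheme = scheme),
            class = "tensor_field")
}

# Weighted LLS on log-signals for one voxel; w length M (subset allowed).
.wls_solve <- function(x, logy, w) {
  xw <- x * w
  solve(crossprod(xw, x), crossprod(xw, logy))[, 1L]
}

# Vectorized OLS: theta (7 x V) for all voxels at once.
.ols_all <- function(x, logy_t) solve(crossprod(x), crossprod(x, logy_t))

# Vectorized weighted LS across voxels: per-voxel 7x7 normal equations
# assembled by one matrix product, then small dense solves.
.wls_all <- function(x, logy_t, w_t) {
  m <- nrow(x)
  p <- matrix(0, m, 49L)
  for (i in seq_len(m)) p[i, ] <- as.numeric(tcrossprod(x[i, ]))
  nv <- ncol(logy_t)
  nmat <- crossprod(p, w_t)              # 49 x V
  rhs <- crossprod(x, w_t * logy_t)      # 7 x V
  th <- matrix(NA_real_, 7L, nv)
  for (v in seq_len(nv)) {
    a <- matrix(nmat[, v], 7L, 7L)
    b <- rhs[, v]
    if (all(is.finite(a)) && all(is.finite(b)))
      th[, v] <- tryCatch(solve(a, b), error = function(e) rep(NA_real_, 7L))
  }
  th
}

.fit_prepare <- function(dwi, bmatrix, mask) {
  if (!inherits(dwi, "dwi_dataset")) stop("dwi must be a dwi_dataset")
  if (!inherits(bmatrix, "bmatrix")) stop("bmatrix must come from build_bmatrix()")
  grid <- dim(dwi$signal)[1:3]
  m <- dim(dwi$signal)[4L]
  if (m < 7L) stop("at least 7 measurements are required to fit a tensor")
  if (m != nrow(bmatrix$design)) stop("b-matrix rows do not match measurement count")
  marr <- .as_mask_array(mask, grid)
  idx <- which(marr)
  if (length(idx) == 0L) stop("empty mask")
  y <- matrix(dwi$signal, ncol = m)[idx, , drop = FALSE]
  cl <- .clamp_signals(y)
  y <- cl$y
  y[!cl$usable, ] <- 1   # placeholder; these voxels are flagged invalid
  list(grid = grid, m = m, idx = idx, y = y, clamped = cl$clamped, usable = cl$usable)
}

#' Ordinary least-squares tensor fit
#'
#' Log-linear fit of the monoexponential signal model per voxel. Non-positive
#' signals are clamped to half the voxel's smallest positive measurement and
#' counted in `clamped`; voxels with fewer than 7 usable measurements are
#' marked invalid.
#'
#' @param dwi A [dwi_dataset()].
#' @param bmatrix A [build_bmatrix()] result matching the scheme.
#' @param mask Optional [region_mask()] / logical array; default all voxels.
#' @return A `tensor_field`: per-voxel tensor 6-vector arrays (`d6`),
#'   `log_s0`, `outlier_count`, `method` codes, `valid` mask, `clamped`
#'   counts.
#' @export
fit_tensor_lls <- function(dwi, bmatrix, mask = NULL) {
  pr <- .fit_prepare(dwi, bmatrix, mask)
  x <- bmatrix$design
  th <- .ols_all(x, t(log(pr$y)))
  .new_tensor_field(pr$grid, pr$idx, t(th[1:6, , drop = FALSE]), th[7L, ],
                    integer(length(pr$idx)), .method_codes[["lls"]] * as.integer(pr$usable),
                    pr$usable, pr$clamped, bmatrix$scheme)
}

# Shared WLLS core: one reweighting pass with weights = predicted signal^2.
.wlls_theta <- function(x, logy_t) {
  th0 <- .ols_all(x, logy_t)
  w <- exp(2 * (x %*% th0))   # squared predicted signals, M x V
  # normalize per voxel (scale does not affect the WLS solution) to avoid
  # overflow from pathological (noise-only) voxels
  w <- w / rep(apply(w, 2L, max), each = nrow(w))
  w[!is.finite(w)] <- 1
  .wls_all(x, logy_t, w)
}

#' Weighted least-squares tensor fit
#'
#' One reweighting iteration of the log-linear fit with weights equal to the
#' squared predicted signals from an initial OLS pass; the standard variance
#' stabilization for log-transformed Rician-corrupted magnitudes.
#'
#' @inheritParams fit_tensor_lls
#' @return A `tensor_field`.
#' @export
fit_tensor_wlls <- function(dwi, bmatrix, mask = NULL) {
  pr <- .fit_prepare(dwi, bmatrix, mask)
  x <- bmatrix$design
  th <- .wlls_theta(x, t(log(pr$y)))
  .new_tensor_field(pr$grid, pr$idx, t(th[1:6, , drop = FALSE]), th[7L, ],
                    integer(length(pr$idx)), .method_codes[["wlls"]] * as.integer(pr$usable),
                    pr$usable, pr$clamped, bmatrix$scheme)
}

#' RESTORE robust tensor fit
#'
#' Per voxel: (1) WLLS initial fit; (2) if all signal-domain residuals lie
#' within `3 * noise_sigma`, accept it; (3) otherwise iteratively reweight
#' with Geman-McClure weights `w_i = 1 / (r_i^2 + C^2)^2`,
#' `C = 1.4826 * median(|r|)`, until the maximum relative weight change is
#' below 1e-6 or 50 iterations; (4) flag measurements with
#' `|r| > 3 * noise_sigma` as outliers and refit by WLLS excluding them;
#' (5) if fewer than 7 measurements survive, fall back to the full-data WLLS
#' fit (`restore_fallback`).
#'
#' @inheritParams fit_tensor_lls
#' @param noise_sigma Rician channel SD (> 0), e.g. from
#'   [estimate_noise_sigma()].
#' @return A `tensor_field` with per-voxel `outlier_count` and method flags.
#' @export
fit_tensor_restore <- function(dwi, bmatrix, mask = NULL, noise_sigma) {
  if (missing(noise_sigma) || !is.finite(noise_sigma) || noise_sigma <= 0)
    stop("noise_sigma must be a positive number")
  pr <- .fit_prepare(dwi, bmatrix, mask)
  x <- bmatrix$design
  m <- pr$m
  logy_t <- t(log(pr$y))
  th <- .wlls_theta(x, logy_t)
  resid <- t(pr$y) - exp(x %*% th)              # M x V, signal domain
  thr <- 3 * noise_sigma
  suspect <- which(apply(abs(resid), 2L, max) > thr & pr$usable)

  outliers <- integer(length(pr$idx))
  method <- rep(.method_codes[["restore"]], length(pr$idx))
  method[!pr$usable] <- .method_codes[["invalid"]]

  for (v in suspect) {
    logy <- logy_t[, v]
    yv <- pr$y[v, ]
    thv <- th[, v]
    w_old <- rep(1, m)
    for (it in seq_len(50L)) {
      r <- yv - exp(x %*% thv)[, 1L]
      cc <- 1.4826 * stats::median(abs(r))
      if (cc <= 1e-12 * noise_sigma) break      # residuals collapsed: converged
      w <- 1 / (r^2 + cc^2)^2
      w <- w / max(w)
      if (max(abs(w - w_old) / pmax(w_old, 1e-300)) < 1e-6) break
      w_old <- w
      thv_new <- tryCatch(.wls_solve(x, logy, w), error = function(e) NULL)
      if (is.null(thv_new) || any(!is.finite(thv_new))) break
      thv <- thv_new
    }
    r <- yv - exp(x %*% thv)[, 1L]
    out <- abs(r) > thr
    if (m - sum(out) >= 7L) {
      keep <- !out
      xs <- x[keep, , drop = FALSE]
      if (qr(xs)$rank == 7L) {
        th0 <- .wls_solve(xs, logy[keep], rep(1, sum(keep)))
        wk <- exp(2 * (xs %*% th0))[, 1L]
        th[, v] <- .wls_solve(xs, logy[keep], wk)
        outliers[v] <- sum(out)
        next
      }
    }
    method[v] <- .method_codes[["restore_fallback"]]   # keep full-data WLLS fit
  }

  .new_tensor_field(pr$grid, pr$idx, t(th[1:6, , drop = FALSE]), th[7L, ],
                    outliers, method, pr$usable, pr$clamped, bmatrix$scheme)
}

#' Estimate the Rician noise sigma from background voxels
#'
#' Rayleigh moment estimator `sigma = sqrt(mean(background^2) / 2)` over all
#' measurements of all background voxels.
#'
#' @param dwi A [dwi_dataset()].
#' @param background_mask Logical array / [region_mask()] of air voxels
#'   outside the head; at least 100 voxels.
#' @return Estimated channel SD (0 for an all-zero background).
#' @export
estimate_noise_sigma <- function(dwi, background_mask) {
  grid <- dim(dwi$signal)[1:3]
  m <- .as_mask_array(background_mask, grid)
  n <- sum(m)
  if (n == 0L) stop("empty background mask")
  if (n < 100L) stop("background mask too small (", n, " voxels; need >= 100)")
  vals <- matrix(dwi$signal, ncol = dim(dwi$signal)[4L])[which(m), ]
  sqrt(mean(vals^2) / 2)
}
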