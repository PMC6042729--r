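# Two-compartment, two-group, two-timepoint synthetic DWI phantom with known
# ground-truth tensors. Geometry is two non-overlapping axis-aligned boxes
# ("cerebrum", "brainstem_cerebellum") in a larger grid whose remainder is
# noise-only background; histogram analysis uses no spatial information, so
# the masks only need to be distinct.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code does not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.scheme_cache <- new.env(parent = emptyenv())

# Deterministic substream seed derivation; stays below 2^31.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

#' Generate a diffusion gradient scheme by electrostatic repulsion
#'
#' Places `n_directions` unit vectors on the sphere by minimizing an
#' antipodally symmetric Coulomb-like energy (pairs +-g repel), prepended
#' with a single b = 0 measurement. Deterministic given `seed`. The result is
#' non-coplanar (direction matrix rank 3) with pairwise angular separation
#' (modulo sign) of at least 10 degrees.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6).
#' @param b_value Diffusion weighting for the non-zero shell (s/mm^2).
#' @param seed Integer seed for the initial configuration.
#' @return A [gradient_scheme()] with `n_directions + 1` measurements.
#' @export
make_gradient_scheme <- function(n_directions, b_value = 1000, seed = 1L) {
  if (n_directions < 6L) stop("at least 6 directions are required for a tensor fit")
  key <- paste(n_directions, b_value, seed, sep = "_")
  cached <- .scheme_cache[[key]]
  if (!is.null(cached)) return(cached)
  g <- with_seed(derive_seed(seed, 7L), {
    x <- matrix(stats::rnorm(3L * n_directions), ncol = 3L)
    x / sqrt(rowSums(x^2))
  })
  step <- 0.05
  for (iter in seq_len(500L)) {
    frc <- matrix(0, n_directions, 3L)
    for (i in seq_len(n_directions)) {
      d1 <- sweep(g[-i, , drop = FALSE], 2L, g[i, ], function(a, b) b - a)   # g_i - g_j
      d2 <- sweep(-g[-i, , drop = FALSE], 2L, g[i, ], function(a, b) b - a)  # g_i + g_j
      w1 <- rowSums(d1^2); w2 <- rowSums(d2^2)
      frc[i, ] <- colSums(d1 / pmax(w1, 1e-12)^2) + colSums(d2 / pmax(w2, 1e-12)^2)
    }
    g <- g + step * frc / max(sqrt(rowSums(frc^2)))
    g <- g / sqrt(rowSums(g^2))
    if (iter %% 100L == 0L) step <- step / 2
  }
  dots <- abs(tcrossprod(g))
  diag(dots) <- 0
  min_angle <- acos(min(1, max(dots))) * 180 / pi
  if (min_angle < 10)
    stop("direction placement failed: minimum angular separation ", round(min_angle, 2), " deg")
  if (qr(g)$rank < 3L) stop("direction placement failed: coplanar set")
  out <- gradient_scheme(c(0, rep(b_value, n_directions)), rbind(c(0, 0, 0), g))
  .scheme_cache[[key]] <- out
  out
}

# 3x3 symmetric tensor <-> 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor6_to_mat <- function(d6) {
  matrix(c(d6[1L], d6[4L], d6[5L],
           d6[4L], d6[2L], d6[6L],
           d6[5L], d6[6L], d6[3L]), 3L, 3L)
}
tensor_mat_to6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

# Quadratic forms b * g' D g for every measurement x voxel; d6 is V x 6.
.tensor_attenuation <- function(d6, scheme) {
  g <- scheme$bvecs
  Q <- cbind(g[, 1L]^2, g[, 2L]^2, g[, 3L]^2,
             2 * g[, 1L] * g[, 2L], 2 * g[, 1L] * g[, 3L], 2 * g[, 2L] * g[, 3L])
  (scheme$bvals * Q) %*% t(d6)   # n_meas x V
}

#' Simulate noise-free DWI signals from a tensor
#'
#' Monoexponential model `S = s0 * exp(-b g' D g)`. The b = 0 measurements
#' equal `s0` exactly.
#'
#' @param tensor 3x3 symmetric PSD matrix, or 6-vector
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), in mm^2/s.
#' @param scheme A [gradient_scheme()].
#' @param s0 Non-diffusion-weighted signal (> 0).
#' @return Numeric vector of length `scheme$n_measurements`.
#' @export
simulate_signal <- function(tensor, scheme, s0 = 1000) {
  d6 <- if (is.matrix(tensor)) tensor_mat_to6(tensor) else as.numeric(tensor)
  if (length(d6) != 6L) stop("tensor must be a 3x3 matrix or 6-vector")
  q <- .tensor_attenuation(matrix(d6, nrow = 1L), scheme)[, 1L]
  if (any(q < -1e-12 * max(scheme$bvals)))
    stop("negative apparent diffusivity along a gradient: tensor is not PSD")
  as.numeric(s0 * exp(-pmax(q, 0)))
}

#' Add Rician noise to signals
#'
#' Returns `sqrt((S + e1)^2 + e2^2)` with `e1, e2` iid zero-mean Gaussians of
#' standard deviation `noise_sigma` (the magnitude-MRI noise model).
#' Reproducible given `seed`; `noise_sigma = 0` is the identity.
#'
#' @param signals Numeric array/vector of noise-free signals (>= 0).
#' @param noise_sigma Channel standard deviation (same units as the signal).
#' @param seed Integer seed.
#' @return Noisy signals, same shape as `signals`.
#' @export
add_rician_noise <- function(signals, noise_sigma, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(signals < 0)) stop("signals must be >= 0")
  if (noise_sigma == 0) return(signals)
  n <- length(signals)
  noisy <- with_seed(seed, {
    e1 <- stats::rnorm(n, 0, noise_sigma)
    e2 <- stats::rnorm(n, 0, noise_sigma)
    sqrt((as.numeric(signals) + e1)^2 + e2^2)
  })
  if (is.array(signals)) array(noisy, dim = dim(signals)) else noisy
}

.box_indices <- function(grid, from, to) {
  idx <- array(FALSE, dim = grid)
  idx[from[1L]:to[1L], from[2L]:to[2L], from[3L]:to[3L]] <- TRUE
  idx
}

#' Specification of a synthetic two-compartment DWI study
#'
#' Defaults encode the emulated study design: 9 patients vs 16 controls,
#' scanned twice 2.2-4.0 (patients) / 1.9-4.7 (controls) years apart, 15
#' directions at b = 1000 s/mm^2 plus one b = 0, Rician noise at SNR
#' `s0 / noise_sigma` = 20. Compartment eigenvalue means are calibrated so
#' that the true axial/radial diffusivity medians reproduce the shape of the
#' emulated study's region medians (controls' brainstem-cerebellum
#' (1.00, 0.70, 0.70)x10^-3 mm^2/s, patients' (1.30, 1.03, 1.03)x10^-3, both
#' groups' cerebrum (1.05, 0.69, 0.69)x10^-3). The longitudinal effect scales
#' patients' brainstem-cerebellum eigenvalues uniformly so true MD grows at
#' `md_rate_patient_bc` per year (0.010x10^-3 mm^2/s/year by default, vs
#' -0.003x10^-3 for controls); uniform scaling preserves FA and MO.
#'
#' @param grid_shape 3 integers; each compartment must hold >= 200 voxels.
#' @param n_patients,n_controls Group sizes.
#' @param eig_control_bc,eig_patient_bc,eig_cerebrum Mean eigenvalue triples
#'   (descending, mm^2/s).
#' @param jitter Per-voxel multiplicative eigenvalue jitter fraction in
#'   `[0, 0.5]` (each eigenvalue scaled by `1 + jitter * U(-1, 1)`, re-sorted).
#' @param direction_model `"random"` (uniform orientations) or `"fixed"`.
#' @param s0 Baseline b = 0 intensity (arbitrary units).
#' @param noise_sigma Rician channel SD, same units as `s0`.
#' @param md_rate_patient_bc,md_rate_control MD rate of change (mm^2/s per
#'   year) in patients' / controls' brainstem-cerebellum.
#' @param md_rate_cerebrum Cerebrum MD rate applied to both groups.
#' @param fa_drift Additional per-year FA drift (default 0; the emulated
#'   design found a longitudinal effect only in MD).
#' @param interval_patients,interval_controls Uniform (low, high) ranges for
#'   the inter-scan interval in years.
#' @param n_directions,b_value Gradient scheme parameters.
#' @param scheme_seed Seed for the gradient-direction placement. Kept
#'   separate from `seed` because the acquisition protocol is fixed across a
#'   study (and across replicate studies), as on a real scanner.
#' @param seed Global seed; all per-subject substreams derive from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L),
                         n_patients = 9L, n_controls = 16L,
                         eig_control_bc = c(1.00, 0.70, 0.70) * 1e-3,
                         eig_patient_bc = c(1.30, 1.03, 1.03) * 1e-3,
                         eig_cerebrum   = c(1.05, 0.69, 0.69) * 1e-3,
                         jitter = 0.10,
                         direction_model = c("random", "fixed"),
                         s0 = 1000, noise_sigma = 50,
                         md_rate_patient_bc = 0.010e-3,
                         md_rate_control = -0.003e-3,
                         md_rate_cerebrum = 0,
                         fa_drift = 0,
                         interval_patients = c(2.2, 4.0),
                         interval_controls = c(1.9, 4.7),
                         n_directions = 15L, b_value = 1000,
                         scheme_seed = 1L,
                         seed = 1L) {
  direction_model <- match.arg(direction_model)
  for (e in list(eig_control_bc, eig_patient_bc, eig_cerebrum)) {
    if (any(e <= 0) || is.unsorted(rev(e))) stop("eigenvalue means must be positive and descending")
  }
  if (jitter < 0 || jitter > 0.5) stop("jitter fraction must lie in [0, 0.5]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers >= 8")

  # two boxes split along z, one-voxel margins; remainder is background
  nz <- grid_shape[3L]
  zsplit <- max(3L, nz %/% 2L)
  cer_mask <- .box_indices(grid_shape, c(2L, 2L, 2L), c(grid_shape[1L] - 1L, grid_shape[2L] - 1L, zsplit - 1L))
  bc_mask  <- .box_indices(grid_shape, c(2L, 2L, zsplit + 1L), c(grid_shape[1L] - 1L, grid_shape[2L] - 1L, nz - 1L))
  if (sum(cer_mask) < 200L || sum(bc_mask) < 200L)
    stop("grid too small: each compartment needs >= 200 voxels")

  structure(list(grid_shape = grid_shape,
                 cerebrum_mask = cer_mask, bc_mask = bc_mask,
                 n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
                 eig_control_bc = eig_control_bc, eig_patient_bc = eig_patient_bc,
                 eig_cerebrum = eig_cerebrum,
                 jitter = jitter, direction_model = direction_model,
                 s0 = s0, noise_sigma = noise_sigma,
                 md_rate_patient_bc = md_rate_patient_bc,
                 md_rate_control = md_rate_control,
                 md_rate_cerebrum = md_rate_cerebrum,
                 fa_drift = fa_drift,
                 interval_patients = interval_patients,
                 interval_controls = interval_controls,
                 n_directions = as.integer(n_directions), b_value = b_value,
                 scheme_seed = as.integer(scheme_seed),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# V random rotation matrices as three orthonormal column triples, vectorized.
.random_frames <- function(v) {
  n1 <- matrix(stats::rnorm(3L * v), v, 3L)
  e1 <- n1 / sqrt(rowSums(n1^2))
  n2 <- matrix(stats::rnorm(3L * v), v, 3L)
  n2 <- n2 - rowSums(n2 * e1) * e1
  e2 <- n2 / sqrt(rowSums(n2^2))
  e3 <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  list(e1 = e1, e2 = e2, e3 = e3)
}

# Per-voxel tensors (V x 6) from jittered eigenvalue triples and orientations.
.compartment_tensors <- function(v, eig_mean, jitter, direction_model) {
  lam <- matrix(rep(eig_mean, each = v), v, 3L)
  if (jitter > 0) {
    lam <- lam * (1 + jitter * matrix(stats::runif(3L * v, -1, 1), v, 3L))
    hi <- pmax(lam[, 1L], lam[, 2L], lam[, 3L])
    lo <- pmin(lam[, 1L], lam[, 2L], lam[, 3L])
    lam <- cbind(hi, rowSums(lam) - hi - lo, lo)
  }
  if (direction_model == "fixed") {
    d6 <- cbind(lam[, 1L], lam[, 2L], lam[, 3L], 0, 0, 0)
  } else {
    f <- .random_frames(v)
    outer6 <- function(e) cbind(e[, 1L]^2, e[, 2L]^2, e[, 3L]^2,
                                e[, 1L] * e[, 2L], e[, 1L] * e[, 3L], e[, 2L] * e[, 3L])
    d6 <- lam[, 1L] * outer6(f$e1) + lam[, 2L] * outer6(f$e2) + lam[, 3L] * outer6(f$e3)
  }
  list(d6 = d6, lambda = lam)
}

#' Generate a complete synthetic two-timepoint DWI study
#'
#' Builds per-subject baseline and follow-up DWI datasets on a shared grid,
#' region masks, a clinical manifest, and ground truth (per-voxel tensors and
#' per-compartment true index medians). Patients' brainstem-cerebellum
#' tensors at follow-up are scaled uniformly so true MD increases by
#' `md_rate_patient_bc * interval_years`; cerebrum distributions are
#' identical across groups. Fully reproducible given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_study`: list with `subjects` (manifest
#'   data.frame), `scheme`, `masks` (named [region_mask()] list plus
#'   `background` logical array), `dwi` (per subject: list of `baseline` /
#'   `followup` [dwi_dataset()]), and `ground_truth`.
#' @export
make_study <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  scheme <- make_gradient_scheme(spec$n_directions, spec$b_value, seed = spec$scheme_seed)
  grid <- spec$grid_shape
  affine <- diag(c(2, 2, 2, 1))  # 2 mm isotropic voxels
  cer_idx <- which(spec$cerebrum_mask)
  bc_idx <- which(spec$bc_mask)
  bg <- !(spec$cerebrum_mask | spec$bc_mask)
  nvox <- prod(grid)

  n_sub <- spec$n_patients + spec$n_controls
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  ids <- sprintf("S%02d", seq_len(n_sub))

  manifest <- with_seed(derive_seed(spec$seed, 1L), {
    ip <- stats::runif(spec$n_patients, spec$interval_patients[1L], spec$interval_patients[2L])
    ic <- stats::runif(spec$n_controls, spec$interval_controls[1L], spec$interval_controls[2L])
    clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    np <- spec$n_patients
    iacrs_b <- round(clamp(stats::rnorm(np, 17.2, 4.3), 0, 38))
    iacrs_f <- round(clamp(iacrs_b + stats::rnorm(np, 4.1, 3.0), 0, 38))
    icars_b <- round(clamp(stats::rnorm(np, 39.7, 14.3), 0, 100))
    icars_f <- round(clamp(icars_b + stats::rnorm(np, 4.6, 5.0), 0, 100))
    cag <- pmax(34, round(stats::rnorm(np, 40.6, 1.4)))
    dur <- clamp(stats::rnorm(np, 12.8, 7.3), 2, 23)
    data.frame(subject_id = ids, group = groups,
               interval_years = c(ip, ic),
               iacrs_baseline = c(iacrs_b, rep(NA, spec$n_controls)),
               iacrs_followup = c(iacrs_f, rep(NA, spec$n_controls)),
               icars_baseline = c(icars_b, rep(NA, spec$n_controls)),
               icars_followup = c(icars_f, rep(NA, spec$n_controls)),
               cag_repeats = c(cag, rep(NA, spec$n_controls)),
               disease_duration_years = c(dur, rep(NA, spec$n_controls)),
               stringsAsFactors = FALSE)
  })

  dwi <- vector("list", n_sub)
  names(dwi) <- ids
  gt_tensors <- vector("list", n_sub)
  names(gt_tensors) <- ids
  scale_followup <- numeric(n_sub)

  for (s in seq_len(n_sub)) {
    grp <- groups[s]
    interval <- manifest$interval_years[s]
    eig_bc <- if (grp == "patient") spec$eig_patient_bc else spec$eig_control_bc
    md_rate_bc <- if (grp == "patient") spec$md_rate_patient_bc else spec$md_rate_control

    tensors <- with_seed(derive_seed(spec$seed, 2L, s), {
      list(cer = .compartment_tensors(length(cer_idx), spec$eig_cerebrum,
                                      spec$jitter, spec$direction_model),
           bc = .compartment_tensors(length(bc_idx), eig_bc,
                                     spec$jitter, spec$direction_model))
    })

    # follow-up: uniform eigenvalue scaling so true MD changes at the group rate
    sc_bc <- 1 + md_rate_bc * interval / mean(eig_bc)
    sc_cer <- 1 + spec$md_rate_cerebrum * interval / mean(spec$eig_cerebrum)
    if (sc_bc <= 0 || sc_cer <= 0) stop("longitudinal rate drives diffusivity negative")
    scale_followup[s] <- sc_bc

    d6_tp <- list(
      baseline = list(cer = tensors$cer$d6, bc = tensors$bc$d6),
      followup = list(cer = tensors$cer$d6 * sc_cer, bc = tensors$bc$d6 * sc_bc)
    )

    dwi[[s]] <- list()
    for (tp in c("baseline", "followup")) {
      d6_all <- matrix(0, nvox, 6L)
      d6_all[cer_idx, ] <- d6_tp[[tp]]$cer
      d6_all[bc_idx, ] <- d6_tp[[tp]]$bc
      att <- .tensor_attenuation(d6_all, scheme)        # n_meas x V
      sig <- spec$s0 * exp(-t(att))                     # V x n_meas
      sig[bg, ] <- 0                                    # background: pure noise
      sig <- add_rician_noise(array(sig, dim = c(grid, scheme$n_measurements)),
                              spec$noise_sigma,
                              seed = derive_seed(spec$seed, 3L, s, match(tp, c("baseline", "followup"))))
      dwi[[s]][[tp]] <- dwi_dataset(sig, affine, scheme)
    }
    gt_tensors[[s]] <- list(baseline = d6_tp$baseline, followup = d6_tp$followup)
  }

  masks <- list(
    cerebrum = region_mask(spec$cerebrum_mask, "cerebrum", voxel_volume = 8),
    brainstem_cerebellum = region_mask(spec$bc_mask, "brainstem_cerebellum", voxel_volume = 8),
    background = bg
  )

  true_medians <- list(
    cerebrum = list(md = mean(spec$eig_cerebrum)),
    brainstem_cerebellum = list(
      control = list(md = mean(spec$eig_control_bc), ad = spec$eig_control_bc[1L],
                     rd = mean(spec$eig_control_bc[2:3])),
      patient = list(md = mean(spec$eig_patient_bc), ad = spec$eig_patient_bc[1L],
                     rd = mean(spec$eig_patient_bc[2:3]))
    )
  )

  structure(list(spec = spec, subjects = manifest, scheme = scheme,
                 masks = masks, dwi = dwi,
                 ground_truth = list(tensors = gt_tensors,
                                     followup_bc_scale = scale_followup,
                                     true_medians = true_medians)),
            class = "phantom_study")
}

#' Write a phantom study to disk
#'
#' Produces per-subject/timepoint NIfTI DWIs with bval/bvec files, the two
#' region masks, the subject manifest CSV, and a ground-truth JSON (per-voxel
#' tensors are summarized by compartment means; full tensors stay in memory).
#'
#' @param study A [make_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  affine <- study$dwi[[1L]]$baseline$affine
  write_nifti(study$masks$cerebrum$mask + 0, affine,
              file.path(dir, "mask_cerebrum.nii.gz"), datatype = "uint8")
  write_nifti(study$masks$brainstem_cerebellum$mask + 0, affine,
              file.path(dir, "mask_brainstem_cerebellum.nii.gz"), datatype = "uint8")
  write_manifest(study$subjects, file.path(dir, "manifest.csv"))
  for (id in names(study$dwi)) {
    for (tp in c("baseline", "followup")) {
      stem <- file.path(dir, paste0(id, "_", tp))
      write_dwi(study$dwi[[id]][[tp]], paste0(stem, "_dwi.nii.gz"),
                paste0(stem, ".bval"), paste0(stem, ".bvec"))
    }
  }
  gt <- list(seed = study$spec$seed,
             followup_bc_scale = study$ground_truth$followup_bc_scale,
             true_medians = study$ground_truth$true_medians)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
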