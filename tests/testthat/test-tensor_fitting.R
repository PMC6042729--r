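test_that("b-matrix rows follow the doubled cross-term convention", {
  full <- test_scheme()
  bmx <- build_bmatrix(full)
  expect_equal(dim(bmx$bmat), c(16L, 6L))
  expect_equal(bmx$bmat[1, ], rep(0, 6), ignore_attr = TRUE)      # b=0 row
  expect_equal(bmx$design[1, ], c(rep(0, 6), 1), ignore_attr = TRUE)

  # direct evaluation of the convention on known directions
  row_of <- function(g, b = 1000)
    b * c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
  expect_equal(row_of(c(1, 0, 0)), c(1000, 0, 0, 0, 0, 0))
  expect_equal(row_of(c(1, 1, 0) / sqrt(2)), c(500, 500, 0, 1000, 0, 0))
  for (i in 2:16)
    expect_equal(bmx$bmat[i, ], row_of(full$bvecs[i, ]), ignore_attr = TRUE)

  # rank-deficient (coplanar) scheme rejected
  ang <- seq(0, pi * 5 / 6, length.out = 6)
  coplanar <- gradient_scheme(c(0, rep(1000, 6)),
                              rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0)))
  expect_error(build_bmatrix(coplanar), "rank-deficient")
})

test_that("b-matrix rotation uses only the rotational part of the affine", {
  bmx <- build_bmatrix(test_scheme())
  expect_equal(rotate_bmatrix(bmx, diag(4))$bmat, bmx$bmat)

  scaled <- diag(c(1.1, 0.9, 1.0, 1))                 # pure anisotropic scaling
  expect_equal(rotate_bmatrix(bmx, scaled)$bmat, bmx$bmat, tolerance = 1e-12)

  # 90 deg about z maps the x-gradient row onto the y-gradient row
  rz <- rbind(c(0, -1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  r <- polar_rotation(rz)
  gx <- c(1, 0, 0)
  expect_equal(as.numeric(r %*% gx), c(0, 1, 0), tolerance = 1e-12)
  rot <- rotate_bmatrix(bmx, rz)
  i <- 5L
  g <- bmx$scheme$bvecs[i, ]
  grot <- as.numeric(r %*% g)
  expect_equal(rot$bmat[i, ],
               1000 * c(grot[1]^2, grot[2]^2, grot[3]^2, 2 * grot[1] * grot[2],
                        2 * grot[1] * grot[3], 2 * grot[2] * grot[3]),
               ignore_attr = TRUE)

  expect_error(rotate_bmatrix(bmx, diag(c(1, 1, 0, 1))), "singular")
  # shear + rotation: polar part is still a proper rotation
  aff <- rz %*% diag(c(1.05, 0.95, 1, 1))
  rr <- polar_rotation(aff)
  expect_equal(crossprod(rr), diag(3), tolerance = 1e-12)
  expect_equal(det(rr), 1, tolerance = 1e-12)
})

test_that("all three fitters invert noise-free signals exactly", {
  sch <- test_scheme()
  bmx <- build_bmatrix(sch)
  d6s <- rbind(c(0.8, 0.8, 0.8, 0, 0, 0) * 1e-3,
               c(1.7, 0.3, 0.3, 0, 0, 0) * 1e-3,
               random_psd_tensors(4, seed = 21))
  for (k in seq_len(nrow(d6s))) {
    dwi <- uniform_tensor_dwi(d6s[k, ], sch, grid = c(3, 3, 3))
    for (fit in list(fit_tensor_lls, fit_tensor_wlls,
                     function(d, b, m) fit_tensor_restore(d, b, m, noise_sigma = 1))) {
      tf <- fit(dwi, bmx, NULL)
      got <- sapply(1:6, function(j) tf$d6[2, 2, 2, j])
      expect_equal(got, d6s[k, ], tolerance = 1e-10, ignore_attr = TRUE)
      expect_true(all(tf$valid))
    }
  }
})

test_that("fitting requires at least 7 measurements", {
  sch6 <- gradient_scheme(c(0, rep(1000, 5)),
                          rbind(c(0, 0, 0), diag(3), c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2)))
  dwi <- uniform_tensor_dwi(diag(3) * 1e-3, sch6, grid = c(2, 2, 2))
  expect_error(fit_tensor_lls(dwi, build_bmatrix(test_scheme()), NULL),
               "at least 7 measurements")
  expect_error(build_bmatrix(sch6), "rank-deficient")
})

test_that("WLLS equals LLS on noise-free data and beats it under Rician noise", {
  sch <- test_scheme()
  bmx <- build_bmatrix(sch)
  d6 <- c(1.2, 0.5, 0.4, 0.1, -0.05, 0.02) * 1e-3
  dwi <- uniform_tensor_dwi(d6, sch, grid = c(3, 3, 3))
  a <- fit_tensor_lls(dwi, bmx); b <- fit_tensor_wlls(dwi, bmx)
  expect_equal(a$d6, b$d6, tolerance = 1e-10)

  # Monte-Carlo: 500 voxels at SNR 20
  nv <- 500L
  s <- simulate_signal(d6, sch, 1000)
  sig <- array(rep(s, each = nv), dim = c(nv, 1, 1, 16))
  noisy <- add_rician_noise(sig, 50, seed = 77)
  dwin <- dwi_dataset(noisy, diag(4), sch)
  err <- function(tf) {
    d <- sapply(1:6, function(j) tf$d6[, 1, 1, j])
    rowSums(sweep(d, 2, d6)^2)
  }
  mse_lls <- mean(err(fit_tensor_lls(dwin, bmx)))
  mse_wlls <- mean(err(fit_tensor_wlls(dwin, bmx)))
  expect_lte(mse_wlls, mse_lls)
})

test_that("RESTORE flags injected corruption and recovers the tensor", {
  sch <- test_scheme()
  bmx <- build_bmatrix(sch)
  d6 <- c(1.7, 0.3, 0.3, 0, 0, 0) * 1e-3
  s <- simulate_signal(d6, sch, 1000)

  # clean data: early accept, equals WLLS, zero outliers
  clean <- uniform_tensor_dwi(d6, sch, grid = c(2, 2, 2))
  tf0 <- fit_tensor_restore(clean, bmx, NULL, noise_sigma = 5)
  expect_true(all(tf0$outlier_count == 0))
  expect_equal(tf0$d6, fit_tensor_wlls(clean, bmx)$d6, tolerance = 1e-10)

  # one measurement multiplied by 1.5, no noise
  corrupted <- s
  corrupted[6] <- 1.5 * s[6]
  sig <- array(rep(corrupted, each = 1), dim = c(1, 1, 1, 16))
  dwic <- dwi_dataset(sig, diag(4), sch)
  tfr <- fit_tensor_restore(dwic, bmx, NULL, noise_sigma = 5)
  expect_identical(tfr$outlier_count[1, 1, 1], 1L)
  got <- sapply(1:6, function(j) tfr$d6[1, 1, 1, j])
  expect_equal(got, d6, tolerance = 1e-8, ignore_attr = TRUE)
  lls <- sapply(1:6, function(j) fit_tensor_lls(dwic, bmx)$d6[1, 1, 1, j])
  expect_gt(max(abs(lls - d6)), 1e-6 * max(abs(d6)))   # LLS is visibly biased

  # 10 of 16 corrupted (mutually inconsistent factors): too few inliers,
  # falls back to full-data WLLS
  many <- s
  many[2:11] <- (1.5 + 0.2 * (0:9)) * many[2:11]
  dwim <- dwi_dataset(array(many, dim = c(1, 1, 1, 16)), diag(4), sch)
  tfm <- fit_tensor_restore(dwim, bmx, NULL, noise_sigma = 5)
  expect_identical(tfm$method[1, 1, 1],
                   which(tfm$method_levels == "restore_fallback") - 1L)

  expect_error(fit_tensor_restore(clean, bmx, NULL, noise_sigma = 0), "positive")
})

test_that("noise sigma is recovered by the Rayleigh moment estimator", {
  sch <- test_scheme()
  nv <- 10000L
  bg <- add_rician_noise(array(0, dim = c(nv, 1, 1, 16)), 5, seed = 13)
  dwi <- dwi_dataset(bg, diag(4), sch)
  mask <- array(TRUE, dim = c(nv, 1, 1))
  expect_equal(estimate_noise_sigma(dwi, mask), 5, tolerance = 0.02)

  zero <- dwi_dataset(array(0, dim = c(200, 1, 1, 16)), diag(4), sch)
  expect_equal(estimate_noise_sigma(zero, array(TRUE, dim = c(200, 1, 1))), 0)

  small <- dwi_dataset(array(0, dim = c(50, 1, 1, 16)), diag(4), sch)
  expect_error(estimate_noise_sigma(small, array(TRUE, dim = c(50, 1, 1))), "too small")
})

test_that("rotation consistency: rotated scheme + rotated b-matrix recover the tensor", {
  sch <- test_scheme()
  rz <- rbind(c(cos(0.7), -sin(0.7), 0, 0), c(sin(0.7), cos(0.7), 0, 0),
              c(0, 0, 1, 0), c(0, 0, 0, 1))
  r <- polar_rotation(rz)
  rot_scheme <- gradient_scheme(sch$bvals, t(r %*% t(sch$bvecs)))
  d6 <- c(1.5, 0.4, 0.3, 0.05, 0, 0) * 1e-3
  # data acquired with the rotated gradients
  dwi_rot <- uniform_tensor_dwi(d6, rot_scheme, grid = c(2, 2, 2))
  # fitting with the rotated b-matrix must recover the same tensor
  bmx_rot <- rotate_bmatrix(build_bmatrix(sch), rz)
  tf <- fit_tensor_lls(dwi_rot, bmx_rot)
  got <- sapply(1:6, function(j) tf$d6[1, 1, 1, j])
  expect_equal(got, d6, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("non-positive signals are clamped and flagged", {
  sch <- test_scheme()
  bmx <- build_bmatrix(sch)
  s <- simulate_signal(c(1, 1, 1, 0, 0, 0) * 1e-3, sch, 100)
  s[10] <- 0
  dwi <- dwi_dataset(array(s, dim = c(1, 1, 1, 16)), diag(4), sch)
  tf <- fit_tensor_lls(dwi, bmx)
  expect_identical(tf$clamped[1, 1, 1], 1L)
  expect_true(tf$valid[1, 1, 1])
})
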