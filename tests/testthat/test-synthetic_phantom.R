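test_that("electrostatic direction placement meets the scheme contract", {
  sch <- make_gradient_scheme(15, 1000, seed = 1)
  expect_equal(sch$n_measurements, 16L)
  expect_equal(sch$bvals[1], 0)
  expect_equal(sch$bvals[-1], rep(1000, 15))

  g <- sch$bvecs[-1, ]
  expect_equal(unname(qr(g)$rank), 3L)                     # non-coplanar
  dots <- abs(tcrossprod(g)); diag(dots) <- 0
  expect_gte(acos(max(dots)) * 180 / pi, 10)               # >= 10 deg apart

  sch6 <- make_gradient_scheme(6, 1000, seed = 1)
  expect_equal(sch6$n_measurements, 7L)
  expect_error(make_gradient_scheme(5, 1000, seed = 1), "at least 6")

  # deterministic given seed
  expect_identical(make_gradient_scheme(15, 1000, seed = 9)$bvecs,
                   make_gradient_scheme(15, 1000, seed = 9)$bvecs)
})

test_that("simulate_signal implements the monoexponential tensor model", {
  sch <- test_scheme()
  d <- 0.8e-3
  s <- simulate_signal(diag(3) * d, sch, s0 = 1000)
  expect_equal(s, 1000 * exp(-sch$bvals * d))              # isotropy
  expect_identical(s[1], 1000)                             # b=0 row exact

  # stick tensor along x, gradient along y: no attenuation
  stick <- c(1e-3, 0, 0, 0, 0, 0)
  schy <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(0, 1, 0)))
  expect_equal(simulate_signal(stick, schy, 500), c(500, 500))

  expect_error(simulate_signal(c(-1e-3, 0, 0, 0, 0, 0),
                               gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0))),
                               1000), "PSD")
})

test_that("Rician noise matches its model and the Rayleigh limit", {
  s <- c(0, 10, 100)
  expect_identical(add_rician_noise(s, 0, seed = 3), s)
  expect_identical(add_rician_noise(s, 5, seed = 3), add_rician_noise(s, 5, seed = 3))
  expect_error(add_rician_noise(s, -1), "noise_sigma")

  # S = 0: Rayleigh with mean sigma * sqrt(pi/2) ~ 1.2533 at sigma = 1
  draws <- add_rician_noise(numeric(1e6), 1, seed = 11)
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), sqrt(pi / 2), tolerance = 0.01)
})

test_that("make_study produces the declared design, reproducibly", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8), n_patients = 2L, n_controls = 3L,
                       seed = 5L)
  study <- make_study(spec)
  expect_equal(nrow(study$subjects), 5L)
  expect_equal(sum(study$subjects$group == "patient"), 2L)
  expect_length(study$dwi, 5L)
  expect_named(study$dwi[[1]], c("baseline", "followup"))
  expect_true(all(study$subjects$interval_years > 0))
  with(study$subjects[study$subjects$group == "patient", ], {
    expect_true(all(iacrs_baseline >= 0 & iacrs_baseline <= 38))
    expect_true(all(icars_followup >= 0 & icars_followup <= 100))
    expect_true(all(cag_repeats >= 34))
  })

  study2 <- make_study(spec)
  expect_identical(study$dwi[["S01"]]$baseline$signal, study2$dwi[["S01"]]$baseline$signal)
  expect_identical(study$subjects, study2$subjects)
})

test_that("degenerate spec (no jitter, no noise) gives constant ground truth", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8), n_patients = 1L, n_controls = 1L,
                       jitter = 0, noise_sigma = 0, direction_model = "fixed", seed = 2L)
  study <- make_study(spec)
  gt <- study$ground_truth$tensors[["S02"]]$baseline$bc     # the control
  md <- rowMeans(gt[, 1:3])
  expect_equal(diff(range(md)), 0)
  expect_equal(md[1], mean(spec$eig_control_bc))
})

test_that("follow-up scaling applies the group MD rate to patients' BC", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8), n_patients = 1L, n_controls = 1L,
                       jitter = 0, noise_sigma = 0, seed = 3L)
  study <- make_study(spec)
  iv <- study$subjects$interval_years
  for (s in 1:2) {
    id <- study$subjects$subject_id[s]
    rate <- if (study$subjects$group[s] == "patient") spec$md_rate_patient_bc else spec$md_rate_control
    gt <- study$ground_truth$tensors[[id]]
    md_b <- mean(rowMeans(gt$baseline$bc[, 1:3]))
    md_f <- mean(rowMeans(gt$followup$bc[, 1:3]))
    expect_equal((md_f - md_b) / iv[s], rate, tolerance = 1e-12)
    # cerebrum untouched by default (rate 0)
    expect_identical(gt$baseline$cer, gt$followup$cer)
  }
})

test_that("true compartment medians separate groups in the stated direction", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8), n_patients = 2L, n_controls = 2L, seed = 8L)
  study <- make_study(spec)
  tm <- study$ground_truth$true_medians$brainstem_cerebellum
  expect_gt(tm$patient$md, tm$control$md)
  # FA of the mean triples: patients lower
  fa_of <- function(l) {
    dv <- l - mean(l); sqrt(1.5 * sum(dv^2) / sum(l^2))
  }
  expect_lt(fa_of(spec$eig_patient_bc), fa_of(spec$eig_control_bc))
})

test_that("paper_like preset reproduces the emulated study design", {
  spec <- dtihist:::.presets("paper_like", seed = 1L)
  expect_equal(spec$n_patients, 9L)
  expect_equal(spec$n_controls, 16L)
  expect_equal(spec$interval_patients, c(2.2, 4.0))
  expect_equal(spec$interval_controls, c(1.9, 4.7))
  expect_equal(spec$md_rate_patient_bc, 0.010e-3)
  expect_equal(spec$md_rate_control, -0.003e-3)
})

test_that("phantom spec rejects invalid parameterizations", {
  expect_error(phantom_spec(jitter = 0.6), "jitter")
  expect_error(phantom_spec(eig_control_bc = c(0.7, 1.0, 0.7) * 1e-3), "descending")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "200 voxels")
})
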