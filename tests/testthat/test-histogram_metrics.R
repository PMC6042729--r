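test_that("default binning follows the published widths and ranges", {
  expect_equal(histogram_spec("md")$bin_width, 0.05e-3)
  expect_equal(histogram_spec("ad")$range, c(0, 4e-3))
  expect_equal(histogram_spec("fa")$bin_width, 0.03)
  expect_equal(histogram_spec("mo")$bin_width, 0.08)
  expect_equal(histogram_spec("mo")$range, c(-1, 1))
  expect_length(histogram_spec("mo")$centers, 25L)   # 2 / 0.08
  expect_error(histogram_spec("md", bin_width = 0), "bin_width")
})

test_that("degenerate and two-cluster histograms normalize correctly", {
  spec <- histogram_spec("md")
  h <- build_histogram(rep(0.8e-3, 1000), spec = spec)
  expect_equal(sum(h$freq), 1)
  expect_equal(max(h$freq), 1)
  expect_equal(h$centers[which.max(h$freq)], 0.825e-3)   # bin [0.80, 0.85)

  two <- c(rep(0.41e-3, 250), rep(1.22e-3, 250))
  h2 <- build_histogram(two, spec = spec)
  expect_equal(sort(h2$freq[h2$freq > 0]), c(0.5, 0.5))
})

test_that("binning matches an independent counting oracle", {
  set.seed(12)
  spec <- histogram_spec("fa")
  for (rep_i in 1:5) {
    vals <- pmin(1, pmax(0, rnorm(2000, 0.35, 0.15)))
    h <- build_histogram(vals, spec = spec)
    o <- oracle_hist_metrics(vals, spec$breaks)
    expect_equal(h$freq, o$freq)
    m <- compute_metrics(h)
    expect_identical(m$median, o$median)
    expect_equal(m$peak_location, o$peak_location, tolerance = 1e-12)
    expect_identical(m$peak_height, o$peak_height)
  }
})

test_that("metrics conventions: even-n median, tie-break, constants", {
  spec <- histogram_spec("md")
  m <- compute_metrics(build_histogram(c(1, 2, 3, 4) * 1e-4, spec = spec))
  expect_equal(m$median, 2.5e-4)

  mc <- compute_metrics(build_histogram(rep(0.7e-3, 50), spec = spec))
  expect_equal(mc$median, 0.7e-3)
  expect_equal(mc$peak_height, 1)
  expect_equal(mc$peak_location, 0.725e-3)

  # tie broken toward the lowest bin center
  tied <- c(rep(0.12e-3, 5), rep(2.33e-3, 5))
  mt <- compute_metrics(build_histogram(tied, spec = spec))
  expect_equal(mt$peak_location, 0.125e-3)
})

test_that("metrics match the sort/count oracle on large simulated FA samples", {
  set.seed(3)
  vals <- pmin(1, pmax(0, rbeta(10000, 2, 6)))
  spec <- histogram_spec("fa")
  m <- compute_metrics(build_histogram(vals, spec = spec))
  o <- oracle_hist_metrics(vals, spec$breaks)
  expect_identical(m$median, o$median)
  expect_equal(m$peak_location, o$peak_location, tolerance = 1e-12)
  expect_identical(m$peak_height, o$peak_height)
})

test_that("normalization removes size dependence; median ignores binning", {
  set.seed(8)
  vals <- runif(500, 0.2e-3, 1.8e-3)
  spec <- histogram_spec("md")
  m1 <- compute_metrics(build_histogram(vals, spec = spec))
  m2 <- compute_metrics(build_histogram(rep(vals, 2), spec = spec))
  expect_equal(m1[c("median", "peak_location", "peak_height")],
               m2[c("median", "peak_location", "peak_height")])

  half <- histogram_spec("md", bin_width = 0.025e-3)
  m3 <- compute_metrics(build_histogram(vals, spec = half))
  expect_identical(m3$median, m1$median)
  # anchor-shift sensitivity: peak moves at most one (original) bin width
  expect_lte(abs(m3$peak_location - m1$peak_location), spec$bin_width)
})

test_that("out-of-range and empty inputs are rejected", {
  spec <- histogram_spec("fa")
  expect_error(build_histogram(numeric(0), spec = spec), "empty")
  bad <- c(runif(80), rep(7, 20))     # 20% out of range
  expect_error(build_histogram(bad, spec = spec), "outside")
  # small out-of-range fraction tolerated and tallied
  ok <- c(runif(99), 7)
  h <- build_histogram(ok, spec = spec)
  expect_equal(h$n_excluded, 1L)
  expect_equal(h$n_counted, 99L)
})

test_that("region metrics table has the 2 x 5 x 3 layout and label passthrough", {
  sch <- test_scheme()
  grid <- c(6, 6, 4)
  dwi <- uniform_tensor_dwi(c(1.1, 0.5, 0.4, 0, 0, 0) * 1e-3, sch, grid = grid)
  tf <- fit_tensor_lls(dwi, build_bmatrix(sch))
  maps <- tensor_to_indices(tf)
  m1 <- array(FALSE, dim = grid); m1[1:3, , ] <- TRUE
  m2 <- array(FALSE, dim = grid); m2[4:6, , ] <- TRUE
  masks <- list(a = region_mask(m1, "cerebrum"), b = region_mask(m2, "brainstem_cerebellum"))
  tab <- region_metrics_table(maps, masks)
  expect_equal(nrow(tab), 30L)
  expect_setequal(unique(tab$region), c("cerebrum", "brainstem_cerebellum"))
  expect_setequal(unique(tab$metric), c("median", "peak_location", "peak_height"))

  swapped <- list(a = region_mask(m1, "brainstem_cerebellum"), b = region_mask(m2, "cerebrum"))
  tab2 <- region_metrics_table(maps, swapped)
  v1 <- tab[tab$region == "cerebrum", "value"]
  v2 <- tab2[tab2$region == "brainstem_cerebellum", "value"]
  expect_equal(v1, v2)
})

test_that("known-median phantom recovery lands within half a bin", {
  spec <- phantom_spec(grid_shape = c(14, 14, 10), n_patients = 1L, n_controls = 1L,
                       jitter = 0.02, noise_sigma = 0, seed = 77L)
  study <- make_study(spec)
  res <- analyze_study(study, fit_method = "lls")
  md_bc <- res$metrics[res$metrics$region == "brainstem_cerebellum" &
                         res$metrics$index == "md" & res$metrics$metric == "median" &
                         res$metrics$timepoint == "baseline", ]
  truth_p <- mean(spec$eig_patient_bc)
  got_p <- md_bc$value[md_bc$group == "patient"]
  expect_lt(abs(got_p - truth_p), 0.5 * histogram_spec("md")$bin_width)
})
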