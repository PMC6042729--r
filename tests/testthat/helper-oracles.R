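# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately use brute force / enumeration, not the package's code
# paths.

# Literal enumeration Mann-Whitney: U over all choose(n1+n2, n1) assignments
# of the observed combined sample, two-sided p from the tail doubling rule.
oracle_mw_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  picks <- utils::combn(n1 + n2, n1)
  u_all <- apply(picks, 2L, function(ix) u_of(comb[ix], comb[-ix]))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = min(u_obs, n1 * n2 - u_obs), p = min(1, p))
}

# Sort/count histogram-metric oracle on raw values given explicit breaks
# (left-closed right-open, last bin closed).
oracle_hist_metrics <- function(values, breaks) {
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  v <- values[values >= breaks[1] & values <= breaks[length(breaks)]]
  counts <- integer(length(centers))
  for (val in v) {
    k <- max(which(breaks <= val))
    if (k > length(centers)) k <- length(centers)
    counts[k] <- counts[k] + 1L
  }
  freq <- counts / length(v)
  pk <- which(freq == max(freq))[1L]
  sv <- sort(v)
  n <- length(sv)
  med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
  list(median = med, peak_location = centers[pk], peak_height = freq[pk], freq = freq)
}

# Fixed small scheme shared by fitting tests (cached inside the package).
test_scheme <- function() make_gradient_scheme(15, 1000, seed = 1)

# Random PSD tensor 6-vectors: random rotations of nonnegative eigenvalues.
random_psd_tensors <- function(n, seed, lambda_max = 2.5e-3) {
  set.seed(seed)
  t(sapply(seq_len(n), function(i) {
    lam <- sort(runif(3, 0, lambda_max), decreasing = TRUE)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    dtihist:::tensor_mat_to6(q %*% diag(lam) %*% t(q))
  }))
}

# DWI dataset holding one tensor's noise-free signals in every grid voxel.
uniform_tensor_dwi <- function(d6, scheme, s0 = 1000, grid = c(3, 3, 3)) {
  s <- simulate_signal(d6, scheme, s0)
  sig <- array(rep(s, each = prod(grid)), dim = c(grid, scheme$n_measurements))
  dwi_dataset(sig, diag(4), scheme)
}
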