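# Shared fixture builders and brute-force oracles for the test suite.

toy_grid <- function(n_bins = 5L, start = 2, by = 2) {
  frequency_grid(seq(start, by = by, length.out = n_bins))
}

# subjects x bins matrix of random unit-mass spectra
random_unit_spectra <- function(n, bins, seed = 1L) {
  set.seed(seed)
  W <- matrix(stats::rexp(n * bins), nrow = n)
  W / rowSums(W)
}

# Small multi-site cohort with random unit-mass spectra.
toy_cohort <- function(n = 12L, bins = 6L, channels = c("C3", "O1"),
                       sites = c("alpha", "beta"), seed = 1L, ages = NULL) {
  set.seed(seed)
  grid <- toy_grid(bins)
  if (is.null(ages)) ages <- round(stats::runif(n, 8, 80), 1)
  meta <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    age = ages,
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = rep_len(sites, n),
    stringsAsFactors = FALSE)
  spectra <- lapply(channels, function(ch) {
    W <- matrix(stats::rexp(n * bins), nrow = n)
    W <- W / rowSums(W)
    rownames(W) <- meta$subject_id
    W
  })
  names(spectra) <- channels
  eeg_cohort(meta, spectra, grid)
}

# Naive O((n+m)^2) MMD^2 oracle: expand weighted samples into individual
# sample points and take the literal double sums.
mmd_sq_bruteforce <- function(P, Q, spec, u_statistic = FALSE) {
  xs <- rep(P$support, P$counts)
  zs <- rep(Q$support, Q$counts)
  n <- length(xs); m <- length(zs)
  Kxx <- outer(xs, xs, inner_kernel_eval, spec = spec)
  Kzz <- outer(zs, zs, inner_kernel_eval, spec = spec)
  Kxz <- outer(xs, zs, inner_kernel_eval, spec = spec)
  if (u_statistic) {
    (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) +
      (sum(Kzz) - sum(diag(Kzz))) / (m * (m - 1)) -
      2 * sum(Kxz) / (n * m)
  } else {
    mean(Kxx) + mean(Kzz) - 2 * mean(Kxz)
  }
}

# Reference dual-ridge solution via an explicit inverse.
dual_ridge_oracle <- function(K, y, alpha) {
  yc <- y - mean(y)
  drop(solve(K + diag(alpha, nrow(K)), yc))
}
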