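# Independent oracles used across test files. These re-derive quantities
# by brute force so they share no code with the implementation paths
# they check.

# literal double-loop evaluation of the lagged autocorrelation with
# windowed means and the unbiased global variance
brute_force_acf <- function(a, j_max) {
  n <- length(a)
  sigma2 <- sum((a - mean(a))^2) / (n - 1)
  vapply(0:j_max, function(j) {
    i <- seq_len(n - j)
    mu1 <- mean(a[i])
    mu2 <- mean(a[i + j])
    acc <- 0
    for (k in i) acc <- acc + (a[k] - mu1) * (a[k + j] - mu2)
    acc / (sigma2 * (n - j))
  }, numeric(1))
}

# discordant-pair count form of the Mann-Whitney U (ties count 1/2);
# combined over strata as sum(min(U1, U2)) / sum(n1 * n2)
brute_force_combined_u <- function(counts, labels, strata) {
  num <- 0
  den <- 0
  for (s in unique(strata)) {
    x1 <- counts[strata == s & labels == levels(factor(labels))[1]]
    x2 <- counts[strata == s & labels == levels(factor(labels))[2]]
    if (!length(x1) || !length(x2)) next
    u1 <- 0
    for (a in x1) for (b in x2) {
      u1 <- u1 + (a > b) + 0.5 * (a == b)
    }
    num <- num + min(u1, length(x1) * length(x2) - u1)
    den <- den + length(x1) * length(x2)
  }
  num / den
}

# noiseless mixture-of-exponentials autocorrelogram wrapped as a
# spike_acf object (AC(0) fixed at its identity value), for fitting
# tests that bypass spike generation
synthetic_acf <- function(coeffs, taus, bin_width = 0.005, n_lags = 1000,
                          noise_sd = 0, n_bins = 120000) {
  lags <- (0:n_lags) * bin_width
  ac <- as.numeric(exp(-outer(lags, 1 / taus)) %*% coeffs)
  if (noise_sd > 0) ac <- ac + stats::rnorm(length(ac), sd = noise_sd)
  ac[1] <- (n_bins - 1) / n_bins
  structure(
    list(degenerate = FALSE, lags = lags, ac = ac, sample_variance = 1,
         mu1 = NULL, mu2 = NULL, bin_width = bin_width, n_bins = n_bins,
         unit_id = "synthetic"),
    class = "spike_acf"
  )
}
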