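test_that("spike binning matches direct counting", {
  tr <- spike_train(c(0.001, 0.004, 0.011), duration = 0.02)
  expect_identical(bin_spikes(tr, 0.005)$counts, c(2L, 0L, 1L, 0L))

  empty <- spike_train(numeric(0), duration = 0.05)
  expect_identical(bin_spikes(empty, 0.005)$counts, rep(0L, 10))

  set.seed(11)
  times <- sort(runif(500, 0, 3.3))
  bc <- bin_spikes(spike_train(times, 3.3), 0.005)
  expect_equal(sum(bc$counts), sum(times < bc$n_bins * 0.005))
  # half-open bins: a spike exactly at a bin edge belongs to the later bin
  tr_edge <- spike_train(c(0.005), duration = 0.02)
  expect_identical(bin_spikes(tr_edge, 0.005)$counts, c(0L, 1L, 0L, 0L))
  expect_error(bin_spikes(spike_train(0.001, 0.002), 0.005), "shorter")
})

test_that("autocorrelation equals the brute-force double loop and its zero-lag identity", {
  set.seed(21)
  for (n in c(30, 47)) {
    a <- rpois(n, 3)
    bc <- structure(list(counts = a, bin_width = 0.005, n_bins = n,
                         unit_id = "t"), class = "binned_counts")
    ac <- autocorrelation(bc, max_lag = 10 * 0.005)
    expect_equal(ac$ac, brute_force_acf(a, 10), tolerance = 1e-10)
    expect_equal(ac$ac[1], (n - 1) / n, tolerance = 1e-12)
  }
  # hand-evaluated short series
  a <- c(1, 0, 2, 1, 0)
  bc <- structure(list(counts = a, bin_width = 0.005, n_bins = 5L,
                       unit_id = "t"), class = "binned_counts")
  ac <- autocorrelation(bc, max_lag = 0.01)
  expect_equal(ac$ac[2:3], brute_force_acf(a, 2)[2:3], tolerance = 1e-12)
})

test_that("iid Poisson counts have near-zero autocorrelation beyond lag 0", {
  set.seed(31)
  n <- 1e5
  bc <- structure(list(counts = rpois(n, 2), bin_width = 0.005,
                       n_bins = n, unit_id = "t"), class = "binned_counts")
  ac <- autocorrelation(bc, max_lag = 0.25)
  vals <- ac$ac[-1]
  se <- 1 / sqrt(n)
  expect_lt(abs(mean(vals)), 3 * se / sqrt(length(vals)))
})

test_that("constant count series is flagged degenerate", {
  bc <- structure(list(counts = rep(2L, 5000), bin_width = 0.005,
                       n_bins = 5000L, unit_id = "t"),
                  class = "binned_counts")
  ac <- autocorrelation(bc, max_lag = 0.05)
  expect_true(ac$degenerate)
  expect_null(ac$ac)
})

test_that("fit start is the argmax of the autocorrelation within the horizon", {
  mono <- synthetic_acf(1, 0.1)
  expect_identical(find_fit_start(mono), 1L)
  # refractory dip at lags 1-2, peak at lag 3
  dip <- synthetic_acf(1, 0.1)
  dip$ac[2:3] <- c(-0.2, -0.1)
  expect_identical(find_fit_start(dip), 3L)
  # exponential + small noise (decay per lag well above the noise
  # floor): start 1 nearly always
  set.seed(41)
  hits <- vapply(1:200, function(i) {
    ac <- synthetic_acf(1, 0.05, noise_sd = 0.01)
    find_fit_start(ac) == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mixture fits recover noiseless parameters", {
  ac2 <- synthetic_acf(c(0.7, 0.3), c(0.05, 0.5))
  fit <- fit_exp_mixture(ac2, 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$taus, c(0.05, 0.5), tolerance = 1e-3)
  expect_equal(fit$coeffs, c(0.7, 0.3), tolerance = 1e-3)

  ac1 <- synthetic_acf(0.6, 0.2)
  fit1 <- fit_exp_mixture(ac1, 1, seed = 2)
  expect_equal(fit1$taus, 0.2, tolerance = 1e-6)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-9)

  flat <- synthetic_acf(1, 0.1)
  flat$ac[-1] <- 0
  fit0 <- fit_exp_mixture(flat, 1, seed = 3)
  expect_true(!fit0$converged || fit0$r_squared <= 0)
})

test_that("BIC selection picks the planted order and enforces the 1% rule", {
  # well-separated two-timescale data at high SNR
  set.seed(51)
  picks <- vapply(1:100, function(i) {
    ac <- synthetic_acf(c(0.5, 0.5), c(0.05, 0.5), noise_sd = 0.004)
    fits <- lapply(1:4, function(m) fit_exp_mixture(ac, m, seed = i * 10 + m))
    select_model(fits)$M
  }, integer(1))
  expect_gte(mean(picks == 2L), 0.9)

  # a tiny coefficient demotes the model even at lower BIC
  f2 <- structure(list(M = 2L, taus = c(0.05, 0.5), coeffs = c(0.995, 0.005),
                       bic = -100, r_squared = 0.99, start_lag = 1L,
                       tau_eff = 0.052, converged = TRUE),
                  class = "exp_mixture_fit")
  f1 <- structure(list(M = 1L, taus = 0.06, coeffs = 1, bic = -90,
                       r_squared = 0.9, start_lag = 1L, tau_eff = 0.06,
                       converged = TRUE),
                  class = "exp_mixture_fit")
  expect_identical(select_model(list(f1, f2))$M, 1L)

  # only M=1 converged
  f2$converged <- FALSE
  expect_identical(select_model(list(f1, f2))$M, 1L)
  expect_true(is_excluded(select_model(list())))
})

test_that("effective timescale is the coefficient-weighted mean and matches the area identity", {
  mk <- function(coeffs, taus) {
    structure(list(M = length(taus), taus = taus, coeffs = coeffs,
                   bic = 0, r_squared = 1, start_lag = 1L,
                   tau_eff = NA, converged = TRUE),
              class = "exp_mixture_fit")
  }
  expect_equal(effective_timescale(mk(1, 0.2)), 0.2)
  expect_equal(effective_timescale(mk(c(0.5, 0.5), c(0.1, 0.3))), 0.2)
  # area under the mixture equals sum(c) * tau_eff
  cc <- c(0.4, 0.25, 0.1)
  tt <- c(0.03, 0.2, 1.1)
  area <- integrate(function(t) colSums(cc * exp(-outer(1 / tt, t))),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(area, sum(cc) * effective_timescale(mk(cc, tt)),
               tolerance = 1e-8)
  # invariance to coefficient rescaling
  expect_equal(effective_timescale(mk(5 * cc, tt)),
               effective_timescale(mk(cc, tt)))
  expect_error(effective_timescale(mk(c(0, 0), c(0.1, 0.2))), "positive")
})

test_that("planted timescales are recovered from doubly stochastic spike trains", {
  # moderate seed count here; the full 50-seed recovery property runs in
  # the acceptance suite
  taus <- sapply(1:10, function(s) {
    tr <- gen_multiscale_spike_train(
      30, data.frame(tau = c(0.05, 0.5), amplitude = c(10.5, 10.5)),
      duration = 600, seed = 100 + s)
    fit_exp_mixture(autocorrelation(bin_spikes(tr)), 2,
                    seed = 200 + s)$taus
  })
  expect_lt(abs(median(taus[1, ]) - 0.05) / 0.05, 0.3)
  expect_lt(abs(median(taus[2, ]) - 0.5) / 0.5, 0.3)
})

test_that("single-exponential pathway fits all neurons without quality control", {
  tr <- gen_multiscale_spike_train(15, data.frame(tau = 0.2, amplitude = 6),
                                   duration = 300, seed = 7)
  fit <- estimate_timescales(tr, single_exponential = TRUE, seed = 8)
  expect_identical(fit$M, 1L)
  expect_true(is.na(fit$qc_pass))
  expect_equal(fit$taus, 0.2, tolerance = 0.5)
})
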