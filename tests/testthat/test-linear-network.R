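test_that("eigenvalue families sample within support with the right moments", {
  fam_u <- eigen_family("uniform", 0.01, 1)
  x <- sample_eigenvalues(fam_u, 5000, seed = 1)
  expect_true(all(x >= 0.01 & x <= 1))

  fam_s <- eigen_family("semicircle", radius = 1)
  y <- sample_eigenvalues(fam_s, 1e5, seed = 2)
  expect_true(all(y >= 0 & y <= 2))
  expect_lt(abs(mean(y) - 1), 3 * 0.5 / sqrt(1e5))  # symmetric about R

  fam_g <- eigen_family("gamma", shape = 2)
  z <- sample_eigenvalues(fam_g, 1e5, seed = 3)
  expect_lt(abs(mean(z) - 2), 3 * sqrt(2) / sqrt(1e5))
  expect_error(eigen_family("uniform", 1, 0.5), "lambda_min")
  expect_error(eigen_family("gamma", shape = -1), "positive")
})

test_that("timescale density is the reciprocal change of variables and conserves mass", {
  fam <- eigen_family("uniform", 0, 1)
  g <- timescale_density(fam)
  tt <- c(1.5, 2, 10)
  expect_equal(g(tt), 1 / tt^2)
  expect_equal(g(0.5), 0)
  # quadrature over each family's support
  for (fam in list(eigen_family("uniform", 0.2, 1),
                   eigen_family("semicircle", radius = 1),
                   eigen_family("gamma", shape = 2))) {
    gd <- timescale_density(fam)
    mass <- integrate(gd, 0, Inf, rel.tol = 1e-9,
                      subdivisions = 500)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # Monte-Carlo agreement of inverse draws with the density
  fam_u <- eigen_family("uniform", 0, 1)
  tau <- 1 / sample_eigenvalues(fam_u, 1e5, seed = 4)
  # CDF on [1, Inf): G(t) = 1 - 1/t
  ks <- suppressWarnings(ks.test(tau, function(t) 1 - 1 / t))
  expect_gt(ks$p.value, 0.01)
})

test_that("predicted exponent is 2 + zeta with family-specific cutoffs", {
  expect_equal(predicted_exponent(0), 2)
  expect_equal(predicted_exponent(0.5), 2.5)
  expect_equal(predicted_exponent(1), 3)
  expect_equal(predicted_exponent(eigen_family("semicircle")), 2.5)
  expect_equal(eigen_family("semicircle", radius = 1)$tau_cutoff, 0.5)
  expect_equal(eigen_family("gamma", shape = 2)$tau_cutoff, 1 / log(2))
  expect_error(predicted_exponent(-1.2), "exceed -1")
})

test_that("eigenvalue-to-timescale mapping scales with tau_syn and caps at tau_syn/epsilon", {
  ev <- sample_eigenvalues(eigen_family("uniform", 0, 1), 2000, seed = 5)
  t1 <- eigen_to_timescales(ev, tau_syn = 1, epsilon = 1e-3)
  t2 <- eigen_to_timescales(ev, tau_syn = 2, epsilon = 1e-3)
  expect_equal(t2, 2 * t1)
  expect_equal(median(t2), 2 * median(t1))
  expect_lte(max(t1), 1 / 1e-3)
  # uncoupled network: every eigenvalue 1, timescales = tau_syn
  expect_equal(eigen_to_timescales(rep(1, 5), tau_syn = 0.3,
                                   epsilon = 1e-6),
               rep(0.3, 5), tolerance = 1e-5)
  expect_error(eigen_to_timescales(ev, epsilon = 0), "positive")
  # raising epsilon strictly lowers the slowest timescale
  t3 <- eigen_to_timescales(ev, epsilon = 0.05)
  expect_lt(max(t3), max(t1))
  expect_lte(max(t3), 1 / 0.05)
})

test_that("uniform-family timescales at the edge of instability fit the predicted exponent", {
  set.seed(6)
  ev <- sample_eigenvalues(eigen_family("uniform", 0, 1), 1e4)
  tau <- eigen_to_timescales(ev, epsilon = 1e-4)
  f <- fit_power_law(tau, decimate = 10)
  expect_lt(abs(f$gamma - 2), 0.15)
})

test_that("analytic correlation matches closed forms and a stochastic simulation", {
  # single mode: C(t) = D/(2 lambda) exp(-lambda t)
  lam <- 0.8
  expect_equal(analytic_correlation(matrix(lam), 2, 0.5)[1, 1],
               2 / (2 * lam) * exp(-lam * 0.5), tolerance = 1e-12)
  # symmetric M: C(0) PSD, and equals the Lyapunov solution D/2 M^-1
  set.seed(7)
  M <- crossprod(matrix(rnorm(4), 2)) / 2 + diag(2) * 0.5
  C0 <- analytic_correlation(M, 1, 0)
  expect_equal(C0, t(C0), tolerance = 1e-10)
  expect_true(all(eigen(C0, only.values = TRUE)$values > -1e-12))
  expect_equal(C0, 0.5 * solve(M), tolerance = 1e-10)
  # random stable nonsymmetric 5x5: Lyapunov oracle via vectorization
  A <- matrix(rnorm(25, sd = 0.25), 5)
  M5 <- diag(5) * 1.2 - A
  C5 <- analytic_correlation(M5, 0.8, 0)
  L <- kronecker(diag(5), M5) + kronecker(M5, diag(5))
  C_oracle <- matrix(solve(L, as.vector(0.8 * diag(5))), 5)
  expect_equal(C5, C_oracle, tolerance = 1e-8)
  # simulation agreement at zero and positive lag
  sim <- simulate_linear_network(M5, 0.8, t_total = 4000, dt = 0.02,
                                 seed = 8)
  C_emp <- cov(sim$x)
  expect_lt(max(abs(C_emp - C5)), 0.1 * max(abs(C5)))
  expect_error(analytic_correlation(diag(c(1, -0.1)), 1, 0), "unstable")
})

test_that("linear network simulation obeys OU closed forms", {
  # noiseless decay
  sim0 <- simulate_linear_network(matrix(1), 0, t_total = 20, dt = 0.01,
                                  burn_in = 0, x0 = 3)
  expect_lt(abs(sim0$x[nrow(sim0$x), 1]), 1e-6)
  # N=1 stationary variance D/(2 lambda tau_syn)
  lam <- 0.5; D <- 1.5; tau_syn <- 2
  sim1 <- simulate_linear_network(matrix(lam), D, tau_syn = tau_syn,
                                  t_total = 8000, dt = 0.05, seed = 9)
  v_hat <- var(sim1$x[, 1])
  v_true <- D / (2 * lam * tau_syn)
  tau_ac <- tau_syn / lam
  n_eff <- nrow(sim1$x) * sim1$dt / (2 * tau_ac)
  se <- v_true * sqrt(2 / n_eff)
  expect_lt(abs(v_hat - v_true), 3 * se)
})

test_that("fitted single-unit timescales match inverse eigenvalues for unit-localized modes", {
  ps <- vapply(1:10, function(s) {
    set.seed(s)
    lam <- runif(40, 0.1, 1)
    sim <- simulate_linear_network(diag(lam), 1, t_total = 2500,
                                   dt = 0.05, seed = 70 + s,
                                   burn_in = 0.04)
    ut <- unit_timescales(sim$x, 0.05)
    suppressWarnings(ks.test(ut$tau, 1 / lam)$p.value)
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})
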