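dims4 <- c(4L, 4L, 4L)

test_that("feature reduction keeps the fewest components reaching the variance target", {
  # orthogonal features with variances 4, 1, 0
  n <- 64
  f1 <- rep(c(-2, 2), length.out = n)
  f2 <- rep(c(-1, -1, 1, 1), length.out = n)
  grid <- voxel_grid(cbind(f1, f2, 0), dims4)
  red <- reduce_features(grid, 0.95)
  expect_identical(ncol(red$features), 2L)

  set.seed(1)
  g <- voxel_grid(matrix(rnorm(100 * 10), 100), c(100L, 1L, 1L))
  red2 <- reduce_features(g, 0.95)
  ev <- eigen(cov(g$features))$values
  k <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_identical(ncol(red2$features), as.integer(k))
  expect_gte(attr(red2, "variance_retained"), 0.95)
  # target 1 keeps all nonzero-variance components
  red3 <- reduce_features(g, 1)
  expect_identical(ncol(red3$features), 10L)
})

test_that("ridge solution equals an independent augmented-rows least-squares oracle", {
  set.seed(2)
  X <- matrix(rnorm(12 * 2), 12)
  grid <- voxel_grid(X, c(12L, 1L, 1L))
  pl <- data.frame(voxel = rep(1:12, each = 2),
                   tau_eff = exp(rnorm(24)))
  lam <- 0.7
  fit <- ridge_fit(grid, pl, penalty = lam, cv_folds = 0L)
  # oracle: centered augmented system [Xc; sqrt(lam) I] \ [yc; 0] via lm
  y <- log10(pl$tau_eff)
  Xn <- X[pl$voxel, ]
  Xc <- scale(Xn, scale = FALSE)
  yc <- y - mean(y)
  Xa <- rbind(Xc, sqrt(lam) * diag(2))
  ya <- c(yc, 0, 0)
  beta_o <- coef(lm(ya ~ 0 + Xa))
  expect_equal(unname(fit$betas), unname(beta_o), tolerance = 1e-9)
  # noiseless linear data, vanishing penalty: R2 -> 1
  pl2 <- data.frame(voxel = 1:12, tau_eff = 10^(X %*% c(1, -2) + 0.3))
  fit2 <- ridge_fit(grid, pl2, penalty = 1e-10, cv_folds = 0L)
  expect_gt(fit2$r2, 1 - 1e-8)
  expect_error(ridge_fit(grid, pl, penalty = -1), ">= 0")
})

test_that("planted signal fraction is recovered by cross-validated ridge", {
  r2s <- vapply(1:12, function(s) {
    w <- gen_voxel_world(dims = c(6L, 6L, 6L), n_features = 8,
                         signal_beta = 0.127, noise_sd = 0.3,
                         n_neurons = 300, seed = s)
    ridge_fit(w$grid, w$placements, seed = 100 + s)$r2_cv
  }, numeric(1))
  # planted signal fraction ~0.15 (0.127^2 / (0.127^2 + 0.09))
  expect_gt(mean(r2s), 0.05)
  expect_lt(mean(r2s), 0.25)
})

test_that("region baseline reproduces per-region means at negligible penalty", {
  tau <- c(1, 1, 3, 3)
  fit <- baseline_region_model(c("a", "a", "b", "b"), tau,
                               log_transform = FALSE, cv_folds = 0L)
  expect_equal(fit$fitted, c(1, 1, 3, 3), tolerance = 1e-5)
  expect_gt(fit$r2, 1 - 1e-6)
  # a single region explains nothing
  fit1 <- baseline_region_model(rep("a", 10), rlnorm(10),
                                log_transform = FALSE, cv_folds = 0L)
  expect_lt(abs(fit1$r2), 1e-8)
  # random labels stay inside the permutation null band
  set.seed(3)
  tau_r <- rlnorm(60)
  lab <- sample(letters[1:4], 60, TRUE)
  r2_obs <- baseline_region_model(lab, tau_r, cv_folds = 0L)$r2
  null_r2 <- replicate(200, {
    baseline_region_model(sample(lab), tau_r, cv_folds = 0L)$r2
  })
  expect_lte(r2_obs, quantile(null_r2, 0.995))
})

test_that("phase randomization preserves the amplitude spectrum, mean, and autocovariance", {
  set.seed(4)
  w <- gen_voxel_world(dims = c(6L, 8L, 4L), n_features = 3,
                       n_neurons = 10, seed = 5)
  sg <- phase_randomize(w$grid, seed = 6)
  d <- w$grid$dims
  for (a in 1:3) {
    f0 <- fft(array(w$grid$features[, a], d))
    f1 <- fft(array(sg$features[, a], d))
    expect_lt(max(abs(Mod(f0) - Mod(f1))), 1e-10)
    expect_lt(abs(mean(w$grid$features[, a]) - mean(sg$features[, a])),
              1e-12)
    # Wiener-Khinchin: circular autocovariance = inverse FFT of power
    acov0 <- Re(fft(Mod(f0)^2, inverse = TRUE))
    acov1 <- Re(fft(Mod(f1)^2, inverse = TRUE))
    expect_lt(max(abs(acov0 - acov1)) / max(abs(acov0)), 1e-10)
  }
  # constant field: only DC energy, surrogate is identical
  cg <- voxel_grid(matrix(2.5, prod(dims4)), dims4)
  expect_equal(phase_randomize(cg, seed = 7)$features, cg$features,
               tolerance = 1e-12)
  # surrogate differs from the original (phases actually randomized)
  expect_gt(max(abs(sg$features - w$grid$features)), 1e-3)
})

test_that("surrogate test detects aligned signal and stays calibrated under the null", {
  hits <- vapply(1:10, function(s) {
    w <- gen_voxel_world(dims = c(6L, 6L, 6L), n_features = 6,
                         signal_beta = 0.3, noise_sd = 0.25,
                         n_neurons = 300, seed = 200 + s)
    surrogate_test(w$grid, w$placements, n_surr = 60,
                   seed = 300 + s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # null: timescales spatially smooth but independent of the features
  ps <- vapply(1:12, function(s) {
    w <- gen_voxel_world(dims = c(6L, 6L, 6L), n_features = 6,
                         signal_beta = 0, noise_sd = 0.3,
                         n_neurons = 300, seed = 400 + s)
    surrogate_test(w$grid, w$placements, n_surr = 40,
                   seed = 500 + s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
  expect_error(surrogate_test(NULL, NULL, n_surr = 0), "positive")
})

test_that("unique explained variance singles out informative features", {
  # shuffling a constant feature changes nothing
  set.seed(8)
  w <- gen_voxel_world(dims = c(6L, 6L, 6L), n_features = 4,
                       signal_beta = 0.4, noise_sd = 0.2,
                       n_neurons = 250, seed = 9)
  gridc <- voxel_grid(cbind(w$grid$features, 1), w$grid$dims)
  uev_c <- unique_explained_variance(gridc, w$placements, 5, seed = 10)
  expect_lt(abs(uev_c$delta_r2), 0.02)

  # planted informative feature has the largest delta R2
  top_hits <- vapply(1:10, function(s) {
    w2 <- gen_voxel_world(dims = c(6L, 6L, 6L), n_features = 8,
                          signal_beta = 0.4, noise_sd = 0.2,
                          n_neurons = 250, seed = 600 + s)
    dr2 <- vapply(1:8, function(a) {
      unique_explained_variance(w2$grid, w2$placements, a,
                                seed = 700 + s)$delta_r2
    }, numeric(1))
    which.max(dr2) == 1L
  }, logical(1))
  expect_gte(mean(top_hits), 0.9)

  # a duplicated informative feature has ~zero unique variance
  w3 <- gen_voxel_world(dims = c(6L, 6L, 6L), n_features = 4,
                        signal_beta = 0.4, noise_sd = 0.2,
                        n_neurons = 250, seed = 11)
  gridd <- voxel_grid(cbind(w3$grid$features, w3$grid$features[, 1]),
                      w3$grid$dims)
  uev_d <- unique_explained_variance(gridd, w3$placements, 1, seed = 12)
  expect_lt(abs(uev_d$delta_r2), 0.03)
})
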