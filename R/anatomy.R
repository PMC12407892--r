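#' Voxel feature grid
#'
#' Dense 3-D grid of anatomical features (e.g. gene-expression or
#' cell-type densities). Voxels are indexed linearly in column-major
#' (Fortran) order over `dims`.
#'
#' @param features numeric matrix, voxels in rows (length `prod(dims)`),
#'   features in columns.
#' @param dims integer triple `(nx, ny, nz)`.
#' @param voxel_size voxel side length in millimetres (default 0.2, i.e.
#'   200 micrometres).
#' @param feature_names optional column names.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(features, dims, voxel_size = 0.2,
                       feature_names = NULL) {
  features <- as.matrix(features)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, nrow(features) == prod(dims),
            all(is.finite(features)))
  if (!is.null(feature_names)) colnames(features) <- feature_names
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  structure(list(features = features, dims = dims, voxel_size = voxel_size),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %dx%dx%d voxels (%.0f um), %d features\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_size * 1e3,
              ncol(x$features)))
  invisible(x)
}

#' Reduce voxel features to principal components
#'
#' Centers the features and projects onto the smallest number of
#' principal components whose cumulative variance fraction reaches
#' `variance_target` (redundant anatomical features are strongly
#' correlated across voxels).
#'
#' @param grid a [voxel_grid()].
#' @param variance_target fraction of variance to retain (default 0.95).
#' @return a new `voxel_grid` whose features are component scores; the
#'   attained variance fraction and rotation are attached as attributes
#'   `variance_retained` and `rotation`.
#' @export
reduce_features <- function(grid, variance_target = 0.95) {
  stopifnot(inherits(grid, "voxel_grid"),
            variance_target > 0, variance_target <= 1)
  if (nrow(grid$features) < 2L) stop("need at least 2 voxels")
  pc <- stats::prcomp(grid$features, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- cumsum(v) / sum(v)
  k <- which(frac >= variance_target - 1e-12)[1L]
  if (is.na(k)) k <- length(v)
  out <- voxel_grid(pc$x[, seq_len(k), drop = FALSE], grid$dims,
                    grid$voxel_size,
                    feature_names = paste0("PC", seq_len(k)))
  attr(out, "variance_retained") <- frac[k]
  attr(out, "rotation") <- pc$rotation[, seq_len(k), drop = FALSE]
  out
}

# penalized normal equations with unpenalized intercept (via centering)
.ridge_solve <- function(X, y, penalty) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  p <- ncol(X)
  A <- crossprod(Xc) + diag(penalty, p)
  beta <- tryCatch(solve(A, crossprod(Xc, yc)),
                   error = function(e) stop(
                     "singular system; use a penalty > 0", call. = FALSE))
  list(beta = drop(beta), intercept = ym - sum(xm * drop(beta)))
}

.r_squared <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

#' Ridge regression of neuron timescales on voxel features
#'
#' All neurons located in voxel `i` share that voxel's predictor row;
#' the model is `target(tau) ~ X beta + beta0` with an L2 penalty on
#' `beta` (intercept unpenalized). By default the target is
#' `log10(tau_eff)` since timescales are heavy-tailed. When `penalty` is
#' `NULL` it is chosen by k-fold cross-validation over a log-spaced
#' grid; the cross-validated R-squared at the chosen penalty is reported
#' alongside the in-sample one.
#'
#' @param grid a [voxel_grid()].
#' @param placements data.frame with columns `voxel` (linear index into
#'   the grid) and `tau_eff` (seconds).
#' @param penalty ridge penalty; `NULL` to cross-validate.
#' @param log_transform regress `log10(tau_eff)` (default) or raw values.
#' @param cv_folds folds for penalty selection and the CV R-squared.
#' @param penalty_grid candidate penalties when cross-validating.
#' @param seed RNG seed for the fold assignment.
#' @return object of class `ridge_result`: `betas`, `intercept`, `r2`
#'   (in-sample), `r2_cv`, `penalty`, `fitted`, `target`.
#' @export
ridge_fit <- function(grid, placements, penalty = NULL, log_transform = TRUE,
                      cv_folds = 5L, penalty_grid = 10^seq(-4, 4, length.out = 17),
                      seed = NULL) {
  stopifnot(inherits(grid, "voxel_grid"),
            all(c("voxel", "tau_eff") %in% names(placements)))
  if (!is.null(penalty) && penalty < 0) stop("'penalty' must be >= 0")
  if (is.null(penalty) && cv_folds < 2L) {
    stop("penalty selection requires cv_folds >= 2")
  }
  X <- grid$features[placements$voxel, , drop = FALSE]
  y <- if (log_transform) log10(placements$tau_eff) else placements$tau_eff
  n <- length(y)
  if (n < 2L) stop("need at least 2 neurons")
  if (!is.null(seed)) set.seed(seed)
  do_cv <- is.null(penalty) || (cv_folds >= 2L && n >= cv_folds)
  folds <- if (do_cv) sample(rep_len(seq_len(cv_folds), n)) else NULL
  cv_r2 <- function(lam) {
    yhat <- numeric(n)
    for (f in seq_len(cv_folds)) {
      te <- folds == f
      fit <- .ridge_solve(X[!te, , drop = FALSE], y[!te], lam)
      yhat[te] <- X[te, , drop = FALSE] %*% fit$beta + fit$intercept
    }
    .r_squared(y, yhat)
  }
  if (is.null(penalty)) {
    scores <- vapply(penalty_grid, cv_r2, numeric(1L))
    penalty <- penalty_grid[which.max(scores)]
    r2_cv <- max(scores)
  } else {
    r2_cv <- if (do_cv) cv_r2(penalty) else NA_real_
  }
  fit <- .ridge_solve(X, y, penalty)
  yhat <- drop(X %*% fit$beta + fit$intercept)
  structure(
    list(betas = fit$beta, intercept = fit$intercept,
         r2 = .r_squared(y, yhat), r2_cv = r2_cv, penalty = penalty,
         fitted = yhat, target = if (log_transform) "log10_tau" else "tau",
         n = n),
    class = "ridge_result")
}

#' @export
print.ridge_result <- function(x, ...) {
  cat(sprintf(
    "<ridge_result> %d neurons, %d features, penalty = %.3g, R2 = %.3f (CV %.3f)\n",
    x$n, length(x$betas), x$penalty, x$r2, x$r2_cv))
  invisible(x)
}

#' Region-indicator baseline model
#'
#' Ridge regression with one-hot brain-region indicators as the only
#' predictors. With a negligible penalty the predictions equal the
#' per-region means of the target, which is the natural baseline for
#' voxel-level anatomical predictors.
#'
#' @param region_labels factor/character, one region per neuron.
#' @param tau_eff effective timescales (seconds), one per neuron.
#' @param penalty ridge penalty (default near zero).
#' @param log_transform as in [ridge_fit()].
#' @param cv_folds,seed as in [ridge_fit()].
#' @return a `ridge_result`.
#' @export
baseline_region_model <- function(region_labels, tau_eff, penalty = 1e-8,
                                  log_transform = TRUE, cv_folds = 5L,
                                  seed = NULL) {
  region_labels <- factor(region_labels)
  X <- 1 * outer(as.character(region_labels), levels(region_labels), `==`)
  colnames(X) <- levels(region_labels)
  grid <- structure(list(features = X, dims = c(nrow(X), 1L, 1L),
                         voxel_size = NA_real_), class = "voxel_grid")
  placements <- data.frame(voxel = seq_len(nrow(X)), tau_eff = tau_eff)
  ridge_fit(grid, placements, penalty = penalty,
            log_transform = log_transform, cv_folds = cv_folds, seed = seed)
}

#' Phase-randomized surrogate of a voxel grid
#'
#' Applies a 3-D Fourier transform to each feature field, replaces the
#' phases with random ones (Hermitian-symmetric, so the surrogate is
#' real) while keeping every amplitude, and inverts. The zero-frequency
#' coefficient is preserved, so feature means are unchanged. The
#' surrogate has exactly the spatial power spectrum (hence the spatial
#' autocovariance) of the original but no relationship to any external
#' map.
#'
#' @param grid a [voxel_grid()].
#' @param seed RNG seed.
#' @return a new `voxel_grid` of surrogate features.
#' @export
phase_randomize <- function(grid, seed = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(grid$dims < 2L)) stop("each grid dimension must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  d <- grid$dims
  nv <- prod(d)
  out <- grid$features
  for (a in seq_len(ncol(out))) {
    arr <- array(grid$features[, a], dim = d)
    f <- stats::fft(arr)
    # phases of a real white-noise field are Hermitian by construction
    z <- stats::fft(array(stats::rnorm(nv), dim = d))
    mz <- Mod(z)
    ph <- ifelse(mz > 0, z / mz, 1 + 0i)
    g <- Mod(f) * ph
    g[1L] <- f[1L]  # preserve DC (mean)
    out[, a] <- Re(stats::fft(g, inverse = TRUE)) / nv
  }
  voxel_grid(out, d, grid$voxel_size, colnames(grid$features))
}

#' Spatial surrogate test of a feature-timescale relationship
#'
#' Fits the original ridge model, then refits against `n_surr`
#' phase-randomized surrogate grids (same penalty) and reports the
#' fraction of surrogate in-sample R-squared values at or above the
#' observed one. Because the surrogates preserve the features' spatial
#' autocorrelation, a small p-value cannot be explained by independent
#' smooth spatial variation alone.
#'
#' @param grid a [voxel_grid()].
#' @param placements as in [ridge_fit()].
#' @param n_surr number of surrogates (default 500).
#' @param seed RNG seed.
#' @param penalty ridge penalty; `NULL` cross-validates once on the
#'   original fit and reuses the chosen value for all surrogates.
#' @param log_transform as in [ridge_fit()].
#' @return list with `p_value`, `r2_observed`, `r2_surrogate` (vector),
#'   `penalty`.
#' @export
surrogate_test <- function(grid, placements, n_surr = 500L, seed = NULL,
                           penalty = NULL, log_transform = TRUE) {
  n_surr <- as.integer(n_surr)
  if (n_surr < 1L) stop("'n_surr' must be positive")
  if (!is.null(seed)) set.seed(seed)
  fit <- ridge_fit(grid, placements, penalty = penalty,
                   log_transform = log_transform, cv_folds = 5L)
  r2_surr <- vapply(seq_len(n_surr), function(s) {
    sg <- phase_randomize(grid)
    ridge_fit(sg, placements, penalty = fit$penalty,
              log_transform = log_transform, cv_folds = 0L)$r2
  }, numeric(1L))
  list(p_value = mean(r2_surr >= fit$r2), r2_observed = fit$r2,
       r2_surrogate = r2_surr, penalty = fit$penalty)
}

#' Unique explained variance of one feature
#'
#' Refits the model with one feature's values randomly permuted across
#' voxels (breaking its spatial assignment while keeping its marginal
#' distribution) and reports `delta R2 = R2_full - R2_reduced`. Features
#' whose information is duplicated elsewhere in the grid have near-zero
#' unique explained variance.
#'
#' @param grid a [voxel_grid()].
#' @param placements as in [ridge_fit()].
#' @param feature_index column index of the feature to shuffle.
#' @param seed RNG seed.
#' @param penalty ridge penalty; `NULL` cross-validates on the full fit.
#' @param log_transform as in [ridge_fit()].
#' @return list with `delta_r2`, `r2_full`, `r2_reduced`.
#' @export
unique_explained_variance <- function(grid, placements, feature_index,
                                      seed = NULL, penalty = NULL,
                                      log_transform = TRUE) {
  stopifnot(feature_index >= 1L, feature_index <= ncol(grid$features))
  if (!is.null(seed)) set.seed(seed)
  fit <- ridge_fit(grid, placements, penalty = penalty,
                   log_transform = log_transform, cv_folds = 5L)
  shuffled <- grid$features
  shuffled[, feature_index] <- sample(shuffled[, feature_index])
  g2 <- voxel_grid(shuffled, grid$dims, grid$voxel_size,
                   colnames(grid$features))
  fit2 <- ridge_fit(g2, placements, penalty = fit$penalty,
                    log_transform = log_transform, cv_folds = 0L)
  list(delta_r2 = fit$r2 - fit2$r2, r2_full = fit$r2, r2_reduced = fit2$r2)
}
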