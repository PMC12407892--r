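#' Eigenvalue family of a linear network
#'
#' Describes the distribution `f(lambda)` of effective-connectivity
#' eigenvalues. Near zero, `f(lambda) ~ lambda^zeta` determines the
#' power-law exponent `2 + zeta` of the slow-timescale tail at the edge
#' of instability.
#'
#' * `uniform`: constant density on `(lambda_min, lambda_max)`; zeta = 0.
#' * `semicircle`: density `(2/pi R^2) sqrt(R^2 - (R - lambda)^2)` on
#'   `[0, 2R]`; zeta = 0.5 and the slow tail starts near
#'   `tau = 1/(2R)` (eigenvalue cutoff `2R` where the leading sqrt term
#'   stops dominating).
#' * `gamma`: gamma density with shape `alpha` and scale 1; zeta =
#'   `alpha - 1`, eigenvalue cutoff `log(2)`.
#'
#' @param family one of `"uniform"`, `"semicircle"`, `"gamma"`.
#' @param lambda_min,lambda_max uniform support bounds.
#' @param radius semicircle radius R.
#' @param shape gamma shape parameter.
#' @return object of class `eigen_family` with fields `family`, `params`,
#'   `zeta`, `tau_cutoff` (start of the asymptotic tail; `NA` for the
#'   uniform family, whose whole range is power-law).
#' @export
eigen_family <- function(family = c("uniform", "semicircle", "gamma"),
                         lambda_min = 0, lambda_max = 1, radius = 1,
                         shape = 2) {
  family <- match.arg(family)
  out <- switch(family,
    uniform = {
      if (!(lambda_max > lambda_min) || lambda_min < 0) {
        stop("need 0 <= lambda_min < lambda_max")
      }
      list(family = family,
           params = list(lambda_min = lambda_min, lambda_max = lambda_max),
           zeta = 0, tau_cutoff = NA_real_)
    },
    semicircle = {
      if (radius <= 0) stop("'radius' must be positive")
      list(family = family, params = list(radius = radius), zeta = 0.5,
           tau_cutoff = 1 / (2 * radius))
    },
    gamma = {
      if (shape <= 0) stop("'shape' must be positive")
      zeta <- shape - 1
      if (zeta <= -1) stop("gamma shape must exceed 0 (zeta > -1)")
      list(family = family, params = list(shape = shape), zeta = zeta,
           tau_cutoff = 1 / log(2))
    }
  )
  structure(out, class = "eigen_family")
}

#' Sample eigenvalues from a family
#'
#' Uniform values are sampled directly; the semicircle on `[0, 2R]` is a
#' scaled Beta(3/2, 3/2); the gamma family uses the standard gamma
#' sampler with scale 1.
#'
#' @param family an [eigen_family()].
#' @param n number of eigenvalues (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of eigenvalue draws.
#' @export
sample_eigenvalues <- function(family, n = 1000L, seed = NULL) {
  stopifnot(inherits(family, "eigen_family"))
  if (!is.null(seed)) set.seed(seed)
  switch(family$family,
    uniform = stats::runif(n, family$params$lambda_min,
                           family$params$lambda_max),
    semicircle = 2 * family$params$radius * stats::rbeta(n, 1.5, 1.5),
    gamma = stats::rgamma(n, shape = family$params$shape, scale = 1)
  )
}

#' Eigenvalue density of a family
#'
#' @param family an [eigen_family()].
#' @return a vectorized density function `f(lambda)`.
#' @export
eigenvalue_density <- function(family) {
  stopifnot(inherits(family, "eigen_family"))
  switch(family$family,
    uniform = {
      lo <- family$params$lambda_min; hi <- family$params$lambda_max
      function(l) ifelse(l >= lo & l <= hi, 1 / (hi - lo), 0)
    },
    semicircle = {
      R <- family$params$radius
      function(l) {
        d <- R^2 - (R - l)^2
        ifelse(l >= 0 & l <= 2 * R & d >= 0, 2 / (pi * R^2) * sqrt(pmax(d, 0)), 0)
      }
    },
    gamma = {
      a <- family$params$shape
      function(l) stats::dgamma(l, shape = a, scale = 1)
    }
  )
}

#' Timescale density implied by an eigenvalue density
#'
#' Timescales are inverse eigenvalues; by the reciprocal change of
#' variables, `g(tau) = f(1/tau) / tau^2`.
#'
#' @param family an [eigen_family()].
#' @return a vectorized density function `g(tau)`.
#' @export
timescale_density <- function(family) {
  f <- eigenvalue_density(family)
  function(tau) ifelse(tau > 0, f(1 / tau) / tau^2, 0)
}

#' Predicted power-law exponent of slow timescales
#'
#' At the edge of instability the slow-timescale distribution follows a
#' power law with exponent `gamma = 2 + zeta`, where `zeta` is the
#' small-eigenvalue exponent of the connectivity eigenvalue density.
#'
#' @param zeta small-eigenvalue exponent (or an [eigen_family()], whose
#'   `zeta` is used).
#' @return the predicted exponent.
#' @export
predicted_exponent <- function(zeta) {
  if (inherits(zeta, "eigen_family")) zeta <- zeta$zeta
  if (zeta <= -1) stop("zeta must exceed -1 (normalizable density)")
  2 + zeta
}

#' Convert eigenvalues to network timescales at the edge of instability
#'
#' Shifts the eigenvalue support so that its lower edge sits at
#' `epsilon` (the distance to the instability threshold; smaller values
#' move the network closer to the edge and unbound the slowest
#' timescales at `tau_syn / epsilon`), then maps each eigenvalue to a
#' timescale `tau = tau_syn / lambda`. The synaptic time constant scales
#' every timescale proportionally and leaves the tail exponent
#' unchanged.
#'
#' @param eigenvalues numeric draws (e.g. from [sample_eigenvalues()]).
#' @param tau_syn synaptic time constant in seconds (default 1).
#' @param epsilon distance to instability (default 1e-4).
#' @param support_min lower edge of the family's support before the
#'   shift (default 0, the edge-of-instability limit).
#' @return numeric vector of timescales.
#' @export
eigen_to_timescales <- function(eigenvalues, tau_syn = 1, epsilon = 1e-4,
                                support_min = 0) {
  if (epsilon <= 0) stop("'epsilon' must be positive")
  lam <- eigenvalues - support_min + epsilon
  if (any(lam <= 0)) stop("shifted eigenvalues must all be positive")
  tau_syn / lam
}

#' Analytic lagged correlation matrix of a linear noise-driven network
#'
#' For dynamics `dx/dt = -M x + eta` with white noise of magnitude `D`
#' per unit, the stationary lagged correlation matrix is the double
#' eigen-sum
#' \deqn{C(t) = D \sum_{p,q} \frac{u_q^\top u_p}{\lambda_p + \lambda_q}
#'       v_p v_q^\top e^{-\lambda_p t},}
#' with `v_p`/`u_p` the right/left eigenvectors of `M` (normalized so
#' `u_p^T v_q = delta_pq`). The diagonal gives each unit's
#' autocorrelation as a mixture of eigenmode decays with timescales
#' `1/lambda_p`.
#'
#' @param M effective connectivity matrix (eigenvalues must have
#'   positive real part).
#' @param D noise magnitude (common to all units).
#' @param t nonnegative time lag.
#' @return the `N x N` correlation matrix at lag `t`.
#' @export
analytic_correlation <- function(M, D, t) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), t >= 0)
  e <- eigen(M)
  lam <- e$values
  if (any(Re(lam) <= 0)) {
    stop(sprintf("unstable M: min Re(eigenvalue) = %.3g", min(Re(lam))))
  }
  V <- e$vectors
  U <- solve(V)    # rows are left eigenvectors, u_p^T v_q = delta
  G <- U %*% t(U)  # G[p, q] = u_p . u_q (plain product, real noise)
  # with real M, conjugate eigen-pairs make the full sum real; use the
  # complex form and return the real part
  S <- (G / outer(lam, lam, `+`)) * exp(-lam * t)
  C <- V %*% S %*% t(V) * D
  out <- Re(C)
  if (max(abs(Im(C))) > 1e-8 * max(abs(out), 1)) {
    warning("non-negligible imaginary part discarded")
  }
  out
}

#' Euler-Maruyama simulation of the linear network
#'
#' Integrates `tau_syn dx = -M x dt + sqrt(D) dW` and returns the
#' activity traces after an optional burn-in.
#'
#' @param M effective connectivity matrix.
#' @param D noise magnitude.
#' @param tau_syn synaptic time constant (seconds).
#' @param t_total total simulated time (seconds).
#' @param dt integration step; defaults to `0.1 * tau_syn / max Re
#'   eigenvalue` capped at `0.1 * tau_syn`.
#' @param burn_in fraction of initial samples discarded (default 0.1).
#' @param seed RNG seed.
#' @param x0 initial state (default 0).
#' @return list with `x` (time steps in rows, units in columns), `dt`,
#'   `times`.
#' @export
simulate_linear_network <- function(M, D, tau_syn = 1, t_total = 100,
                                    dt = NULL, burn_in = 0.1, seed = NULL,
                                    x0 = NULL) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  lam <- eigen(M, only.values = TRUE)$values
  if (any(Re(lam) <= 0)) {
    stop(sprintf("unstable M: min Re(eigenvalue) = %.3g", min(Re(lam))))
  }
  if (is.null(dt)) dt <- 0.1 * tau_syn / max(max(Re(lam)), 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(M)
  n_steps <- ceiling(t_total / dt)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  keep_from <- floor(burn_in * n_steps) + 1L
  out <- matrix(NA_real_, n_steps - keep_from + 1L, n)
  amp <- sqrt(D * dt) / tau_syn
  row <- 0L
  for (s in seq_len(n_steps)) {
    x <- x - (M %*% x) * (dt / tau_syn) + amp * stats::rnorm(n)
    if (any(!is.finite(x))) {
      stop(sprintf("divergence at step %d; min eigenvalue %.3g too small for dt",
                   s, min(Re(lam))))
    }
    if (s >= keep_from) {
      row <- row + 1L
      out[row, ] <- x
    }
  }
  list(x = out, dt = dt, times = (keep_from:n_steps) * dt)
}
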