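#' Symmetric alpha-stable random numbers
#'
#' Chambers-Mallows-Stuck construction for the symmetric (`beta = 0`,
#' `mu = 0`) stable family. Tails satisfy `P(|X| > x) ~ x^(-alpha)`
#' (density tail exponent `1 + alpha`) for `alpha < 2`; `alpha = 2` is
#' Gaussian with standard deviation `scale * sqrt(2)`.
#'
#' @param n number of draws.
#' @param alpha stability index in `(0, 2]`.
#' @param scale scale parameter `c > 0`.
#' @param seed RNG seed.
#' @return numeric vector of draws.
#' @export
rstable_sym <- function(n, alpha, scale = 1, seed = NULL) {
  if (alpha <= 0 || alpha > 2) stop("'alpha' must be in (0, 2]")
  if (scale <= 0) stop("'scale' must be positive")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n, -pi / 2, pi / 2)
  e <- stats::rexp(n)
  x <- if (abs(alpha - 1) < 1e-12) {
    tan(u)  # Cauchy
  } else {
    sin(alpha * u) / cos(u)^(1 / alpha) *
      (cos((1 - alpha) * u) / e)^((1 - alpha) / alpha)
  }
  scale * x
}

#' Nonlinear network specification
#'
#' Rate network `tau_syn dx/dt = -x + g J phi(x)` with `phi = tanh` and
#' i.i.d. alpha-stable connectivity entries. The connectivity scale
#' defaults to `N^(-1/alpha)` (the convention under which the recurrent
#' input stays O(1) as N grows); `scale_convention = "one_over_n"`
#' selects the literal `1/N` scale instead.
#'
#' @param n_units number of units (default 1000).
#' @param alpha stability index in `(0, 2]`.
#' @param g synaptic gain.
#' @param tau_syn synaptic time constant (seconds).
#' @param n_steps integration steps (default 14400).
#' @param dt integration step; default `0.1 * tau_syn`.
#' @param scale_convention `"n_pow_alpha"` (default) or `"one_over_n"`.
#' @param burn_in fraction of initial steps discarded (default 0.3: in
#'   the chaotic regime the slowest units have timescales comparable to
#'   a tenth of the simulated span, and their initial transients inflate
#'   the slow tail of the pooled timescale distribution unless the
#'   burn-in comfortably exceeds them).
#' @return object of class `nonlinear_spec`.
#' @export
nonlinear_spec <- function(n_units = 1000L, alpha = 1.2, g = 1.8,
                           tau_syn = 1, n_steps = 14400L, dt = NULL,
                           scale_convention = c("n_pow_alpha", "one_over_n"),
                           burn_in = 0.3) {
  scale_convention <- match.arg(scale_convention)
  if (alpha <= 0 || alpha > 2) stop("'alpha' must be in (0, 2]")
  if (is.null(dt)) dt <- 0.1 * tau_syn
  scale <- switch(scale_convention,
                  n_pow_alpha = n_units^(-1 / alpha),
                  one_over_n = 1 / n_units)
  structure(
    list(n_units = as.integer(n_units), alpha = alpha, g = g,
         tau_syn = tau_syn, n_steps = as.integer(n_steps), dt = dt,
         scale = scale, scale_convention = scale_convention,
         burn_in = burn_in),
    class = "nonlinear_spec")
}

#' Sample an alpha-stable connectivity matrix
#'
#' @param spec a [nonlinear_spec()].
#' @param seed RNG seed.
#' @return `N x N` matrix of i.i.d. symmetric alpha-stable entries at
#'   the spec's scale.
#' @export
sample_stable_connectivity <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "nonlinear_spec"))
  n <- spec$n_units
  matrix(rstable_sym(n * n, spec$alpha, spec$scale, seed = seed), n, n)
}

#' Simulate the nonlinear rate network
#'
#' Euler integration of `tau_syn dx/dt = -x + g J tanh(x)` from random
#' initial conditions; the burn-in fraction is discarded.
#'
#' @param spec a [nonlinear_spec()].
#' @param J connectivity matrix (defaults to a fresh draw).
#' @param seed RNG seed (initial conditions and, when `J` is missing,
#'   the connectivity draw).
#' @return list with `x` (post-burn-in traces, steps in rows), `dt`,
#'   `spec`.
#' @export
simulate_nonlinear <- function(spec, J = NULL, seed = NULL) {
  stopifnot(inherits(spec, "nonlinear_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(J)) J <- sample_stable_connectivity(spec)
  n <- spec$n_units
  stopifnot(nrow(J) == n, ncol(J) == n)
  x <- stats::rnorm(n, sd = 0.5)
  a <- spec$dt / spec$tau_syn
  keep_from <- floor(spec$burn_in * spec$n_steps) + 1L
  out <- matrix(NA_real_, spec$n_steps - keep_from + 1L, n)
  gJ <- spec$g * J
  row <- 0L
  for (s in seq_len(spec$n_steps)) {
    x <- (1 - a) * x + a * (gJ %*% tanh(x))
    if (any(!is.finite(x))) stop(sprintf("non-finite state at step %d", s))
    if (s >= keep_from) {
      row <- row + 1L
      out[row, ] <- x
    }
  }
  list(x = out, dt = spec$dt, spec = spec)
}

# FFT-based normalized autocorrelation of a demeaned trace (biased
# estimator), lags 1..j_max
.acf_fft <- function(z, j_max) {
  n <- length(z)
  z <- z - mean(z)
  m <- stats::nextn(2L * n)
  fz <- stats::fft(c(z, numeric(m - n)))
  r <- Re(stats::fft(fz * Conj(fz), inverse = TRUE))[seq_len(j_max + 1L)] / m
  (r / r[1L])[-1L]
}

# single-exponential fit of a continuous-signal autocorrelation
.fit_single_exp_acf <- function(ac, lags_s, dt) {
  # initial guess from the first crossing of 1/e
  below <- which(ac < exp(-1))
  tau0 <- if (length(below)) max(lags_s[below[1L]], dt) else max(lags_s) / 2
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(c0 = max(ac[1L], 0.1), tau = tau0),
      lower = c(0, dt), upper = c(Inf, Inf),
      fn = function(p) p[1L] * exp(-lags_s / p[2L]) - ac,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  list(tau = unname(fit$par["tau"]), c0 = unname(fit$par["c0"]))
}

#' Single-unit timescales from simulated activity
#'
#' Computes each unit's activity autocorrelation (standard biased
#' normalized estimate for continuous signals) and fits a single
#' exponential decay over lags `1..max_lag`. Near-constant units (not
#' activated in the dynamics) and non-convergent fits are excluded; the
#' exclusion count is reported.
#'
#' @param traces matrix of activity (time steps in rows, units in
#'   columns).
#' @param dt time step of the traces (seconds).
#' @param max_lag maximum lag in seconds for the fit (default: a quarter
#'   of the trace length).
#' @param var_floor variance threshold below which a unit is treated as
#'   silent.
#' @return list with `tau` (per retained unit), `n_excluded`.
#' @export
unit_timescales <- function(traces, dt, max_lag = NULL, var_floor = 1e-6) {
  stopifnot(is.matrix(traces), nrow(traces) > 10L)
  t_len <- nrow(traces)
  if (is.null(max_lag)) max_lag <- t_len * dt / 4
  j_max <- max(3L, min(t_len - 2L, floor(max_lag / dt)))
  taus <- rep(NA_real_, ncol(traces))
  for (i in seq_len(ncol(traces))) {
    z <- traces[, i]
    if (stats::var(z) < var_floor) next
    ac <- .acf_fft(z, j_max)
    # fit window adapted to the decay: ~10x the 1/e crossing, so fast and
    # slow units are both resolved without fitting pure noise tail
    below <- which(ac < exp(-1))
    j_fit <- if (length(below)) min(j_max, max(30L, 10L * below[1L])) else j_max
    idx <- unique(round(seq(1L, j_fit, length.out = min(300L, j_fit))))
    fit <- .fit_single_exp_acf(ac[idx], idx * dt, dt)
    if (is.null(fit)) next
    taus[i] <- fit$tau
  }
  keep <- !is.na(taus)
  if (!any(keep)) stop("all units excluded from timescale estimation")
  list(tau = taus[keep], n_excluded = sum(!keep))
}

#' Pooled timescale distribution of the nonlinear network
#'
#' Runs `n_reps` independent simulations (fresh connectivity and initial
#' conditions per repetition), estimates single-unit timescales in each,
#' pools them, and fits a power-law tail. In the chaotic regime the
#' fitted tail exponent matches the connectivity tail exponent
#' `1 + alpha`, independent of the gain, while `tau_syn` scales the
#' cutoff and median.
#'
#' @param spec a [nonlinear_spec()].
#' @param n_reps number of repetitions (default 100).
#' @param seed RNG seed (per-repetition seeds are derived from it).
#' @param decimate candidate-cutoff stride for the tail fit.
#' @param max_lag fit lag extent passed to [unit_timescales()].
#' @param chaos_var_floor minimum mean activity variance for a
#'   repetition to count as chaotic; realizations that settle into the
#'   fixed point are skipped and counted (chaos is verified empirically,
#'   not assumed from the gain alone).
#' @return list with `tau` (pooled samples), `fit` (a `power_law_fit`),
#'   `n_excluded` (units), `n_skipped` (non-chaotic repetitions).
#' @export
timescale_experiment <- function(spec, n_reps = 100L, seed = 1L,
                                 decimate = 1L, max_lag = NULL,
                                 chaos_var_floor = 1e-4) {
  stopifnot(inherits(spec, "nonlinear_spec"), n_reps >= 1L)
  pooled <- vector("list", n_reps)
  excluded <- 0L
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_nonlinear(spec, seed = seed + r)
    if (mean(apply(sim$x, 2L, stats::var)) < chaos_var_floor) {
      skipped <- skipped + 1L
      next
    }
    ut <- unit_timescales(sim$x, spec$dt, max_lag = max_lag)
    pooled[[r]] <- ut$tau
    excluded <- excluded + ut$n_excluded
  }
  tau <- unlist(pooled)
  if (!length(tau)) stop("no chaotic repetition; increase gain or n_reps")
  fit <- fit_power_law(tau, decimate = decimate)
  list(tau = tau, fit = fit, n_excluded = excluded, n_skipped = skipped)
}
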