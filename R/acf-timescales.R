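.exclusion <- function(reason) {
  structure(list(reason = reason), class = "neurotau_exclusion")
}

#' Exclusion marker
#'
#' Neurons can be excluded from timescale analysis (degenerate count
#' series, no converged fit). Such results are marked with class
#' `neurotau_exclusion` carrying the reason.
#'
#' @param x object to test.
#' @return logical.
#' @export
is_excluded <- function(x) inherits(x, "neurotau_exclusion")

#' @export
print.neurotau_exclusion <- function(x, ...) {
  cat(sprintf("<excluded> %s\n", x$reason))
  invisible(x)
}

#' Spike train object
#'
#' Container for a single unit's spike times over a recording of known
#' duration. Times are in seconds, sorted nondecreasing, within
#' `[0, duration]`.
#'
#' @param spike_times numeric vector of spike times (seconds).
#' @param duration recording duration in seconds.
#' @param unit_id identifier for the unit.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(spike_times, duration, unit_id = "unit") {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && is.unsorted(spike_times)) {
    spike_times <- sort(spike_times)
  }
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("'duration' must be a single positive number (seconds)")
  }
  if (length(spike_times) && (spike_times[1L] < 0 ||
                              spike_times[length(spike_times)] > duration)) {
    stop("spike times must lie within [0, duration]")
  }
  structure(
    list(unit_id = unit_id, spike_times = spike_times, duration = duration),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes over %.1f s (rate %.2f Hz)\n",
              x$unit_id, length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration))
  invisible(x)
}

#' Bin a spike train into counts
#'
#' Counts spikes in consecutive half-open bins `[i*dt, (i+1)*dt)`. The
#' number of bins is `floor(duration / bin_width)`; spikes at or beyond
#' the last full bin edge are dropped (a fractional trailing bin is never
#' formed).
#'
#' @param train a [spike_train()].
#' @param bin_width bin width in seconds (default 5 ms).
#' @return an object of class `binned_counts` with fields `counts`,
#'   `bin_width`, `n_bins`.
#' @export
bin_spikes <- function(train, bin_width = 0.005) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("'bin_width' must be a single positive number")
  }
  n_bins <- floor(train$duration / bin_width)
  if (n_bins < 1L) stop("duration shorter than one bin")
  edges_end <- n_bins * bin_width
  st <- train$spike_times[train$spike_times < edges_end]
  idx <- floor(st / bin_width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(counts = as.integer(counts), bin_width = bin_width,
         n_bins = as.integer(n_bins), unit_id = train$unit_id),
    class = "binned_counts"
  )
}

#' Spike-count autocorrelation with lag-dependent windowed means
#'
#' Computes the autocorrelogram of binned spike counts. At lag index `j`
#' the estimate is
#' \deqn{AC(t_j) = \frac{1}{\hat\sigma^2 (N-j)} \sum_{i=1}^{N-j}
#'   (A_i - \hat\mu_1(j)) (A_{i+j} - \hat\mu_2(j)),}
#' where \eqn{\hat\mu_1(j)} and \eqn{\hat\mu_2(j)} are the means of the
#' leading and trailing windows of length \eqn{N-j} and
#' \eqn{\hat\sigma^2} is the unbiased sample variance of the full series.
#' Under this normalization the zero-lag value is exactly `(N-1)/N`.
#'
#' The cross-products are evaluated by FFT, so the result is identical
#' (to floating point) to the direct double sum.
#'
#' @param counts a [bin_spikes()] result.
#' @param max_lag largest lag in seconds (default 5 s).
#' @return object of class `spike_acf`: `lags` (seconds, starting at 0),
#'   `ac`, `sample_variance`, `mu1`, `mu2`, `bin_width`, `n_bins`.
#'   A constant count series has zero variance; in that case the object is
#'   flagged `degenerate = TRUE` and carries no autocorrelation values.
#' @export
autocorrelation <- function(counts, max_lag = 5) {
  stopifnot(inherits(counts, "binned_counts"))
  a <- as.numeric(counts$counts)
  n <- length(a)
  j_max <- floor(max_lag / counts$bin_width)
  if (n <= j_max + 1L) stop("series too short for requested max_lag")
  s1 <- sum(a)
  s2 <- sum(a^2)
  sigma2 <- (s2 - s1^2 / n) / (n - 1)
  if (sigma2 <= 0) {
    return(structure(
      list(degenerate = TRUE, unit_id = counts$unit_id,
           bin_width = counts$bin_width, n_bins = n),
      class = "spike_acf"
    ))
  }
  # raw lagged cross-products sum_i A_i A_{i+j} for all j at once
  m <- stats::nextn(2L * n)
  fa <- stats::fft(c(a, numeric(m - n)))
  cross <- Re(stats::fft(fa * Conj(fa), inverse = TRUE)) / m
  j <- 0:j_max
  s_j <- cross[j + 1L]
  cs <- cumsum(a)
  # mu1(j): mean of a[1..n-j]; mu2(j): mean of a[(j+1)..n]
  mu1 <- cs[n - j] / (n - j)
  mu2 <- (cs[n] - c(0, cs[j[-1L]])) / (n - j)
  ac <- (s_j - (n - j) * mu1 * mu2) / (sigma2 * (n - j))
  structure(
    list(degenerate = FALSE, lags = j * counts$bin_width, ac = ac,
         sample_variance = sigma2, mu1 = mu1, mu2 = mu2,
         bin_width = counts$bin_width, n_bins = n, unit_id = counts$unit_id),
    class = "spike_acf"
  )
}

#' @export
print.spike_acf <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<spike_acf> degenerate (zero-variance counts)\n")
  } else {
    cat(sprintf("<spike_acf> unit %s: %d lags of %.0f ms, AC(0)=%.4f\n",
                x$unit_id, length(x$lags), x$bin_width * 1e3, x$ac[1L]))
  }
  invisible(x)
}

#' Locate the lag at which the autocorrelation starts to decay
#'
#' Some neurons show refractory-like dips at the first lags; fitting
#' starts at the earliest lag from which the autocorrelation decays,
#' operationalized as the argmax of AC over lags `1..search_horizon`.
#' Neurons whose autocorrelation decays monotonically return lag 1.
#'
#' @param ac a [autocorrelation()] result.
#' @param search_horizon number of lags to search (default 20, i.e.
#'   100 ms at 5 ms bins).
#' @return integer lag index (1-based, lag 0 excluded).
#' @export
find_fit_start <- function(ac, search_horizon = 20L) {
  stopifnot(inherits(ac, "spike_acf"), !isTRUE(ac$degenerate))
  search_horizon <- max(1L, as.integer(search_horizon))
  h <- min(search_horizon, length(ac$ac) - 1L)
  which.max(ac$ac[1L + seq_len(h)])
}

.mixture_predict <- function(par, t, M) {
  cc <- par[seq_len(M)]
  tau <- par[M + seq_len(M)]
  drop(exp(-outer(t, 1 / tau)) %*% cc)
}

#' Fit a mixture of exponential decays to an autocorrelogram
#'
#' Fits \eqn{AC(t) = \sum_{i=1}^{M} c_i e^{-t/\tau_i}} by nonlinear least
#' squares in linear AC space (unweighted), over lags from `start_lag` up
#' to `max_lag_fit`. Timescales are bounded in `[bin_width, tau_max]` and
#' coefficients are nonnegative. Ten multi-start initializations are used
#' with log-spaced timescales; the best converged run is kept.
#'
#' `tau_max` defaults to the fitted lag extent: decay constants longer
#' than the fitted window are not identifiable from it, and leaving them
#' unbounded lets noise drive unidentifiable fits to arbitrarily slow
#' values, inflating the slow tail of a population's estimates.
#'
#' The BIC reported is the least-squares form
#' `n*log(RSS/n) + k*log(n)` with `k = 2M` free parameters over the `n`
#' fitted lags.
#'
#' @param ac a [autocorrelation()] result.
#' @param M number of exponential components (1-4).
#' @param start_lag first fitted lag index (from [find_fit_start()]).
#' @param max_lag_fit last fitted lag in seconds (default 5).
#' @param tau_max upper bound for timescales (seconds); defaults to
#'   `max_lag_fit`.
#' @param n_starts number of random initializations.
#' @param seed optional RNG seed for the multi-start draws.
#' @return object of class `exp_mixture_fit` with `M`, `taus` (ascending),
#'   `coeffs`, `bic`, `r_squared`, `start_lag`, `tau_eff`, `converged`.
#' @export
fit_exp_mixture <- function(ac, M, start_lag = 1L, max_lag_fit = 5,
                            tau_max = NULL, n_starts = 10L, seed = NULL) {
  stopifnot(inherits(ac, "spike_acf"), !isTRUE(ac$degenerate))
  M <- as.integer(M)
  if (M < 1L || M > 4L) stop("M must be between 1 and 4")
  if (!is.null(seed)) set.seed(seed)
  dt <- ac$bin_width
  if (is.null(tau_max)) tau_max <- max_lag_fit
  j_hi <- min(length(ac$ac) - 1L, floor(max_lag_fit / dt))
  idx <- (start_lag:j_hi) + 1L
  t_fit <- ac$lags[idx]
  y_fit <- ac$ac[idx]
  n <- length(y_fit)
  failed <- structure(
    list(M = M, taus = rep(NA_real_, M), coeffs = rep(NA_real_, M),
         bic = Inf, r_squared = -Inf, start_lag = start_lag,
         tau_eff = NA_real_, converged = FALSE, n_fit = n),
    class = "exp_mixture_fit"
  )
  if (n < 2L * M + 1L) return(failed)
  ss_tot <- sum((y_fit - mean(y_fit))^2)
  if (ss_tot <= 0) return(failed)

  amp0 <- max(y_fit[1L], 1e-3)
  lower <- c(rep(0, M), rep(dt, M))
  upper <- c(rep(Inf, M), rep(tau_max, M))
  best <- NULL
  for (s in seq_len(n_starts)) {
    tau0 <- if (s == 1L) {
      exp(seq(log(2 * dt), log(min(max_lag_fit, tau_max) / 2),
              length.out = M))
    } else {
      sort(exp(stats::runif(M, log(dt), log(min(max_lag_fit * 2, tau_max)))))
    }
    w <- stats::runif(M)
    c0 <- amp0 * w / sum(w)
    par0 <- c(c0, tau0)
    names(par0) <- c(paste0("c", seq_len(M)), paste0("tau", seq_len(M)))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = lower, upper = upper,
        fn = function(p) .mixture_predict(p, t_fit, M) - y_fit,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(failed)
  cc <- unname(best$par[seq_len(M)])
  tau <- unname(best$par[M + seq_len(M)])
  ord <- order(tau)
  tau <- tau[ord]; cc <- cc[ord]
  rss <- best$rss
  bic <- n * log(rss / n) + 2 * M * log(n)
  r2 <- 1 - rss / ss_tot
  tau_eff <- if (sum(cc) > 0) sum(cc * tau) / sum(cc) else NA_real_
  structure(
    list(M = M, taus = tau, coeffs = cc, bic = bic, r_squared = r2,
         start_lag = start_lag, tau_eff = tau_eff, converged = TRUE,
         n_fit = n),
    class = "exp_mixture_fit"
  )
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<exp_mixture_fit> M=%d: not converged\n", x$M))
  } else {
    cat(sprintf(
      "<exp_mixture_fit> M=%d: tau = %s s, c = %s, R2=%.3f, tau_eff=%.3f s\n",
      x$M, paste(signif(x$taus, 3), collapse = "/"),
      paste(signif(x$coeffs, 3), collapse = "/"), x$r_squared, x$tau_eff))
  }
  invisible(x)
}

#' Select the best mixture model by BIC with a 1 percent coefficient rule
#'
#' Chooses the converged fit with the lowest BIC (ties toward fewer
#' components), then demotes to the next-smaller model order whenever any
#' mixing coefficient contributes less than 1% of the total
#' (`c_i < 0.01 * sum(c)`), even if the larger model had the lower BIC.
#' The selected fit carries `qc_pass = (R2 > 0.5)`.
#'
#' @param fits list of [fit_exp_mixture()] results for M = 1..4.
#' @param min_coeff_frac minimum fractional contribution per component.
#' @return the selected `exp_mixture_fit` with `qc_pass` attached, or a
#'   `neurotau_exclusion` (see [is_excluded()]) when no fit survives.
#' @export
select_model <- function(fits, min_coeff_frac = 0.01) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) {
    return(.exclusion("no converged fit"))
  }
  ord <- order(vapply(fits, `[[`, 0, "bic"),
               vapply(fits, `[[`, 0L, "M"))
  fits <- fits[ord]
  by_m <- split(fits, vapply(fits, `[[`, 0L, "M"))
  ok <- function(f) {
    all(f$coeffs >= min_coeff_frac * sum(f$coeffs)) && sum(f$coeffs) > 0
  }
  cand <- fits[[1L]]
  while (!ok(cand)) {
    m_next <- cand$M - 1L
    cand <- NULL
    while (m_next >= 1L) {
      hit <- by_m[[as.character(m_next)]]
      if (!is.null(hit)) { cand <- hit[[1L]]; break }
      m_next <- m_next - 1L
    }
    if (is.null(cand)) {
      return(.exclusion("all models violate coefficient rule"))
    }
    if (cand$M == 1L) break
  }
  cand$qc_pass <- cand$r_squared > 0.5
  cand
}

#' Effective timescale of a mixture fit
#'
#' The coefficient-weighted mean of the fitted timescales,
#' \eqn{\tau_{eff} = \sum c_i \tau_i / \sum c_i}. The area under the
#' mixture over `[0, Inf)` equals `sum(c) * tau_eff`, so `tau_eff` is the
#' decay constant of the area-matched single exponential.
#'
#' @param fit an `exp_mixture_fit`.
#' @return effective timescale in seconds.
#' @export
effective_timescale <- function(fit) {
  stopifnot(inherits(fit, "exp_mixture_fit"))
  s <- sum(fit$coeffs)
  if (!isTRUE(s > 0)) stop("sum of mixing coefficients must be positive")
  sum(fit$coeffs * fit$taus) / s
}

#' Full per-neuron timescale estimation
#'
#' Runs the estimation chain for one spike train: bin counts, compute the
#' autocorrelogram, locate the fit start, fit mixtures with M = 1..4, and
#' select by BIC with the 1% coefficient rule. Set `single_exponential =
#' TRUE` for the conventional single-timescale pathway (M fixed at 1,
#' fit from the first lag, no quality control applied).
#'
#' @param train a [spike_train()].
#' @param bin_width count bin width in seconds.
#' @param max_lag autocorrelation extent in seconds.
#' @param search_horizon decay-onset search horizon in lags.
#' @param single_exponential fit only M = 1 from lag 1 (robustness
#'   pathway).
#' @param seed RNG seed for multi-start initializations.
#' @return the selected `exp_mixture_fit`, or a `neurotau_exclusion`
#'   carrying the reason when the neuron is excluded.
#' @export
estimate_timescales <- function(train, bin_width = 0.005, max_lag = 5,
                                search_horizon = 20L,
                                single_exponential = FALSE, seed = NULL) {
  bc <- bin_spikes(train, bin_width)
  ac <- autocorrelation(bc, max_lag)
  if (isTRUE(ac$degenerate)) {
    return(.exclusion("degenerate (zero-variance) count series"))
  }
  if (single_exponential) {
    fit <- fit_exp_mixture(ac, 1L, start_lag = 1L, max_lag_fit = max_lag,
                           seed = seed)
    if (!fit$converged) {
      return(.exclusion("single-exponential fit did not converge"))
    }
    fit$qc_pass <- NA
    return(fit)
  }
  start <- find_fit_start(ac, search_horizon)
  fits <- lapply(1:4, function(m) {
    fit_exp_mixture(ac, m, start_lag = start, max_lag_fit = max_lag,
                    seed = if (is.null(seed)) NULL else seed + m)
  })
  select_model(fits)
}
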