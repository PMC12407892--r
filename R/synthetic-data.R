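# stationary OU sample path on a regular grid via the exact AR(1) update
.ou_path <- function(n, dt, tau, sd) {
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1L, sd = sd)))
}

#' Doubly stochastic spike train with a mixture-of-exponentials
#' autocorrelation
#'
#' The firing rate is `rate(t) = max(0, r0 + sum_i y_i(t))` with
#' independent Ornstein-Uhlenbeck modulators `y_i` of time constant
#' `tau_i` and stationary standard deviation `a_i`; spikes are an
#' inhomogeneous Poisson process given the rate. Beyond lag zero the
#' spike-count autocorrelation is then (to first order, while
#' rectification is rare) a mixture of exponentials with the planted
#' timescales and weights proportional to `a_i^2`. Keeping
#' `sum(a_i) <= 0.5 * r0` keeps the rectified fraction small.
#'
#' @param base_rate baseline rate `r0` in Hz.
#' @param components data.frame (or list) with columns/fields `tau`
#'   (seconds) and `amplitude` (Hz, OU stationary sd).
#' @param duration recording length in seconds (default 600).
#' @param dt_sim rate simulation step (default 1 ms).
#' @param seed RNG seed.
#' @param unit_id unit identifier.
#' @return a [spike_train()]; attributes `rectified_fraction` and
#'   `components` carry the generator's ground truth. A warning is
#'   emitted when more than 20% of time points are rectified.
#' @export
gen_multiscale_spike_train <- function(base_rate, components = NULL,
                                       duration = 600, dt_sim = 0.001,
                                       seed = NULL, unit_id = "synth") {
  if (base_rate <= 0) stop("'base_rate' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt_sim)
  rate <- rep(base_rate, n)
  if (!is.null(components) && length(components) &&
      NROW(as.data.frame(components))) {
    comp <- as.data.frame(components)
    stopifnot(all(c("tau", "amplitude") %in% names(comp)))
    for (k in seq_len(nrow(comp))) {
      if (comp$amplitude[k] == 0) next
      rate <- rate + .ou_path(n, dt_sim, comp$tau[k], comp$amplitude[k])
    }
  } else {
    comp <- data.frame(tau = numeric(0), amplitude = numeric(0))
  }
  rect <- rate < 0
  rate[rect] <- 0
  if (mean(rect) > 0.2) {
    warning(sprintf("%.0f%% of time rectified; count autocorrelation will be distorted",
                    100 * mean(rect)))
  }
  counts <- stats::rpois(n, rate * dt_sim)
  idx <- rep.int(seq_len(n), counts)
  times <- sort((idx - 1L) * dt_sim + stats::runif(length(idx)) * dt_sim)
  out <- spike_train(times, duration, unit_id)
  attr(out, "rectified_fraction") <- mean(rect)
  attr(out, "components") <- comp
  out
}

#' Population of spike trains with planted timescales
#'
#' Each neuron receives a single planted timescale drawn from a power
#' law (or taken from a fixed list) and a doubly stochastic spike train
#' whose count autocorrelation decays with that timescale. The ground
#' truth is returned for recovery scoring.
#'
#' @param n_neurons number of neurons (ignored when `taus` is given).
#' @param gamma,theta power-law exponent and cutoff of the planted
#'   timescale distribution.
#' @param taus optional fixed vector of planted timescales.
#' @param base_rate baseline rate in Hz.
#' @param amplitude_frac OU modulation sd as a fraction of `base_rate`
#'   (default 0.5, the largest value that keeps rectification rare).
#' @param duration recording length in seconds.
#' @param seed RNG seed.
#' @return list with `trains` (list of [spike_train()]) and `truth`
#'   (data.frame `unit_id`, `tau`).
#' @export
gen_population <- function(n_neurons = 100L, gamma = 2, theta = 0.2,
                           taus = NULL, base_rate = 20,
                           amplitude_frac = 0.5, duration = 600,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taus)) {
    taus <- sample_power_law(n_neurons, gamma, theta)
  }
  n_neurons <- length(taus)
  ids <- sprintf("n%04d", seq_len(n_neurons))
  trains <- lapply(seq_len(n_neurons), function(i) {
    gen_multiscale_spike_train(
      base_rate,
      data.frame(tau = taus[i], amplitude = amplitude_frac * base_rate),
      duration = duration, unit_id = ids[i])
  })
  list(trains = trains, truth = data.frame(unit_id = ids, tau = taus))
}

#' Trial table with block structure
#'
#' Emulates a visual two-alternative task in which the stimulus-side
#' prior alternates between blocks: 80/20 in right blocks and 20/80 in
#' left blocks, with block lengths uniform between 20 and 100 trials.
#' Contrast is drawn uniformly from 100, 25, 12.5, 6 or 0 percent. The
#' simulated agent reports the stimulus side with probability
#' `accuracy` (otherwise the opposite side); reward is delivered exactly
#' when the reported side matches the stimulus. The recorded `choice`
#' variable is the direction of the first wheel movement, which agrees
#' with the reported side with probability `movement_consistency`: mice
#' sometimes reverse an initial movement, and without this distinction
#' the triple (stimulus, choice, reward) would be exactly collinear and
#' the stratified selectivity test for stimulus would have no usable
#' strata. Event times are laid out at a fixed trial spacing: stimulus
#' onset, first movement 350 ms later, feedback 500 ms after onset.
#'
#' @param n_trials number of trials.
#' @param block_len_range inclusive block length bounds (default 20-100).
#' @param p_side probability of a right-side stimulus in left and right
#'   blocks (default `c(0.2, 0.8)`).
#' @param contrasts contrast levels in percent.
#' @param accuracy probability of a correct report.
#' @param movement_consistency probability that the first wheel movement
#'   matches the reported side (default 0.9).
#' @param trial_spacing seconds between consecutive stimulus onsets.
#' @param seed RNG seed.
#' @return data.frame with `trial`, `block_id`, `block_p_right`,
#'   `stimulus_side`, `contrast`, `choice`, `reward`, `t_stim`,
#'   `t_move`, `t_feedback`.
#' @export
gen_trial_table <- function(n_trials, block_len_range = c(20L, 100L),
                            p_side = c(0.2, 0.8),
                            contrasts = c(100, 25, 12.5, 6, 0),
                            accuracy = 0.8, movement_consistency = 0.9,
                            trial_spacing = 2, seed = NULL) {
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  block_id <- integer(0)
  p_right <- numeric(0)
  b <- 0L
  right_block <- stats::runif(1L) < 0.5
  while (length(block_id) < n_trials) {
    b <- b + 1L
    len <- sample(block_len_range[1L]:block_len_range[2L], 1L)
    block_id <- c(block_id, rep(b, len))
    p_right <- c(p_right, rep(if (right_block) p_side[2L] else p_side[1L], len))
    right_block <- !right_block
  }
  block_id <- block_id[seq_len(n_trials)]
  p_right <- p_right[seq_len(n_trials)]
  stimulus_side <- ifelse(stats::runif(n_trials) < p_right, "right", "left")
  contrast <- sample(contrasts, n_trials, replace = TRUE)
  flip <- function(side) ifelse(side == "right", "left", "right")
  correct <- stats::runif(n_trials) < accuracy
  report <- ifelse(correct, stimulus_side, flip(stimulus_side))
  reward <- ifelse(report == stimulus_side, "yes", "no")
  consistent <- stats::runif(n_trials) < movement_consistency
  choice <- ifelse(consistent, report, flip(report))
  t_stim <- (seq_len(n_trials) - 1L) * trial_spacing + 0.5
  data.frame(
    trial = seq_len(n_trials), block_id = block_id,
    block_p_right = p_right, stimulus_side = stimulus_side,
    contrast = contrast, choice = choice, reward = reward,
    t_stim = t_stim, t_move = t_stim + 0.35, t_feedback = t_stim + 0.5)
}

#' Per-trial spike counts with planted task effects and slow drift
#'
#' Generates Poisson spike counts whose mean is multiplied by a planted
#' effect for each task variable at its second level (right stimulus,
#' right choice, rewarded trial) and optionally by a slow multiplicative
#' drift (a log-OU process over the trial index) that correlates with
#' the task's block structure. With all effects at 1 the counts are
#' independent of the labels, which is the regime for type-I calibration
#' of the selectivity test.
#'
#' @param table a [gen_trial_table()] result.
#' @param base_mean expected count per trial at baseline.
#' @param effects named multipliers `c(stimulus=, choice=, reward=)`.
#' @param drift_sd stationary sd of the log-rate drift (0 disables).
#' @param drift_tau_trials drift time constant in trials.
#' @param seed RNG seed.
#' @return integer vector of per-trial counts.
#' @export
gen_trial_counts <- function(table, base_mean = 5,
                             effects = c(stimulus = 1, choice = 1,
                                         reward = 1),
                             drift_sd = 0, drift_tau_trials = 50,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  full <- c(stimulus = 1, choice = 1, reward = 1)
  full[names(effects)] <- effects
  effects <- full
  n <- nrow(table)
  mu <- rep(base_mean, n)
  mu <- mu * ifelse(table$stimulus_side == "right", effects[["stimulus"]], 1)
  mu <- mu * ifelse(table$choice == "right", effects[["choice"]], 1)
  mu <- mu * ifelse(table$reward == "yes", effects[["reward"]], 1)
  if (drift_sd > 0) {
    mu <- mu * exp(.ou_path(n, 1, drift_tau_trials, drift_sd))
  }
  stats::rpois(n, mu)
}

#' Session-long spike train with task-locked rate modulation
#'
#' Builds a piecewise-constant-rate Poisson spike train over the whole
#' session: baseline rate everywhere, multiplied inside each variable's
#' response window by the planted effect when the trial carries the
#' variable's second level. Use with [count_spikes_in_window()] for
#' end-to-end selectivity checks.
#'
#' @param table a [gen_trial_table()] result.
#' @param base_rate baseline rate in Hz.
#' @param effects named multipliers as in [gen_trial_counts()].
#' @param windows list of response windows (seconds, relative to the
#'   variable's event) with entries `stimulus`, `choice`, `reward`.
#' @param seed RNG seed.
#' @return a [spike_train()] spanning the session.
#' @export
gen_task_spike_train <- function(table, base_rate = 20,
                                 effects = c(stimulus = 1, choice = 1,
                                             reward = 1),
                                 windows = list(stimulus = c(0, 0.1),
                                                choice = c(-0.1, 0),
                                                reward = c(0, 0.2)),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  full <- c(stimulus = 1, choice = 1, reward = 1)
  full[names(effects)] <- effects
  effects <- full
  duration <- max(table$t_feedback) + 1
  # homogeneous baseline, thinned/boosted inside response windows
  events <- list(stimulus = table$t_stim, choice = table$t_move,
                 reward = table$t_feedback)
  level2 <- list(stimulus = table$stimulus_side == "right",
                 choice = table$choice == "right",
                 reward = table$reward == "yes")
  times <- sort(stats::runif(stats::rpois(1L, base_rate * duration),
                             0, duration))
  for (v in names(windows)) {
    eff <- effects[[v]]
    if (eff == 1) next
    ev <- events[[v]][level2[[v]]]
    lo <- ev + windows[[v]][1L]
    hi <- ev + windows[[v]][2L]
    extra_rate <- base_rate * (eff - 1)
    if (extra_rate > 0) {
      n_extra <- stats::rpois(length(ev), extra_rate * (hi - lo))
      add <- unlist(lapply(seq_along(ev), function(k) {
        stats::runif(n_extra[k], lo[k], hi[k])
      }))
      times <- sort(c(times, add))
    } else {
      # thinning for suppressive effects
      in_win <- rep(FALSE, length(times))
      for (k in seq_along(ev)) {
        in_win <- in_win | (times >= lo[k] & times < hi[k])
      }
      drop <- in_win & stats::runif(length(times)) > eff
      times <- times[!drop]
    }
  }
  times <- pmin(pmax(times, 0), duration)
  spike_train(times, duration, "task_synth")
}

# smooth Gaussian random field by spectral synthesis
.smooth_field <- function(dims, smoothness) {
  nv <- prod(dims)
  k <- lapply(dims, function(d) {
    f <- c(0:floor(d / 2), -(ceiling(d / 2) - 1):-1)[seq_len(d)] / d
    2 * pi * f
  })
  k2 <- outer(outer(k[[1L]]^2, k[[2L]]^2, `+`), k[[3L]]^2, `+`)
  amp <- (1 + k2)^(-smoothness / 2)
  z <- stats::fft(array(stats::rnorm(nv), dim = dims))
  field <- Re(stats::fft(amp * z, inverse = TRUE)) / nv
  as.numeric(scale(as.numeric(field)))
}

#' Synthetic voxel world with a planted feature-timescale relation
#'
#' Features are independent smooth Gaussian random fields (spectral
#' synthesis with amplitude `(1+|k|^2)^(-smoothness/2)`, standardized
#' per feature). Per-neuron log10 timescales are a planted linear map of
#' their voxel's features plus Gaussian noise; neurons are placed
#' several per voxel.
#'
#' @param dims grid dimensions, each at least 4.
#' @param n_features number of feature fields.
#' @param smoothness spectral falloff exponent (larger = smoother).
#' @param signal_beta coefficient vector of the planted map (length
#'   `n_features`; a scalar is applied to the first feature only).
#' @param noise_sd per-neuron noise sd on log10 tau.
#' @param n_neurons number of neurons to place.
#' @param intercept mean log10 timescale (default -0.5, i.e. ~0.3 s).
#' @param seed RNG seed.
#' @return list with `grid` (a [voxel_grid()]), `placements`
#'   (data.frame `unit_id`, `voxel`, `tau_eff`), and `truth`
#'   (`beta`, `signal_fraction` = planted variance fraction of log10
#'   tau).
#' @export
gen_voxel_world <- function(dims = c(8L, 8L, 8L), n_features = 10L,
                            smoothness = 2, signal_beta = 0,
                            noise_sd = 0.3, n_neurons = 400L,
                            intercept = -0.5, seed = NULL) {
  dims <- as.integer(dims)
  if (any(dims < 4L)) stop("each dimension must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  nv <- prod(dims)
  X <- vapply(seq_len(n_features), function(a) .smooth_field(dims, smoothness),
              numeric(nv))
  beta <- if (length(signal_beta) == 1L) {
    c(signal_beta, rep(0, n_features - 1L))
  } else {
    stopifnot(length(signal_beta) == n_features)
    as.numeric(signal_beta)
  }
  grid <- voxel_grid(X, dims)
  voxel <- sample.int(nv, n_neurons, replace = TRUE)
  signal <- drop(X %*% beta)[voxel]
  log_tau <- intercept + signal + stats::rnorm(n_neurons, sd = noise_sd)
  placements <- data.frame(unit_id = sprintf("n%04d", seq_len(n_neurons)),
                           voxel = voxel, tau_eff = 10^log_tau)
  sig_var <- stats::var(signal)
  list(grid = grid, placements = placements,
       truth = list(beta = beta,
                    signal_fraction = sig_var / (sig_var + noise_sd^2)))
}
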