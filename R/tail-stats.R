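#' Draw samples from a continuous power law
#'
#' Inverse-CDF sampling of the Pareto density
#' \eqn{p(x) = (\gamma-1)\theta^{\gamma-1} x^{-\gamma}} on
#' `[theta, Inf)`: `x = theta * (1-u)^(-1/(gamma-1))`.
#'
#' @param n number of draws.
#' @param gamma exponent, must exceed 1.
#' @param theta lower cutoff, positive.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`.
#' @export
sample_power_law <- function(n, gamma, theta = 1, seed = NULL) {
  if (gamma <= 1) stop("power-law exponent must exceed 1")
  if (theta <= 0) stop("cutoff 'theta' must be positive")
  if (!is.null(seed)) set.seed(seed)
  theta * (1 - stats::runif(n))^(-1 / (gamma - 1))
}

# closed-form continuous MLE for fixed cutoff
.plaw_mle <- function(x_tail, theta) {
  1 + length(x_tail) / sum(log(x_tail / theta))
}

# KS distance between sorted tail and the fitted truncated power law
.plaw_ks <- function(x_sorted, theta, gamma) {
  n <- length(x_sorted)
  fx <- 1 - (x_sorted / theta)^(1 - gamma)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  max(pmax(abs(emp_hi - fx), abs(emp_lo - fx)))
}

#' Fit a power-law tail with a KS-minimizing lower cutoff
#'
#' For each candidate cutoff taken from the ascending data values
#' (optionally decimated to every `decimate`-th order statistic), the
#' continuous maximum-likelihood exponent
#' \eqn{\hat\gamma = 1 + N_\theta / \sum \ln(x_i/\theta)} is computed on
#' the samples at or above the cutoff, together with the
#' Kolmogorov-Smirnov distance between the empirical tail and the fitted
#' truncated power law. The cutoff minimizing the KS distance is
#' selected; no upper cutoff is imposed.
#'
#' @param samples positive numeric values (e.g. effective timescales).
#' @param min_tail minimum number of samples required above any candidate
#'   cutoff (default 25).
#' @param decimate candidate grid stride: every `decimate`-th order
#'   statistic is a candidate cutoff (default 1 = all values).
#' @param theta optional fixed cutoff; skips the cutoff search.
#' @return object of class `power_law_fit`: `gamma`, `theta`, `n_tail`,
#'   `ks`, `ci_gamma` (normal-approximation 95% interval), `n_total`.
#' @export
fit_power_law <- function(samples, min_tail = 25L, decimate = 1L,
                          theta = NULL) {
  x <- sort(as.numeric(samples))
  x <- x[is.finite(x) & x > 0]
  n <- length(x)
  if (!is.null(theta)) {
    tail_x <- x[x >= theta]
    if (length(tail_x) < 2L) stop("too few samples above fixed cutoff")
    if (sum(log(tail_x / theta)) <= 0) {
      stop("degenerate tail: all samples at the cutoff")
    }
    g <- .plaw_mle(tail_x, theta)
    ks <- .plaw_ks(tail_x, theta, g)
    return(.plaw_result(g, theta, length(tail_x), ks, n))
  }
  if (n < min_tail) stop("need at least 'min_tail' samples")
  if (all(x == x[1L])) stop("degenerate input: all samples equal")
  # candidate cutoffs: order statistics keeping >= min_tail points above
  cand_idx <- seq.int(1L, n - min_tail + 1L, by = max(1L, as.integer(decimate)))
  log_x <- log(x)
  suffix <- rev(cumsum(rev(log_x)))  # suffix[i] = sum(log x[i..n])
  best <- NULL
  for (i in cand_idx) {
    th <- x[i]
    m <- n - i + 1L
    slog <- suffix[i] - m * log_x[i]
    if (slog <= 0) next  # all tail values equal the cutoff
    g <- 1 + m / slog
    ks <- .plaw_ks(x[i:n], th, g)
    if (is.null(best) || ks < best$ks) {
      best <- list(gamma = g, theta = th, n_tail = m, ks = ks)
    }
  }
  if (is.null(best)) stop("no valid cutoff candidate")
  .plaw_result(best$gamma, best$theta, best$n_tail, best$ks, n)
}

.plaw_result <- function(gamma, theta, n_tail, ks, n_total) {
  se <- (gamma - 1) / sqrt(n_tail)
  structure(
    list(gamma = gamma, theta = theta, n_tail = n_tail, ks = ks,
         ci_gamma = gamma + c(-1, 1) * stats::qnorm(0.975) * se,
         n_total = n_total),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> gamma = %.3f [%.3f, %.3f], theta = %.4g, N_theta = %d/%d, KS = %.4f\n",
    x$gamma, x$ci_gamma[1L], x$ci_gamma[2L], x$theta, x$n_tail, x$n_total,
    x$ks))
  invisible(x)
}

#' Bootstrap goodness of fit for a power-law tail
#'
#' Generates `n_boot` synthetic datasets of `N_theta` samples from the
#' fitted truncated power law, refits each with the same KS-minimizing
#' cutoff procedure, and reports the fraction of synthetic KS distances
#' at or above the observed one. Values above the conventional
#' conservative threshold of 0.1 mean the power-law hypothesis cannot be
#' ruled out.
#'
#' @param fit a [fit_power_law()] result.
#' @param n_boot number of synthetic datasets (>= 1).
#' @param seed RNG seed.
#' @param decimate candidate-cutoff stride used in the refits.
#' @param min_tail minimum tail size in the refits.
#' @return list with `p_value`, `n_boot`, `threshold` (0.1) and the
#'   synthetic KS distances.
#' @export
bootstrap_gof <- function(fit, n_boot = 1000L, seed = NULL, decimate = 1L,
                          min_tail = 25L) {
  stopifnot(inherits(fit, "power_law_fit"))
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("'n_boot' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ks_syn <- vapply(seq_len(n_boot), function(b) {
    x <- sample_power_law(fit$n_tail, fit$gamma, fit$theta)
    f <- fit_power_law(x, min_tail = min(min_tail, fit$n_tail - 1L),
                       decimate = decimate)
    f$ks
  }, numeric(1L))
  list(p_value = mean(ks_syn >= fit$ks), n_boot = n_boot, threshold = 0.1,
       ks_synthetic = ks_syn)
}

# MLE of exponential on x >= theta: density lambda * exp(-lambda (x-theta))
.fit_exp_tail <- function(x, theta) {
  lambda <- 1 / (mean(x) - theta)
  list(
    lambda = lambda,
    logdens = function(z) log(lambda) - lambda * (z - theta)
  )
}

# MLE of log-normal restricted to x >= theta (truncated likelihood).
# The truncated log-normal can shadow a power-law tail with mu far below
# log(theta) and large sigma, so the likelihood surface is flat in that
# direction; multiple starts (including deep-mu ones) are needed for the
# optimizer to reach the supremum.
.fit_lnorm_tail <- function(x, theta) {
  lx <- log(x)
  lth <- log(theta)
  nll <- function(p) {
    mu <- p[1L]; sig <- exp(p[2L])
    log_tail <- stats::pnorm(lth, mu, sig, lower.tail = FALSE, log.p = TRUE)
    if (!is.finite(log_tail)) return(1e10)
    val <- -sum(stats::dlnorm(x, mu, sig, log = TRUE)) +
      length(x) * log_tail
    if (!is.finite(val)) 1e10 else val
  }
  s0 <- max(stats::sd(lx), 1e-3)
  starts <- list(c(mean(lx), log(s0)),
                 c(lth - 1, log(1)),
                 c(lth - 5, log(2.5)),
                 c(lth - 20, log(5)),
                 c(lth - 80, log(10)))
  opt <- NULL
  for (p0 in starts) {
    o <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  mu <- opt$par[1L]; sig <- exp(opt$par[2L])
  log_tail <- stats::pnorm(log(theta), mu, sig, lower.tail = FALSE,
                           log.p = TRUE)
  list(
    mu = mu, sigma = sig,
    logdens = function(z) stats::dlnorm(z, mu, sig, log = TRUE) - log_tail
  )
}

#' Likelihood-ratio comparison of a power-law tail against alternatives
#'
#' Fits the power law (fixed cutoff `theta`), the exponential, and the
#' log-normal to the samples at or above `theta` by maximum likelihood,
#' and for each alternative computes the raw log-likelihood ratio
#' \eqn{R_0 = \ln[L(power law)/L(alt)]} and the normalized ratio
#' \eqn{R = R_0 / (\sqrt{N} \sigma_{R_0})}, where \eqn{\sigma_{R_0}} is
#' the standard deviation of the pointwise log-likelihood differences.
#' Significance is a two-sided normal test on `R`; positive `R` favors
#' the power law.
#'
#' @param samples numeric values; only those `>= theta` are used.
#' @param theta tail cutoff.
#' @param alternatives subset of `c("exponential", "lognormal")`.
#' @param alpha significance level for the normal test (default 0.05).
#' @return list of `llr_result` objects (one per alternative), each with
#'   `alternative`, `r0`, `r_norm`, `sigma_r0`, `p_value`, `significant`.
#' @export
compare_distributions <- function(samples, theta,
                                  alternatives = c("exponential", "lognormal"),
                                  alpha = 0.05) {
  alternatives <- match.arg(alternatives, several.ok = TRUE)
  x <- as.numeric(samples)
  x <- x[is.finite(x) & x >= theta]
  n <- length(x)
  if (n < 3L) stop("too few tail samples for model comparison")
  gamma <- .plaw_mle(x, theta)
  ll_pl <- log(gamma - 1) - log(theta) - gamma * log(x / theta)
  lapply(alternatives, function(alt) {
    alt_fit <- switch(alt,
      exponential = .fit_exp_tail(x, theta),
      lognormal = .fit_lnorm_tail(x, theta)
    )
    d <- ll_pl - alt_fit$logdens(x)
    r0 <- sum(d)
    sigma <- stats::sd(d)
    if (!isTRUE(sigma > 0)) {
      return(structure(
        list(alternative = alt, r0 = r0, r_norm = NA_real_, sigma_r0 = sigma,
             p_value = NA_real_, significant = NA, degenerate = TRUE),
        class = "llr_result"))
    }
    r_norm <- r0 / (sqrt(n) * sigma)
    p <- 2 * stats::pnorm(-abs(r_norm))
    structure(
      list(alternative = alt, r0 = r0, r_norm = r_norm, sigma_r0 = sigma,
           p_value = p, significant = p < alpha, degenerate = FALSE),
      class = "llr_result")
  })
}

#' @export
print.llr_result <- function(x, ...) {
  cat(sprintf("<llr_result> vs %s: R0 = %.3f, R = %.3f, p = %.3g%s\n",
              x$alternative, x$r0, x$r_norm, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Percentile rank of the power-law cutoff within a sample
#'
#' The percentage of samples strictly below the cutoff; samples below the
#' cutoff are classified as fast, those at or above as slow.
#'
#' @param samples numeric values.
#' @param theta cutoff.
#' @return list with `percentile`, and the `fast`/`slow` partition.
#' @export
cutoff_percentile <- function(samples, theta) {
  x <- as.numeric(samples)
  if (!length(x)) stop("'samples' must be nonempty")
  list(percentile = 100 * mean(x < theta),
       fast = x[x < theta], slow = x[x >= theta])
}

#' Control simulation for LLR significance under a true power law
#'
#' Repeatedly samples datasets from a genuine power law, fits the tail
#' with the KS-minimizing cutoff, fits a log-normal on the same tail, and
#' computes the normalized log-likelihood ratio with its two-sided normal
#' significance. Under a true power law with moderate tail counts the
#' significant count stays in the low single digits per 1,000 datasets
#' and most non-significant ratios are slightly negative (the log-normal
#' has an extra parameter).
#'
#' @param n_datasets number of simulated datasets.
#' @param n_tail samples per dataset.
#' @param gamma true exponent.
#' @param theta true cutoff.
#' @param decimate candidate-cutoff stride for speed.
#' @param seed RNG seed.
#' @param alpha significance level.
#' @return list with `n_significant`, `n_negative` (count of negative
#'   normalized LLRs), `r_norm` (all normalized ratios), `p_values`.
#' @export
llr_control_simulation <- function(n_datasets, n_tail = 1000L, gamma = 2,
                                   theta = 1, decimate = 10L, seed = NULL,
                                   alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 1L) {
    return(list(n_significant = 0L, n_negative = 0L,
                r_norm = numeric(0), p_values = numeric(0)))
  }
  r_norm <- numeric(n_datasets)
  p_values <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    x <- sample_power_law(n_tail, gamma, theta)
    f <- fit_power_law(x, decimate = decimate)
    res <- compare_distributions(x, f$theta, alternatives = "lognormal",
                                 alpha = alpha)[[1L]]
    r_norm[i] <- res$r_norm
    p_values[i] <- res$p_value
  }
  sig <- p_values < alpha
  list(n_significant = sum(sig, na.rm = TRUE),
       n_negative = sum(r_norm < 0, na.rm = TRUE),
       r_norm = r_norm, p_values = p_values)
}

#' Pooled cutoff across groups
#'
#' When pooling samples from several groups whose individual power-law
#' cutoffs differ, the maximum group cutoff is used, so the pooled tail
#' is consistent with a power law within every group.
#'
#' @param fits list of [fit_power_law()] results (one per group).
#' @return the maximum cutoff.
#' @export
pooled_cutoff <- function(fits) {
  stopifnot(length(fits) >= 1L)
  max(vapply(fits, `[[`, 0, "theta"))
}
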