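#' Count spikes in a window around task events
#'
#' For each event time, counts spikes in the half-open window
#' `[event + window[1], event + window[2])`. Trials whose event time is
#' missing (`NA`) get an `NA` count and are reported in the `dropped`
#' attribute.
#'
#' @param train a [spike_train()].
#' @param events numeric vector of event times (seconds), `NA` allowed.
#' @param window length-2 numeric, window relative to the event in
#'   seconds, `window[1] < window[2]` (e.g. `c(0, 0.1)` for 0-100 ms).
#' @return integer vector of per-trial counts with attribute `dropped`
#'   (indices of missing-event trials).
#' @export
count_spikes_in_window <- function(train, events, window) {
  stopifnot(inherits(train, "spike_train"))
  if (length(window) != 2L || !(window[1L] < window[2L])) {
    stop("'window' must be c(a, b) with a < b")
  }
  st <- train$spike_times
  counts <- rep(NA_integer_, length(events))
  ok <- which(!is.na(events))
  if (length(ok)) {
    lo <- findInterval(events[ok] + window[1L], st, left.open = TRUE)
    hi <- findInterval(events[ok] + window[2L], st, left.open = TRUE)
    counts[ok] <- hi - lo
  }
  structure(counts, dropped = which(is.na(events)))
}

.task_columns <- c(stimulus = "stimulus_side", choice = "choice",
                   reward = "reward")

#' Stratify trials by the task variables held fixed
#'
#' When testing one task variable (stimulus, choice or reward), trials
#' are cross-classified by the values of the other two variables; the
#' resulting strata isolate the tested variable's influence. Strata in
#' which the tested variable does not take both values are unusable and
#' excluded downstream.
#'
#' @param table trial data.frame with columns `stimulus_side`, `choice`,
#'   `reward` (and `block_id` for permutation tests).
#' @param variable one of `"stimulus"`, `"choice"`, `"reward"`.
#' @return list with `labels` (factor, the tested variable),
#'   `strata` (factor of held-fixed combinations), `variable`.
#' @export
stratify_trials <- function(table, variable = c("stimulus", "choice",
                                                "reward")) {
  variable <- match.arg(variable)
  test_col <- .task_columns[[variable]]
  fixed_cols <- setdiff(unname(.task_columns), test_col)
  labels <- factor(table[[test_col]])
  strata <- interaction(table[fixed_cols], drop = TRUE, lex.order = TRUE)
  list(labels = labels, strata = strata, variable = variable)
}

# shuffle labels within each permutation cell; preserves each cell's
# (hence each block's) label counts exactly
.permute_within_cells <- function(labels, cell_idx) {
  out <- labels
  for (ix in cell_idx) {
    if (length(ix) > 1L) out[ix] <- labels[sample(ix)]
  }
  out
}

# per-stratum U = min(U1, U2) with average ranks for ties; returns the
# combined statistic P = sum_j U_j / sum_j n1_j n2_j over usable strata
.combined_u <- function(counts, labels01, strata_int, n_strata) {
  num <- 0
  den <- 0
  for (s in seq_len(n_strata)) {
    in_s <- strata_int == s
    lab <- labels01[in_s]
    n1 <- sum(lab == 1L)
    n2 <- sum(lab == 2L)
    if (n1 == 0L || n2 == 0L) next
    r <- rank(counts[in_s])
    r1 <- sum(r[lab == 1L])
    u1 <- r1 - n1 * (n1 + 1) / 2
    u <- min(u1, n1 * n2 - u1)
    num <- num + u
    den <- den + n1 * n2
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Condition-combined Mann-Whitney U statistic
#'
#' Within each stratum `j`, ranks of the per-trial spike counts give the
#' rank sums `R1`, `R2` of the two values of the tested variable and
#' `U_j = min(R1 - n1(n1+1)/2, R2 - n2(n2+1)/2)`. The combined statistic
#' is `P = sum_j U_j / sum_j n1_j * n2_j`, in `[0, 0.5]` with small values
#' indicating strong separation. Ties receive average ranks; strata with
#' only one label value are excluded from both sums.
#'
#' @param counts per-trial spike counts.
#' @param strat a [stratify_trials()] result (or a factor of strata, in
#'   which case `labels` must be supplied).
#' @param labels optional factor of tested-variable values per trial.
#' @return the combined probability statistic `P` (NA when no stratum is
#'   usable).
#' @export
combined_u_statistic <- function(counts, strat, labels = NULL) {
  if (is.list(strat)) {
    labels <- strat$labels
    strata <- strat$strata
  } else {
    strata <- as.factor(strat)
  }
  stopifnot(length(counts) == length(labels),
            length(counts) == length(strata))
  keep <- !is.na(counts) & !is.na(labels) & !is.na(strata)
  counts <- counts[keep]
  labels <- droplevels(factor(labels[keep]))
  strata <- droplevels(factor(strata[keep]))
  if (nlevels(labels) > 2L) stop("tested variable must be binary")
  .combined_u(counts, as.integer(labels), as.integer(strata),
              nlevels(strata))
}

#' Block-restricted permutation test of task-variable selectivity
#'
#' Computes the observed condition-combined U statistic `P`, then
#' permutes the tested variable's trial labels `n_perm` times within
#' cells defined by block identity crossed with the held-fixed task
#' variables. The within-block restriction removes spurious selectivity
#' driven by slow rate drifts that correlate with the block structure of
#' the task. The p-value is the fraction of permutations whose statistic
#' is more extreme (smaller) than the observed one; neurons with
#' `p < 0.05` are called selective.
#'
#' @param counts per-trial spike counts.
#' @param table trial data.frame with `stimulus_side`, `choice`,
#'   `reward`, `block_id`.
#' @param variable tested variable.
#' @param n_perm number of permutations (default 3000).
#' @param seed RNG seed.
#' @param alpha selectivity threshold (default 0.05).
#' @return object of class `selectivity_result`: `variable`, `p_stat`
#'   (observed P), `perm_p`, `selective`, `n_perm`, `n_trials_used`.
#' @export
permutation_test <- function(counts, table, variable = c("stimulus",
                                                         "choice", "reward"),
                             n_perm = 3000L, seed = NULL, alpha = 0.05) {
  variable <- match.arg(variable)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be positive")
  if (!is.null(seed)) set.seed(seed)
  strat <- stratify_trials(table, variable)
  keep <- !is.na(counts) & !is.na(strat$labels) & !is.na(strat$strata) &
    !is.na(table$block_id)
  counts <- as.numeric(counts[keep])
  labels <- droplevels(factor(strat$labels[keep]))
  strata <- droplevels(factor(strat$strata[keep]))
  block <- factor(table$block_id[keep])
  if (nlevels(labels) != 2L) {
    return(structure(
      list(variable = variable, p_stat = NA_real_, perm_p = NA_real_,
           selective = NA, n_perm = n_perm, n_trials_used = length(counts),
           degenerate = TRUE),
      class = "selectivity_result"))
  }
  labels01 <- as.integer(labels)
  strata_int <- as.integer(strata)
  n_strata <- nlevels(strata)
  p_obs <- .combined_u(counts, labels01, strata_int, n_strata)
  if (is.na(p_obs)) {
    return(structure(
      list(variable = variable, p_stat = NA_real_, perm_p = NA_real_,
           selective = NA, n_perm = n_perm, n_trials_used = length(counts),
           degenerate = TRUE),
      class = "selectivity_result"))
  }
  # permutation cells: block x held-fixed variables
  cells <- interaction(block, strata, drop = TRUE)
  cell_idx <- split(seq_along(counts), cells)
  p_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lab_perm <- .permute_within_cells(labels01, cell_idx)
    p_perm[b] <- .combined_u(counts, lab_perm, strata_int, n_strata)
  }
  perm_p <- mean(p_perm < p_obs, na.rm = TRUE)
  structure(
    list(variable = variable, p_stat = p_obs, perm_p = perm_p,
         selective = perm_p < alpha, n_perm = n_perm,
         n_trials_used = length(counts), degenerate = FALSE,
         p_perm_distribution = p_perm),
    class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> %s: P = %.4f, perm p = %.4f (%s)\n",
              x$variable, x$p_stat, x$perm_p,
              if (isTRUE(x$selective)) "selective" else "non-selective"))
  invisible(x)
}

#' Compare timescales of selective and non-selective neurons
#'
#' Two-sided Wilcoxon rank-sum test of effective timescales between
#' selective and non-selective neurons, per group (e.g. brain
#' structure), with Benjamini-Hochberg correction across groups.
#'
#' @param tau_eff numeric effective timescales, one per neuron.
#' @param selective logical, one per neuron.
#' @param group optional grouping factor (e.g. brain structure); a single
#'   group when omitted.
#' @param fdr_alpha FDR level for the corrected decisions (default 0.01).
#' @return data.frame with one row per group: medians, n, raw p, BH
#'   adjusted p, significance flag.
#' @export
compare_selective_timescales <- function(tau_eff, selective, group = NULL,
                                         fdr_alpha = 0.01) {
  if (is.null(group)) group <- rep("all", length(tau_eff))
  group <- factor(group)
  rows <- lapply(levels(group), function(g) {
    in_g <- group == g & !is.na(tau_eff) & !is.na(selective)
    sel <- tau_eff[in_g & selective]
    non <- tau_eff[in_g & !selective]
    p <- if (length(sel) >= 1L && length(non) >= 1L) {
      stats::wilcox.test(sel, non, alternative = "two.sided", exact = FALSE)$p.value
    } else NA_real_
    data.frame(group = g, n_selective = length(sel),
               n_nonselective = length(non),
               median_selective = stats::median(sel),
               median_nonselective = stats::median(non),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < fdr_alpha
  out
}
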