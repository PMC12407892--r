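#' Write spike trains to a two-column TSV
#'
#' Columns `unit_id` and `spike_time_s`, one row per spike.
#'
#' @param trains a [spike_train()] or list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_spike_tsv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$spike_times)) return(NULL)
    data.frame(unit_id = tr$unit_id, spike_time_s = tr$spike_times)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read spike trains from a two-column TSV
#'
#' @param path TSV with columns `unit_id`, `spike_time_s`.
#' @param duration recording duration (seconds); defaults to the last
#'   spike time rounded up to the next second.
#' @return named list of [spike_train()] objects.
#' @export
read_spike_tsv <- function(path, duration = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "spike_time_s") %in% names(df))) {
    stop("spike TSV must have columns 'unit_id' and 'spike_time_s'")
  }
  if (is.null(duration)) duration <- ceiling(max(df$spike_time_s))
  split_times <- split(df$spike_time_s, df$unit_id)
  out <- lapply(names(split_times), function(id) {
    spike_train(split_times[[id]], duration, id)
  })
  names(out) <- names(split_times)
  out
}

#' Write / read a trial table CSV
#'
#' @param table a trial data.frame (see [gen_trial_table()]).
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_trial_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-neuron timescale table
#'
#' Runs [estimate_timescales()] on each train and assembles the standard
#' per-neuron output table: model order, up to four timescales and
#' coefficients, fit quality and the effective timescale. Excluded
#' neurons appear with `NA` estimates and the exclusion reason.
#'
#' @param trains list of [spike_train()] objects.
#' @param ... passed to [estimate_timescales()].
#' @return data.frame with columns `unit_id`, `M`, `tau_1..tau_4`,
#'   `c_1..c_4`, `r2`, `tau_eff`, `qc_pass`, `reason`.
#' @export
fit_timescale_table <- function(trains, ...) {
  rows <- lapply(trains, function(tr) {
    fit <- estimate_timescales(tr, ...)
    row <- data.frame(unit_id = tr$unit_id, M = NA_integer_,
                      tau_1 = NA_real_, tau_2 = NA_real_, tau_3 = NA_real_,
                      tau_4 = NA_real_, c_1 = NA_real_, c_2 = NA_real_,
                      c_3 = NA_real_, c_4 = NA_real_, r2 = NA_real_,
                      tau_eff = NA_real_, qc_pass = NA,
                      reason = NA_character_)
    if (is_excluded(fit)) {
      row$reason <- fit$reason
      return(row)
    }
    row$M <- fit$M
    row[paste0("tau_", seq_len(fit$M))] <- as.list(fit$taus)
    row[paste0("c_", seq_len(fit$M))] <- as.list(fit$coeffs)
    row$r2 <- fit$r_squared
    row$tau_eff <- fit$tau_eff
    row$qc_pass <- fit$qc_pass
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tail-fit report for a timescale sample
#'
#' Combines the power-law fit, bootstrap goodness of fit, cutoff
#' percentile, and likelihood-ratio comparisons into a single
#' JSON-serializable report.
#'
#' @param samples positive values (e.g. effective timescales).
#' @param n_boot bootstrap datasets (0 disables the GOF test).
#' @param decimate candidate-cutoff stride.
#' @param seed RNG seed.
#' @return list with `gamma`, `theta`, `n_tail`, `ks`, `ci_gamma`,
#'   `cutoff_percentile`, `p_boot`, `llr` (per alternative).
#' @export
tail_report <- function(samples, n_boot = 200L, decimate = 1L, seed = NULL) {
  fit <- fit_power_law(samples, decimate = decimate)
  p_boot <- if (n_boot > 0L) {
    bootstrap_gof(fit, n_boot = n_boot, seed = seed,
                  decimate = decimate)$p_value
  } else NA_real_
  llr <- compare_distributions(samples, fit$theta)
  list(
    gamma = fit$gamma, theta = fit$theta, n_tail = fit$n_tail,
    ks = fit$ks, ci_gamma = fit$ci_gamma,
    cutoff_percentile = cutoff_percentile(samples, fit$theta)$percentile,
    p_boot = p_boot,
    llr = lapply(llr, function(l) l[c("alternative", "r0", "r_norm",
                                      "p_value", "significant")]))
}

#' End-to-end population analysis
#'
#' Composes the analysis stages over a per-neuron timescale table:
#' per-group medians and interquartile ranges, a power-law tail fit per
#' group (with bootstrap goodness of fit and likelihood-ratio
#' comparisons), a pooled fit across groups using the maximum group
#' cutoff, and, when selectivity flags are supplied, two-sided Wilcoxon
#' comparisons of timescales between selective and non-selective neurons
#' with Benjamini-Hochberg correction across groups.
#'
#' @param timescales data.frame with at least `tau_eff` (seconds) and
#'   optionally `qc_pass`; rows failing QC are dropped.
#' @param group optional factor of group labels (e.g. brain structure).
#' @param selectivity optional data.frame with `variable` and logical
#'   `selective` per neuron (row-aligned with `timescales`).
#' @param n_boot bootstrap datasets per tail fit.
#' @param decimate candidate-cutoff stride.
#' @param min_group_n minimum neurons for a per-group tail fit.
#' @param seed RNG seed.
#' @param out optional path; the report is written there as JSON.
#' @return the report list.
#' @export
full_pipeline <- function(timescales, group = NULL, selectivity = NULL,
                          n_boot = 200L, decimate = 1L, min_group_n = 40L,
                          seed = 1L, out = NULL) {
  if (!NROW(timescales)) stop("empty timescale table")
  keep <- !is.na(timescales$tau_eff)
  if (!is.null(timescales$qc_pass)) keep <- keep & timescales$qc_pass %in% TRUE
  tau <- timescales$tau_eff[keep]
  if (!length(tau)) stop("no neurons pass quality control")
  group <- if (is.null(group)) factor(rep("all", length(tau))) else
    factor(group[keep])

  summaries <- lapply(levels(group), function(g) {
    x <- tau[group == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(group = g, n = length(x), median = q[2L], q25 = q[1L], q75 = q[3L])
  })

  fits <- list()
  for (g in levels(group)) {
    x <- tau[group == g]
    if (length(x) >= min_group_n) {
      fits[[g]] <- tail_report(x, n_boot = n_boot, decimate = decimate,
                               seed = seed)
    }
  }
  pooled <- NULL
  if (length(fits)) {
    theta_pool <- max(vapply(fits, `[[`, 0, "theta"))
    pooled_fit <- fit_power_law(tau, theta = theta_pool)
    pooled <- list(
      theta = theta_pool, gamma = pooled_fit$gamma,
      n_tail = pooled_fit$n_tail, ks = pooled_fit$ks,
      cutoff_percentile = cutoff_percentile(tau, theta_pool)$percentile)
  }

  sel_cmp <- NULL
  if (!is.null(selectivity)) {
    sel <- selectivity[keep, , drop = FALSE]
    sel_cmp <- lapply(split(seq_len(nrow(sel)), sel$variable), function(ix) {
      compare_selective_timescales(tau[ix], sel$selective[ix],
                                   group = group[ix])
    })
  }

  report <- list(n_neurons = length(tau), groups = summaries,
                 tail_fits = fits, pooled = pooled,
                 selectivity_comparisons = sel_cmp)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  report
}

.stage_schemas <- list(
  synth = c("stage", "out_dir", "n_neurons", "gamma", "theta", "duration",
            "base_rate", "seed"),
  `fit-acf` = c("stage", "spikes", "out_dir", "duration", "bin_width",
                "max_lag", "seed"),
  tailfit = c("stage", "samples", "out_dir", "n_boot", "decimate", "seed"),
  pipeline = c("stage", "timescales", "out_dir", "n_boot", "decimate",
               "seed")
)

#' Run one analysis stage from a configuration list
#'
#' Validates the configuration against the stage's schema (unknown keys
#' are an error), executes the stage, writes its artifacts into
#' `out_dir`, appends a JSON-lines run log (`run_log.jsonl`) recording
#' the parameters and seed, and returns the output paths.
#'
#' Stages: `synth` (write a synthetic population: spike TSV +
#' ground-truth CSV), `fit-acf` (spike TSV to per-neuron timescale CSV),
#' `tailfit` (sample CSV to JSON tail report), `pipeline` (timescale CSV
#' to JSON population report).
#'
#' @param config named list; must contain `stage` and `out_dir`.
#' @return named list of output paths, invisibly.
#' @export
run_stage <- function(config) {
  if (is.null(config$stage) || !config$stage %in% names(.stage_schemas)) {
    stop(sprintf("unknown or missing stage: %s",
                 if (is.null(config$stage)) "<none>" else config$stage))
  }
  schema <- .stage_schemas[[config$stage]]
  bad <- setdiff(names(config), schema)
  if (length(bad)) {
    stop(sprintf("invalid config key(s) for stage '%s': %s", config$stage,
                 paste(bad, collapse = ", ")))
  }
  if (is.null(config$out_dir)) stop("config must include 'out_dir'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  grab <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  outputs <- switch(config$stage,
    synth = {
      pop <- gen_population(
        n_neurons = grab("n_neurons", 50L), gamma = grab("gamma", 2),
        theta = grab("theta", 0.2), duration = grab("duration", 600),
        base_rate = grab("base_rate", 20), seed = seed)
      spikes <- file.path(config$out_dir, "spikes.tsv")
      truth <- file.path(config$out_dir, "ground_truth.csv")
      write_spike_tsv(pop$trains, spikes)
      utils::write.csv(pop$truth, truth, row.names = FALSE)
      list(spikes = spikes, ground_truth = truth)
    },
    `fit-acf` = {
      if (is.null(config$spikes) || !file.exists(config$spikes)) {
        stop("missing input: 'spikes'")
      }
      trains <- read_spike_tsv(config$spikes,
                               duration = grab("duration", NULL))
      tab <- fit_timescale_table(trains,
                                 bin_width = grab("bin_width", 0.005),
                                 max_lag = grab("max_lag", 5), seed = seed)
      path <- file.path(config$out_dir, "timescales.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      list(timescales = path)
    },
    tailfit = {
      if (is.null(config$samples) || !file.exists(config$samples)) {
        stop("missing input: 'samples'")
      }
      x <- utils::read.csv(config$samples)[[1L]]
      rep_ <- tail_report(x, n_boot = grab("n_boot", 200L),
                          decimate = grab("decimate", 1L), seed = seed)
      path <- file.path(config$out_dir, "tail_report.json")
      jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      list(tail_report = path)
    },
    pipeline = {
      if (is.null(config$timescales) || !file.exists(config$timescales)) {
        stop("missing input: 'timescales'")
      }
      tab <- utils::read.csv(config$timescales)
      path <- file.path(config$out_dir, "report.json")
      full_pipeline(tab, group = tab$group,
                    n_boot = grab("n_boot", 200L),
                    decimate = grab("decimate", 1L), seed = seed,
                    out = path)
      list(report = path)
    }
  )
  log_line <- jsonlite::toJSON(
    list(stage = config$stage, seed = seed, params = config,
         outputs = outputs,
         package_version = as.character(utils::packageVersion("neurotau")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    auto_unbox = TRUE)
  cat(log_line, "\n", sep = "",
      file = file.path(config$out_dir, "run_log.jsonl"), append = TRUE)
  invisible(outputs)
}
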