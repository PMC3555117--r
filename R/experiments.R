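#' Named synapse parameter conditions
#'
#' The two study conditions share the kinetic time constants
#' (`tau_in` = 1 ms, `tau_rec` = 50 ms, `tau_facil` = 200 ms) and differ only
#' in the initial release probability: `U` = 0.15 under control and
#' `U` = 0.36 under elevated amyloid-beta, the increase sufficient to
#' reproduce the experimentally observed change in EPSC train dynamics.
#'
#' @param condition `"control"` or `"abeta"`.
#' @param A Absolute synaptic strength passed through to [stp_params()].
#' @return An [stp_params()] object.
#' @export
condition_params <- function(condition = c("control", "abeta"), A = 1) {
  condition <- match.arg(condition)
  stp_params(U = if (condition == "control") 0.15 else 0.36,
             tau_in = 1, tau_rec = 50, tau_facil = 200, A = A)
}

# deterministic sub-seed derivation: mixes the master seed with a salt and an
# index, staying below 2^31 so the result is a valid integer seed
derive_seed <- function(master, salt, index) {
  as.integer((as.double(master) * 7919 + as.double(salt) * 104729 +
                as.double(index) * 1299709) %% 2147483629) + 1L
}

#' Experiment configuration
#'
#' Bundles everything an orchestrated experiment needs: the population and
#' neuron specification, trial count, pattern length and the master seed from
#' which all per-trial seeds are derived (see [derive_seed()] logic in the
#' result metadata: `seed_i = (7919 * master + 104729 * salt + 1299709 * i)
#' mod 2147483629 + 1`).
#'
#' @param n_synapses Model synapses per population (default 10).
#' @param multiplicity Real synapses per model synapse (default 15).
#' @param n_trials Trials per protocol (default 10; weights and attenuation
#'   are resampled each trial).
#' @param pattern_duration Naturalistic pattern length, s (default 60; the
#'   full-session length of 600 s is available by configuration).
#' @param master_seed Master seed (integer).
#' @param dist A [weight_distribution()].
#' @param neuron A [neuron_params()].
#' @param sample_step Integration step for free-running simulations, ms.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_synapses = 10, multiplicity = 15,
                              n_trials = 10, pattern_duration = 60,
                              master_seed = 1,
                              dist = weight_distribution(),
                              neuron = neuron_params(),
                              sample_step = 0.025) {
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (n_synapses < 1) stop("'n_synapses' must be >= 1", call. = FALSE)
  structure(list(n_synapses = n_synapses, multiplicity = multiplicity,
                 n_trials = n_trials, pattern_duration = pattern_duration,
                 master_seed = as.integer(master_seed), dist = dist,
                 neuron = neuron, sample_step = sample_step),
            class = "experiment_config")
}

aggregate_by <- function(df, value_col, by_cols) {
  agg <- stats::aggregate(df[[value_col]], df[by_cols], function(v)
    c(mean = mean(v), sem = sem(v)))
  out <- cbind(agg[by_cols], mean = agg$x[, "mean"], sem = agg$x[, "sem"])
  out[do.call(order, out[by_cols]), , drop = FALSE]
}

#' Model validation: five pulses at 100 Hz under both conditions
#'
#' Runs the voltage-clamp protocol used to validate the synapse model —
#' five presynaptic stimuli at 100 Hz, soma held at -70 mV — for the control
#' and the increased-release-probability condition, and reports per-pulse
#' normalized EPSC amplitudes. Under control the train facilitates
#' throughout; under elevated release probability the second pulse still
#' facilitates but later pulses depress below the first.
#'
#' @param config An [experiment_config()].
#' @param n_pulses,frequency Protocol (defaults 5 pulses, 100 Hz).
#' @return A list of class `experiment_result` with `per_trial` (long data
#'   frame: condition, trial, pulse, normalized), `aggregate`
#'   (condition, pulse, mean, sem) and `config`.
#' @export
run_validation <- function(config = experiment_config(), n_pulses = 5,
                           frequency = 100) {
  rows <- list()
  for (cond in c("control", "abeta")) {
    pars <- condition_params(cond)
    for (tr in seq_len(config$n_trials)) {
      pop <- synapse_population(n = config$n_synapses, params = pars,
                                dist = config$dist,
                                multiplicity = config$multiplicity,
                                seed = derive_seed(config$master_seed, 1, tr))
      clamp <- run_voltage_clamp(pop, constant_train(frequency, n_pulses),
                                 hold = config$neuron$clamp_potential,
                                 reversal = config$neuron$synaptic_reversal)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, trial = tr, pulse = seq_len(n_pulses),
                   amplitude = clamp$pulse_peaks,
                   normalized = clamp$normalized)
    }
  }
  per_trial <- do.call(rbind, rows)
  structure(list(per_trial = per_trial,
                 aggregate = aggregate_by(per_trial, "normalized",
                                          c("condition", "pulse")),
                 config = config),
            class = "experiment_result")
}

#' Frequency sweep of short-term plasticity
#'
#' Ten-pulse voltage-clamp trains across a range of stimulation frequencies
#' for both conditions, reporting mean and SEM of the normalized EPSC
#' amplitudes over trials. Captures the transition from facilitation at low
#' frequencies to depression at high frequencies, which the elevated release
#' probability shifts toward lower frequencies.
#'
#' @param config An [experiment_config()].
#' @param frequencies Stimulation frequencies, Hz; values outside
#'   \[5, 200\] are allowed with a warning.
#' @param n_pulses Pulses per train (default 10).
#' @return An `experiment_result` with `per_trial` (condition, frequency,
#'   trial, pulse, normalized) and `aggregate`.
#' @export
run_frequency_sweep <- function(config = experiment_config(),
                                frequencies = c(5, 10, 40, 80, 100, 150, 200),
                                n_pulses = 10) {
  if (any(frequencies < 5 | frequencies > 200))
    warning("frequencies outside the characterised 5-200 Hz range")
  rows <- list()
  for (cond in c("control", "abeta")) {
    pars <- condition_params(cond)
    for (f in frequencies) {
      for (tr in seq_len(config$n_trials)) {
        pop <- synapse_population(n = config$n_synapses, params = pars,
                                  dist = config$dist,
                                  multiplicity = config$multiplicity,
                                  seed = derive_seed(config$master_seed, 2, tr))
        clamp <- run_voltage_clamp(pop, constant_train(f, n_pulses),
                                   hold = config$neuron$clamp_potential,
                                   reversal = config$neuron$synaptic_reversal)
        rows[[length(rows) + 1L]] <-
          data.frame(condition = cond, frequency = f, trial = tr,
                     pulse = seq_len(n_pulses), normalized = clamp$normalized)
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  structure(list(per_trial = per_trial,
                 aggregate = aggregate_by(per_trial, "normalized",
                                          c("condition", "frequency", "pulse")),
                 config = config),
            class = "experiment_result")
}

#' Spike probability versus synaptic weight, with sigmoid fits
#'
#' Free-running simulations against naturalistic drive over a range of
#' uniform weight multipliers, for both conditions, in synchronous or
#' asynchronous (jittered) activation mode. Spike probability per scale is
#' averaged over trials (weights resampled each trial) and patterns, and each
#' condition's curve is fitted with the sigmoid
#' `y = a / (1 + b exp(-c x))` against the mean peak conductance.
#'
#' @param config An [experiment_config()].
#' @param weight_scales Uniform multipliers applied to the sampled weights
#'   (>= 5 values spanning sub- to supra-threshold drive).
#' @param sync `"synchronous"` (all synapses receive each pattern event at
#'   the same time) or `"asynchronous"` (independent per-event delays in
#'   `jitter_range`).
#' @param patterns Optional list of [spike_train()] drive patterns; defaults
#'   to the five shipped generator patterns at `config$pattern_duration`.
#' @param jitter_range Delay range for the asynchronous mode, ms.
#' @param a_fixed Optional fixed sigmoid asymptote (percent).
#' @return An `experiment_result` with `per_trial` (condition, scale,
#'   pattern, trial, conductance, spike_probability), `aggregate`, and `fits`
#'   (a `sigmoid_fit` per condition, `NULL` if the fit is degenerate).
#' @export
run_weight_sweep <- function(config = experiment_config(),
                             weight_scales = c(0.25, 0.5, 1, 2, 4, 8),
                             sync = c("synchronous", "asynchronous"),
                             patterns = NULL, jitter_range = c(0, 9),
                             a_fixed = NULL) {
  sync <- match.arg(sync)
  if (length(weight_scales) < 5)
    stop("provide at least 5 weight scales", call. = FALSE)
  if (is.null(patterns))
    patterns <- ca3_fixture_patterns(duration = config$pattern_duration)
  rows <- list()
  for (cond in c("control", "abeta")) {
    pars <- condition_params(cond)
    for (sc in weight_scales) {
      for (k in seq_along(patterns)) {
        times_ms <- patterns[[k]]$times * 1000
        n_stim <- length(times_ms)
        for (tr in seq_len(config$n_trials)) {
          pop <- synapse_population(n = config$n_synapses, params = pars,
                                    dist = config$dist,
                                    multiplicity = config$multiplicity,
                                    seed = derive_seed(config$master_seed, 3,
                                                       tr))
          pop$weights <- pop$weights * sc
          ev <- if (sync == "synchronous") times_ms
          else jitter_events(times_ms, config$n_synapses, jitter_range,
                             seed = derive_seed(config$master_seed, 4,
                                                tr * 1000 + k))
          run <- run_free(pop, ev, config$neuron,
                          sample_step = config$sample_step)
          rows[[length(rows) + 1L]] <-
            data.frame(condition = cond, scale = sc, pattern = k, trial = tr,
                       conductance = mean(pop$weights * pop$attenuation),
                       spike_probability =
                         spike_probability(run$n_spikes, n_stim))
        }
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  agg <- aggregate_by(per_trial, "spike_probability", c("condition", "scale"))
  gcond <- stats::aggregate(per_trial$conductance,
                            per_trial[c("condition", "scale")], mean)
  names(gcond)[3] <- "conductance"
  agg <- merge(agg, gcond, by = c("condition", "scale"))
  fits <- lapply(stats::setNames(nm = c("control", "abeta")), function(cond) {
    sub <- agg[agg$condition == cond, ]
    tryCatch(fit_sigmoid(sub$conductance, sub$mean, a_fixed = a_fixed),
             error = function(e) NULL)
  })
  structure(list(per_trial = per_trial, aggregate = agg, fits = fits,
                 sync = sync, config = config),
            class = "experiment_result")
}

#' Natural-pattern drive: output statistics per regime
#'
#' Drives the neuron synchronously with each naturalistic pattern, in both
#' conditions, at the weight scale of the requested regime, and reports per
#' pattern and trial: spike probability, output ISI CV, instantaneous
#' frequency histogram mass, and theta (4-8 Hz) / gamma (40-80 Hz) band
#' probabilities. Paired per-pattern condition comparisons (t-test after a
#' normality check; Kolmogorov-Smirnov on pooled instantaneous frequencies)
#' are included.
#'
#' @param config An [experiment_config()].
#' @param regime `"integrative"` or `"saturating"`.
#' @param scales Named list with per-regime weight multipliers as returned by
#'   [calibrate_regimes()] (entries may be the calibration lists or bare
#'   numbers). If `NULL`, calibration is run first on the control condition.
#' @param patterns Optional list of [spike_train()] patterns; defaults to the
#'   five shipped generator patterns at `config$pattern_duration`.
#' @param freq_bins Histogram bin edges, Hz.
#' @return An `experiment_result` with `per_trial`, `per_pattern` (trial
#'   means per pattern and condition), `aggregate`, `tests` (paired
#'   comparisons per metric and the distribution test), `scale` and `regime`.
#' @export
run_natural_drive <- function(config = experiment_config(),
                              regime = c("integrative", "saturating"),
                              scales = NULL, patterns = NULL,
                              freq_bins = c(0, 2, 4, 8, 16, 40, 80, 200)) {
  regime <- match.arg(regime)
  if (is.null(patterns))
    patterns <- ca3_fixture_patterns(duration = config$pattern_duration)
  if (is.null(scales))
    scales <- calibrate_regimes(patterns, condition_params("control"),
                                config$neuron, n_seeds = config$n_trials,
                                seed = config$master_seed,
                                n_synapses = config$n_synapses,
                                multiplicity = config$multiplicity,
                                dist = config$dist,
                                sample_step = config$sample_step)
  sc <- scales[[regime]]
  if (is.list(sc)) sc <- sc$scale
  rows <- list()
  freq_pool <- list(control = numeric(0), abeta = numeric(0))
  theta <- c(4, 8); gamma <- c(40, 80)
  for (cond in c("control", "abeta")) {
    pars <- condition_params(cond)
    for (k in seq_along(patterns)) {
      times_ms <- patterns[[k]]$times * 1000
      n_stim <- length(times_ms)
      for (tr in seq_len(config$n_trials)) {
        pop <- synapse_population(n = config$n_synapses, params = pars,
                                  dist = config$dist,
                                  multiplicity = config$multiplicity,
                                  seed = derive_seed(config$master_seed, 5, tr))
        pop$weights <- pop$weights * sc
        run <- run_free(pop, times_ms, config$neuron,
                        sample_step = config$sample_step)
        out_s <- run$spikes / 1000
        enough <- length(out_s) >= 3
        if (length(out_s) >= 2)
          freq_pool[[cond]] <- c(freq_pool[[cond]], 1 / diff(out_s))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, pattern = k, trial = tr,
          n_spikes = run$n_spikes,
          spike_probability = spike_probability(run$n_spikes, n_stim),
          isi_cv = if (enough) isi_cv(out_s) else NA_real_,
          theta_probability = if (enough) band_probability(out_s, theta)
          else NA_real_,
          gamma_probability = if (enough) band_probability(out_s, gamma)
          else NA_real_)
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  metrics <- c("spike_probability", "isi_cv", "theta_probability",
               "gamma_probability")
  per_pattern <- do.call(rbind, lapply(metrics, function(m) {
    ag <- stats::aggregate(per_trial[[m]], per_trial[c("condition", "pattern")],
                           mean, na.rm = TRUE)
    data.frame(metric = m, condition = ag$condition, pattern = ag$pattern,
               value = ag$x)
  }))
  tests <- lapply(stats::setNames(nm = metrics), function(m) {
    a <- per_pattern$value[per_pattern$metric == m &
                             per_pattern$condition == "abeta"]
    b <- per_pattern$value[per_pattern$metric == m &
                             per_pattern$condition == "control"]
    if (any(is.na(c(a, b)))) return(NULL)
    suppressWarnings(compare_conditions(a, b, "paired-mean"))
  })
  tests$frequency_distribution <-
    if (length(freq_pool$control) >= 3 && length(freq_pool$abeta) >= 3)
      compare_conditions(freq_pool$abeta, freq_pool$control, "distribution")
  else NULL
  aggregate <- do.call(rbind, lapply(metrics, function(m) {
    sub <- per_pattern[per_pattern$metric == m, ]
    ag <- aggregate_by(sub, "value", "condition")
    data.frame(metric = m, ag)
  }))
  structure(list(per_trial = per_trial, per_pattern = per_pattern,
                 aggregate = aggregate, tests = tests, scale = sc,
                 regime = regime, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result\n")
  if (!is.null(x$regime)) cat(sprintf("  regime: %s (weight scale %.3g)\n",
                                      x$regime, x$scale))
  cat(sprintf("  per-trial rows: %d\n", nrow(x$per_trial)))
  cat("  aggregate:\n")
  print(utils::head(x$aggregate, 20))
  invisible(x)
}
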