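#' Reduced CA1 surrogate neuron parameters
#'
#' A single-compartment conductance-based leaky integrate-and-fire cell
#' standing in for a morphologically detailed CA1 pyramidal neuron. Membrane
#' capacitance is implied by `membrane_time_constant * leak_conductance`
#' (pF). The cell runs either free (integrating synaptic conductances and
#' emitting spikes) or voltage-clamped (holding the soma, typically at
#' -70 mV, so the summed synaptic current can be read out directly).
#'
#' @param membrane_time_constant ms.
#' @param leak_conductance nS.
#' @param resting_potential,spike_threshold,reset_potential mV.
#' @param refractory_period Absolute refractory period, ms (> 0).
#' @param synaptic_reversal Excitatory synaptic reversal, mV.
#' @param adapt_increment Spike-triggered adaptation conductance step, nS
#'   (0 disables adaptation).
#' @param adapt_tau Adaptation decay time constant, ms.
#' @param adapt_reversal Adaptation (potassium-like) reversal, mV.
#' @param clamp_potential Holding potential in clamp mode, mV.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(membrane_time_constant = 20, leak_conductance = 10,
                          resting_potential = -70, spike_threshold = -54,
                          reset_potential = -65, refractory_period = 4,
                          synaptic_reversal = 0, adapt_increment = 4,
                          adapt_tau = 100, adapt_reversal = -90,
                          clamp_potential = -70) {
  if (refractory_period <= 0)
    stop("'refractory_period' must be positive", call. = FALSE)
  if (spike_threshold <= reset_potential)
    stop("'spike_threshold' must exceed 'reset_potential'", call. = FALSE)
  if (synaptic_reversal <= spike_threshold)
    stop("'synaptic_reversal' must exceed 'spike_threshold'", call. = FALSE)
  if (membrane_time_constant <= 0 || leak_conductance <= 0)
    stop("membrane time constant and leak conductance must be positive",
         call. = FALSE)
  if (adapt_increment < 0 || adapt_tau <= 0)
    stop("adaptation parameters must be non-negative (tau positive)",
         call. = FALSE)
  structure(list(membrane_time_constant = membrane_time_constant,
                 leak_conductance = leak_conductance,
                 resting_potential = resting_potential,
                 spike_threshold = spike_threshold,
                 reset_potential = reset_potential,
                 refractory_period = refractory_period,
                 synaptic_reversal = synaptic_reversal,
                 adapt_increment = adapt_increment, adapt_tau = adapt_tau,
                 adapt_reversal = adapt_reversal,
                 clamp_potential = clamp_potential),
            class = "neuron_params")
}

# normalise per-synapse input events into a list of ms vectors, one per synapse
as_event_list <- function(input_events, n_syn) {
  if (inherits(input_events, "spike_train"))
    input_events <- input_events$times * 1000
  if (is.numeric(input_events))
    input_events <- replicate(n_syn, input_events, simplify = FALSE)
  if (!is.list(input_events) || length(input_events) != n_syn)
    stop("'input_events' must be one event vector per synapse", call. = FALSE)
  lapply(input_events, function(ti) {
    if (inherits(ti, "spike_train")) ti <- ti$times * 1000
    check_spike_times_ms(ti, allow_empty = TRUE)
    ti
  })
}

#' Voltage-clamp recording of the summed synaptic current
#'
#' Holds the soma at `hold` and returns the total clamp current: the sum over
#' synapses of `weight_i * y_i(t) * (hold - synaptic_reversal)`, i.e. each
#' synapse contributes `A_i * y_i(t)` with `A_i` the weight times the driving
#' force. No spiking occurs in clamp mode, so the trace is an exact linear
#' superposition of the event-driven single-synapse solutions.
#'
#' @param population A [synapse_population()].
#' @param input_events A single event-time vector (ms) applied to every
#'   synapse, or a list with one vector per synapse (e.g. from
#'   [jitter_events()]).
#' @param hold Holding potential, mV.
#' @param sample_step Trace sampling step, ms.
#' @param reversal Synaptic reversal potential, mV.
#' @param inward If `TRUE` the returned current keeps the physical
#'   inward-negative sign; by default magnitudes are positive.
#' @return A list with `trace` (data frame `time` ms, `current` pA),
#'   `pulse_peaks` (per-pulse peak current summed over synapses; only when
#'   all synapses receive identical events, otherwise `NULL`) and
#'   `normalized` (pulse peaks over the first peak).
#' @export
run_voltage_clamp <- function(population, input_events, hold = -70,
                              sample_step = 0.025, reversal = 0,
                              inward = FALSE) {
  stopifnot(inherits(population, "synapse_population"))
  if (population$n < 1) stop("empty synapse population", call. = FALSE)
  events <- as_event_list(input_events, population$n)
  if (hold == reversal)
    stop("zero driving force: 'hold' must differ from 'reversal'",
         call. = FALSE)
  drive <- abs(hold - reversal)
  a_eff <- population$weights * population$attenuation * drive # pA at y = 1
  t_end <- max(c(unlist(events), 0)) + 8 * population$params$tau_in
  grid <- seq(0, t_end, by = sample_step)
  total <- numeric(length(grid))
  props <- vector("list", population$n)
  for (i in seq_len(population$n)) {
    ti <- events[[i]]
    if (!length(ti)) next
    props[[i]] <- stp_propagate(population$params, ti)
    idx <- findInterval(grid, ti)
    live <- idx > 0
    y <- numeric(length(grid))
    y[live] <- props[[i]]$y_post[idx[live]] *
      exp(-(grid[live] - ti[idx[live]]) / population$params$tau_in)
    total <- total + a_eff[i] * y
  }
  identical_events <- length(events) >= 1 &&
    all(vapply(events, function(e) identical(e, events[[1]]), logical(1)))
  pulse_peaks <- NULL
  normalized <- NULL
  if (identical_events && length(events[[1]])) {
    y_post <- props[[which(!vapply(props, is.null, logical(1)))[1]]]$y_post
    pulse_peaks <- sum(a_eff) * y_post
    normalized <- pulse_peaks / pulse_peaks[1]
  }
  cur <- if (inward) -total else total
  list(trace = data.frame(time = grid, current = cur),
       pulse_peaks = pulse_peaks, normalized = normalized)
}

#' Free-running simulation of the CA1 surrogate neuron
#'
#' Integrates the conductance-based membrane equation
#' `C dV/dt = -gL (V - EL) - sum_i w_i y_i(t) (V - Esyn)` with exponential
#' Euler on a fixed grid while the synapses are advanced event-to-event with
#' the exact closed forms. A threshold crossing emits a spike, resets the
#' voltage and enforces the absolute refractory period: inputs arriving
#' inside it cannot trigger action potentials.
#'
#' @param population A [synapse_population()].
#' @param input_events A single event vector (ms) for synchronous activation
#'   of every synapse, or a per-synapse list.
#' @param params A [neuron_params()].
#' @param sample_step Integration step, ms; must not exceed one tenth of the
#'   membrane time constant.
#' @param duration Simulation length, ms; defaults to 50 ms past the last
#'   input event.
#' @param record_trace If `TRUE` also return the membrane-potential trace
#'   (can be large for long simulations).
#' @return A list with `spikes` (output spike times, ms), `n_spikes`, and
#'   optionally `trace` (data frame `time`, `v`).
#' @export
run_free <- function(population, input_events, params = neuron_params(),
                     sample_step = 0.025, duration = NULL,
                     record_trace = FALSE) {
  stopifnot(inherits(population, "synapse_population"),
            inherits(params, "neuron_params"))
  if (population$n < 1) stop("empty synapse population", call. = FALSE)
  if (sample_step > 0.1 * params$membrane_time_constant)
    stop("'sample_step' too large for stable integration ",
         "(must be <= 0.1 * membrane_time_constant)", call. = FALSE)
  events <- as_event_list(input_events, population$n)
  all_t <- unlist(events)
  if (is.null(duration))
    duration <- if (length(all_t)) max(all_t) + 50 else 100
  syn_id <- rep.int(seq_along(events) - 1L,
                    vapply(events, length, integer(1)))
  ord <- order(all_t)
  w_eff <- population$weights * population$attenuation
  res <- lif_run_cpp(as.numeric(all_t[ord]), as.integer(syn_id[ord]),
                     as.numeric(w_eff),
                     population$params$U, population$params$tau_in,
                     population$params$tau_rec, population$params$tau_facil,
                     params$membrane_time_constant * params$leak_conductance,
                     params$leak_conductance, params$resting_potential,
                     params$spike_threshold, params$reset_potential,
                     params$refractory_period, params$synaptic_reversal,
                     params$adapt_increment, params$adapt_tau,
                     params$adapt_reversal,
                     sample_step, duration, record_trace)
  out <- list(spikes = res$spikes, n_spikes = length(res$spikes))
  if (record_trace)
    out$trace <- data.frame(time = res$trace_time, v = res$trace_v)
  out
}

# mean spike probability (%) of a weight-scale multiplier: n_seeds trials,
# each with freshly sampled weights, cycling through the drive patterns
mean_spike_probability <- function(scale, patterns, params, neuron, n_seeds,
                                   base_seed, n_synapses = 10,
                                   multiplicity = 15,
                                   dist = weight_distribution(),
                                   jitter_range = NULL,
                                   sample_step = 0.025) {
  probs <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    pop <- synapse_population(n = n_synapses, params = params, dist = dist,
                              multiplicity = multiplicity,
                              seed = derive_seed(base_seed, 101, s))
    pop$weights <- pop$weights * scale
    pat <- patterns[[(s - 1L) %% length(patterns) + 1L]]
    times_ms <- if (inherits(pat, "spike_train")) pat$times * 1000 else pat
    ev <- if (is.null(jitter_range)) times_ms
    else jitter_events(times_ms, n_synapses, jitter_range,
                       seed = derive_seed(base_seed, 211, s))
    run <- run_free(pop, ev, neuron, sample_step = sample_step)
    probs[s] <- 100 * run$n_spikes / length(times_ms)
  }
  mean(probs)
}

#' Calibrate weight scales for the integrative and saturating regimes
#'
#' Finds, by bisection on a uniform weight multiplier, the scales at which
#' the mean spike probability (over `n_seeds` weight resamplings and all
#' supplied drive patterns) falls inside two target bands: an integrative
#' regime, where several inputs must be summed to reach threshold, and a
#' saturating regime, where almost every stimulus spikes and the refractory
#' period caps the attainable probability.
#'
#' @param drive A list of [spike_train()] objects (or ms event vectors) used
#'   as synchronous input patterns.
#' @param params Synapse [stp_params()] (the condition being calibrated).
#' @param neuron A [neuron_params()].
#' @param bands Named list with `integrative` and `saturating` target bands
#'   in percent, e.g. `list(integrative = c(25, 40), saturating = c(85, 92))`.
#' @param n_seeds Weight resamplings averaged per evaluation.
#' @param seed Base seed for the deterministic resamplings.
#' @param n_synapses,multiplicity,dist Population specification.
#' @param max_scale Upper bound of the bracketing search; probabilities still
#'   below a band there raise a calibration-failure error.
#' @param max_iter Bisection iterations per band.
#' @param sample_step Integration step, ms.
#' @return A list with one entry per band: `scale` (the multiplier) and
#'   `probability` (the achieved mean spike probability, %).
#' @export
calibrate_regimes <- function(drive, params = stp_params(U = 0.15),
                              neuron = neuron_params(),
                              bands = list(integrative = c(25, 40),
                                           saturating = c(85, 92)),
                              n_seeds = 10, seed = 1, n_synapses = 10,
                              multiplicity = 15, dist = weight_distribution(),
                              max_scale = 4096, max_iter = 40,
                              sample_step = 0.025) {
  if (!length(drive)) stop("'drive' must be non-empty", call. = FALSE)
  if (!is.list(drive)) drive <- list(drive)
  memo <- new.env(parent = emptyenv())
  eval_p <- function(scale) {
    key <- format(scale, digits = 15)
    if (!is.null(memo[[key]])) return(memo[[key]])
    p <- mean_spike_probability(scale, drive, params, neuron, n_seeds, seed,
                                n_synapses, multiplicity, dist,
                                sample_step = sample_step)
    memo[[key]] <- p
    p
  }
  out <- list()
  # process the easier (lower) band first so its bracket can be reused
  for (nm in names(bands)[order(vapply(bands, `[`, numeric(1), 1))]) {
    band <- bands[[nm]]
    lo <- 0
    hi <- 1; p_hi <- eval_p(hi)
    while (p_hi < band[1] && hi < max_scale) {
      lo <- hi
      hi <- hi * 2
      p_hi <- eval_p(hi)
    }
    if (p_hi < band[1])
      stop(sprintf(paste0("calibration failure for band '%s' [%g, %g]%%: ",
                          "probability at the maximum scale %g is only ",
                          "%.2f%% (refractory ceiling)"),
                   nm, band[1], band[2], max_scale, p_hi), call. = FALSE)
    scale <- hi; achieved <- p_hi
    for (it in seq_len(max_iter)) {
      if (achieved >= band[1] && achieved <= band[2]) break
      mid <- (lo + hi) / 2
      achieved <- eval_p(mid)
      scale <- mid
      if (achieved < band[1]) lo <- mid else if (achieved > band[2]) hi <- mid
    }
    if (achieved < band[1] || achieved > band[2])
      stop(sprintf(paste0("calibration failure for band '%s' [%g, %g]%%: ",
                          "bisection stalled at %.2f%%"),
                   nm, band[1], band[2], achieved), call. = FALSE)
    out[[nm]] <- list(scale = scale, probability = achieved)
  }
  out[names(bands)]
}
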