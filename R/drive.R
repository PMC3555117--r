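#' Shifted lognormal distribution of miniature EPSC amplitudes
#'
#' Unitary synaptic strengths are drawn from a three-parameter (shifted)
#' lognormal distribution fitted to somatic mEPSC amplitude recordings:
#' `amplitude = shift + Lognormal(mu, sigma)` with log-scale `mu`, shape
#' `sigma` and location offset `shift` in pA. Defaults reproduce the fit
#' mu = 1.6, sigma = 1, shift = 5 pA.
#'
#' @param mu Lognormal log-scale parameter.
#' @param sigma Lognormal shape parameter (> 0).
#' @param shift Location offset, pA (>= 0).
#' @param clamp_bounds Optional `c(min, max)` pA; draws are truncated by
#'   rejection to this interval.
#' @return An object of class `weight_distribution`.
#' @export
weight_distribution <- function(mu = 1.6, sigma = 1, shift = 5,
                                clamp_bounds = NULL) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(shift))
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (shift < 0) stop("'shift' must be non-negative", call. = FALSE)
  if (!is.null(clamp_bounds)) {
    stopifnot(is.numeric(clamp_bounds), length(clamp_bounds) == 2L)
    if (clamp_bounds[1] >= clamp_bounds[2])
      stop("'clamp_bounds' must be increasing", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, shift = shift,
                 clamp_bounds = clamp_bounds),
            class = "weight_distribution")
}

#' Sample mEPSC amplitudes
#'
#' Draws `n` amplitudes (pA) from a [weight_distribution()]. Reproducible
#' when `seed` is given; otherwise the current RNG stream is used.
#'
#' @param n Number of draws.
#' @param dist A `weight_distribution`.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` amplitudes, pA.
#' @export
sample_weights <- function(n, dist = weight_distribution(), seed = NULL) {
  stopifnot(inherits(dist, "weight_distribution"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be >= 1", call. = FALSE)
  draw <- function(m) dist$shift + stats::rlnorm(m, dist$mu, dist$sigma)
  body <- function() {
    w <- draw(n)
    if (!is.null(dist$clamp_bounds)) {
      bad <- which(w < dist$clamp_bounds[1] | w > dist$clamp_bounds[2])
      while (length(bad)) {
        w[bad] <- draw(length(bad))
        bad <- which(w < dist$clamp_bounds[1] | w > dist$clamp_bounds[2])
      }
    }
    w
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Convert a somatic current amplitude to a model conductance
#'
#' Bridges mEPSC amplitudes (pA, recorded under voltage clamp) to peak
#' synaptic conductances (nS): `weight = multiplicity * amplitude /
#' |hold - reversal|`. One model synapse stands for `multiplicity` real
#' synapses, whose conductances are folded into a single weight.
#'
#' @param amplitude Current amplitude, pA.
#' @param hold Holding potential, mV.
#' @param reversal Synaptic reversal potential, mV.
#' @param multiplicity Number of real synapses represented (default 15).
#' @return Conductance(s), nS.
#' @examples
#' amplitude_to_weight(14, hold = -70, reversal = 0, multiplicity = 15) # 3 nS
#' @export
amplitude_to_weight <- function(amplitude, hold = -70, reversal = 0,
                                multiplicity = 15) {
  if (hold == reversal)
    stop("zero driving force: 'hold' must differ from 'reversal'",
         call. = FALSE)
  multiplicity * amplitude / abs(hold - reversal)
}

#' Build a synapse population
#'
#' Assembles `n` model synapses sharing one short-term-plasticity parameter
#' set, with peak conductances sampled from the mEPSC amplitude distribution
#' and converted via [amplitude_to_weight()]. Each model synapse stands for
#' `multiplicity` real Schaffer-collateral contacts; the default population of
#' 10 synapses at multiplicity 15 therefore represents about 150 real active
#' synapses. An optional per-synapse attenuation factor, drawn uniformly in
#' `attenuation_range`, stands in for the electrotonic distance of contacts
#' scattered along the apical trunk and is meant to be resampled each trial.
#'
#' @param n Number of model synapses (default 10).
#' @param params An `stp_params` shared by all synapses.
#' @param dist A `weight_distribution` for mEPSC amplitudes.
#' @param multiplicity Real synapses per model synapse (default 15).
#' @param hold,reversal Potentials (mV) used for the pA -> nS conversion.
#' @param attenuation_range `c(lo, hi)` for the uniform attenuation factor;
#'   use `c(1, 1)` to disable.
#' @param seed Optional integer seed.
#' @return An object of class `synapse_population`: a list with `params`,
#'   `weights` (nS), `attenuation`, `multiplicity` and `n`.
#' @export
synapse_population <- function(n = 10, params = stp_params(U = 0.15),
                               dist = weight_distribution(),
                               multiplicity = 15, hold = -70, reversal = 0,
                               attenuation_range = c(0.7, 1.0), seed = NULL) {
  stopifnot(inherits(params, "stp_params"))
  build <- function() {
    amps <- sample_weights(n, dist)
    att  <- stats::runif(n, attenuation_range[1], attenuation_range[2])
    list(weights = amplitude_to_weight(amps, hold, reversal, multiplicity),
         attenuation = att)
  }
  parts <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(params = params, weights = parts$weights,
                 attenuation = parts$attenuation,
                 multiplicity = multiplicity, hold = hold,
                 reversal = reversal, n = n),
            class = "synapse_population")
}

#' @export
print.synapse_population <- function(x, ...) {
  cat(sprintf("Synapse population: %d model synapses (x%d real contacts each)\n",
              x$n, x$multiplicity))
  cat(sprintf("  effective weights (nS): %s\n",
              paste(sprintf("%.2f", x$weights * x$attenuation), collapse = ", ")))
  cat(sprintf("  U = %.3g, tau_rec = %g ms, tau_facil = %g ms\n",
              x$params$U, x$params$tau_rec, x$params$tau_facil))
  invisible(x)
}

#' Distribute a stimulation pattern over synapses with activation jitter
#'
#' Replicates one event-time pattern across `n_synapses`, adding an
#' independent uniform activation delay to each event of each synapse
#' (asynchronous mode; the default 0-9 ms range is about a quarter of a gamma
#' cycle). A zero-width range yields synchronous activation: identical
#' copies. With `mode = "per_train"` a single offset per synapse is drawn
#' instead of one per event.
#'
#' @param times Event times, ms (strictly increasing).
#' @param n_synapses Number of synapses to drive.
#' @param jitter_range `c(lo, hi)` delay range in ms, `lo >= 0`.
#' @param mode `"per_event"` (default; strongest desynchronisation) or
#'   `"per_train"`.
#' @param seed Optional integer seed.
#' @return A list of `n_synapses` sorted event-time vectors, ms.
#' @export
jitter_events <- function(times, n_synapses, jitter_range = c(0, 9),
                          mode = c("per_event", "per_train"), seed = NULL) {
  mode <- match.arg(mode)
  check_spike_times_ms(times, allow_empty = TRUE)
  stopifnot(is.numeric(jitter_range), length(jitter_range) == 2L)
  if (jitter_range[1] < 0 || jitter_range[2] < jitter_range[1])
    stop("'jitter_range' must be non-negative and increasing", call. = FALSE)
  body <- function() {
    lapply(seq_len(n_synapses), function(i) {
      if (!length(times)) return(numeric(0))
      off <- if (mode == "per_event")
        stats::runif(length(times), jitter_range[1], jitter_range[2])
      else
        rep(stats::runif(1, jitter_range[1], jitter_range[2]), length(times))
      sort(times + off)
    })
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Regular stimulation train
#'
#' `n_pulses` event times at a fixed frequency: intervals of
#' `1000 / frequency` ms starting at `start`.
#'
#' @param frequency Stimulation frequency, Hz (> 0).
#' @param n_pulses Number of pulses (>= 1).
#' @param start Time of the first pulse, ms.
#' @return Numeric vector of event times, ms.
#' @examples
#' constant_train(100, 5) # 0 10 20 30 40
#' @export
constant_train <- function(frequency, n_pulses, start = 0) {
  if (!is.numeric(frequency) || frequency <= 0)
    stop("'frequency' must be positive", call. = FALSE)
  if (!is.numeric(n_pulses) || n_pulses < 1)
    stop("'n_pulses' must be >= 1", call. = FALSE)
  start + (seq_len(n_pulses) - 1) * 1000 / frequency
}

#' Analytic CDF of the shifted lognormal amplitude distribution
#'
#' @param q Quantiles, pA.
#' @param dist A `weight_distribution`.
#' @return `P(amplitude <= q)` ignoring any clamp bounds.
#' @export
weight_cdf <- function(q, dist = weight_distribution()) {
  stopifnot(inherits(dist, "weight_distribution"))
  stats::plnorm(pmax(q - dist$shift, 0), dist$mu, dist$sigma)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded helpers do not perturb outer streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
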