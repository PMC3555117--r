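#' Synapse parameters for the three-state resource model
#'
#' Constructs the parameter set of the resource model of short-term synaptic
#' plasticity. A synapse holds a finite amount of resource split into a
#' recovered fraction `x`, an active fraction `y` and an inactive fraction
#' `z` (with `x + y + z = 1`). On each presynaptic spike a fraction `p` of
#' the recovered resource is activated; the active resource inactivates with
#' time constant `tau_in` and recovers with time constant `tau_rec`. The
#' use-variable `p` facilitates: at a spike it is incremented by
#' `U * (1 - p)` (increment applied before release), and between spikes it
#' decays back to 0 with time constant `tau_facil`, so that `p` at the first
#' spike equals `U` (the initial release probability).
#'
#' @param U Facilitation increment and initial release probability,
#'   dimensionless in (0, 1].
#' @param tau_in Inactivation time constant of the active resource, ms.
#' @param tau_rec Recovery time constant of the inactive resource, ms.
#' @param tau_facil Decay time constant of the use-variable `p`, ms.
#' @param A Absolute synaptic strength: the current (pA) or conductance (nS)
#'   obtained by activating all the resource at once (`y = 1`).
#'
#' @return An object of class `stp_params`.
#' @examples
#' ctrl <- stp_params(U = 0.15)
#' ab   <- stp_params(U = 0.36)
#' @export
stp_params <- function(U, tau_in = 1, tau_rec = 50, tau_facil = 200, A = 1) {
  stopifnot(length(U) == 1L, length(tau_in) == 1L, length(tau_rec) == 1L,
            length(tau_facil) == 1L, length(A) == 1L)
  if (!is.finite(U) || U <= 0 || U > 1)
    stop("'U' must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(c(tau_in, tau_rec, tau_facil))) ||
      any(c(tau_in, tau_rec, tau_facil) <= 0))
    stop("all time constants must be positive and finite", call. = FALSE)
  if (!is.finite(A) || A <= 0)
    stop("'A' must be positive", call. = FALSE)
  structure(list(U = as.numeric(U), tau_in = as.numeric(tau_in),
                 tau_rec = as.numeric(tau_rec),
                 tau_facil = as.numeric(tau_facil), A = as.numeric(A)),
            class = "stp_params")
}

#' @export
print.stp_params <- function(x, ...) {
  cat("Short-term plasticity synapse parameters\n")
  cat(sprintf("  U (initial release probability): %.4g\n", x$U))
  cat(sprintf("  tau_in: %g ms, tau_rec: %g ms, tau_facil: %g ms\n",
              x$tau_in, x$tau_rec, x$tau_facil))
  cat(sprintf("  A (absolute strength): %g\n", x$A))
  invisible(x)
}

#' Initial synapse state
#'
#' All resource recovered, nothing active or inactive, use-variable at its
#' baseline of zero: `x = 1`, `y = 0`, `z = 0`, `p = 0` at time 0.
#'
#' @return An object of class `stp_state` with fields `x`, `y`, `z`, `p`
#'   and `t` (ms).
#' @export
stp_initial_state <- function() {
  structure(list(x = 1, y = 0, z = 0, p = 0, t = 0), class = "stp_state")
}

#' @export
print.stp_state <- function(x, ...) {
  cat(sprintf("stp_state at t = %g ms: x = %.6g, y = %.6g, z = %.6g, p = %.6g\n",
              x$t, x$x, x$y, x$z, x$p))
  invisible(x)
}

#' Relax the synapse state over a spike-free interval
#'
#' Advances the state by `dt` milliseconds using the exact solution of the
#' linear inter-spike system: `y` decays exponentially with `tau_in`; `z`
#' receives the inactivating flux and itself recovers with `tau_rec` (the
#' closed form is a sum of the two exponentials, with the `t * exp(-t/tau)`
#' limit used when `tau_in == tau_rec`); `x` follows from conservation; and
#' the use-variable decays as `p * exp(-dt / tau_facil)`. No stepped
#' integration is involved, so repeated calls accumulate no discretisation
#' error.
#'
#' @param state An `stp_state`.
#' @param dt Interval length, ms (non-negative).
#' @param params An `stp_params`.
#' @return The relaxed `stp_state`, with `t` advanced by `dt`.
#' @export
stp_relax <- function(state, dt, params) {
  stopifnot(inherits(state, "stp_state"), inherits(params, "stp_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("'dt' must be a single non-negative number", call. = FALSE)
  if (dt == 0) return(state)
  e_in <- exp(-dt / params$tau_in)
  if (params$tau_in != params$tau_rec) {
    # particular solution coefficient for the y -> z flux
    cc <- state$y * params$tau_rec / (params$tau_in - params$tau_rec)
    z  <- (state$z - cc) * exp(-dt / params$tau_rec) + cc * e_in
  } else {
    z  <- (state$z + state$y * dt / params$tau_in) * e_in
  }
  y <- state$y * e_in
  structure(list(x = 1 - y - z, y = y, z = z,
                 p = state$p * exp(-dt / params$tau_facil),
                 t = state$t + dt),
            class = "stp_state")
}

#' Apply a presynaptic spike to a relaxed synapse state
#'
#' Implements the discrete spike update: the use-variable is incremented
#' first, `p+ = p- + U * (1 - p-)`, and only then is the released fraction
#' `delta = p+ * x-` moved from the recovered to the active pool. The state
#' must already be relaxed to the spike time.
#'
#' @param state The pre-spike `stp_state`.
#' @param params An `stp_params`.
#' @return A list with elements `state` (post-spike `stp_state`) and
#'   `released` (the fraction `delta` moved from `x` to `y`).
#' @export
stp_apply_spike <- function(state, params) {
  stopifnot(inherits(state, "stp_state"), inherits(params, "stp_params"))
  p_post <- state$p + params$U * (1 - state$p)
  delta  <- p_post * state$x
  new_state <- structure(list(x = state$x - delta, y = state$y + delta,
                              z = state$z, p = p_post, t = state$t),
                         class = "stp_state")
  list(state = new_state, released = delta)
}

#' Event-driven propagation of the synapse through a spike train
#'
#' Alternates exact inter-spike relaxation and discrete spike updates over a
#' sorted train of presynaptic spike times. This is the workhorse behind EPSC
#' traces and amplitude sequences; it is also useful for validating the
#' closed forms against a direct ODE integration.
#'
#' @param params An `stp_params`.
#' @param spike_times Strictly increasing spike times, ms.
#' @return A data frame with one row per spike: pre-spike state
#'   (`x_pre`, `y_pre`, `z_pre`, `p_pre`), post-spike state
#'   (`x_post`, `y_post`, `p_post`) and the released fraction `released`.
#' @export
stp_propagate <- function(params, spike_times) {
  stopifnot(inherits(params, "stp_params"))
  check_spike_times_ms(spike_times)
  n <- length(spike_times)
  out <- data.frame(t = spike_times,
                    x_pre = numeric(n), y_pre = numeric(n),
                    z_pre = numeric(n), p_pre = numeric(n),
                    p_post = numeric(n), x_post = numeric(n),
                    y_post = numeric(n), released = numeric(n))
  st <- stp_initial_state()
  t_prev <- 0
  for (i in seq_len(n)) {
    st <- stp_relax(st, spike_times[i] - t_prev, params)
    out$x_pre[i] <- st$x; out$y_pre[i] <- st$y
    out$z_pre[i] <- st$z; out$p_pre[i] <- st$p
    upd <- stp_apply_spike(st, params)
    st <- upd$state
    out$p_post[i] <- st$p; out$x_post[i] <- st$x
    out$y_post[i] <- st$y; out$released[i] <- upd$released
    t_prev <- spike_times[i]
  }
  out
}

#' Sampled EPSC trace from a spike train
#'
#' The excitatory postsynaptic current is proportional to the active
#' resource, `EPSC(t) = A * y(t)`. The trace is produced by event-driven
#' closed-form propagation between spikes and sampled on a regular grid, so
#' no integration error accumulates. `y` jumps upward by the released
#' fraction at each spike time and decays in between.
#'
#' @param params An `stp_params`.
#' @param spike_times Strictly increasing spike times, ms.
#' @param sample_step Sampling step, ms.
#' @param t_end End of the trace, ms; defaults to the last spike plus
#'   `8 * tau_in` (or 1 ms for an empty train).
#' @param inward If `TRUE`, report the current with the inward-negative sign
#'   convention used for display; by default magnitudes are positive.
#' @return A data frame with columns `time` (ms) and `current` (units of `A`).
#' @export
epsc_trace <- function(params, spike_times, sample_step, t_end = NULL,
                       inward = FALSE) {
  stopifnot(inherits(params, "stp_params"))
  if (!is.numeric(sample_step) || length(sample_step) != 1L || sample_step <= 0)
    stop("'sample_step' must be a single positive number", call. = FALSE)
  check_spike_times_ms(spike_times, allow_empty = TRUE)
  if (is.null(t_end))
    t_end <- if (length(spike_times)) max(spike_times) + 8 * params$tau_in else 1
  grid <- seq(0, t_end, by = sample_step)
  y <- numeric(length(grid))
  if (length(spike_times)) {
    prop <- stp_propagate(params, spike_times)
    # piecewise: y(t) = y_post_i * exp(-(t - t_i)/tau_in) on [t_i, t_{i+1})
    idx <- findInterval(grid, spike_times)
    live <- idx > 0
    y[live] <- prop$y_post[idx[live]] *
      exp(-(grid[live] - spike_times[idx[live]]) / params$tau_in)
  }
  cur <- params$A * y
  if (inward) cur <- -cur
  data.frame(time = grid, current = cur)
}

#' Per-pulse EPSC peak amplitudes of a regular train
#'
#' Simulates `n_pulses` presynaptic spikes at the given frequency and returns
#' the peak current attributable to each pulse together with the sequence
#' normalized to the first pulse. After a spike the active resource decays
#' monotonically, so the analytic maximum of the post-spike `y(t)` expression
#' is its value immediately after the spike; the amplitude convention
#' attributes that whole peak (including any residual active resource from
#' earlier pulses at short intervals) to the pulse, without baseline
#' subtraction.
#'
#' @param params An `stp_params`.
#' @param n_pulses Number of pulses (>= 1).
#' @param frequency Stimulation frequency, Hz.
#' @return A list with `amplitude` (peak `A * y`, one per pulse),
#'   `normalized` (first element exactly 1), and `times` (spike times, ms).
#' @examples
#' # Facilitation-then-depression contrast at 100 Hz
#' train_amplitudes(stp_params(U = 0.15), 5, 100)$normalized
#' train_amplitudes(stp_params(U = 0.36), 5, 100)$normalized
#' @export
train_amplitudes <- function(params, n_pulses, frequency) {
  stopifnot(inherits(params, "stp_params"))
  if (!is.numeric(n_pulses) || length(n_pulses) != 1L || n_pulses < 1)
    stop("'n_pulses' must be >= 1", call. = FALSE)
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("'frequency' must be positive", call. = FALSE)
  times <- constant_train(frequency, n_pulses)
  prop  <- stp_propagate(params, times)
  amp   <- params$A * prop$y_post
  list(amplitude = amp, normalized = amp / amp[1], times = times)
}

# shared validation of millisecond event-time vectors
check_spike_times_ms <- function(times, allow_empty = FALSE) {
  if (!is.numeric(times))
    stop("spike times must be numeric", call. = FALSE)
  if (!length(times)) {
    if (allow_empty) return(invisible(TRUE))
    stop("spike train is empty", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0))
    stop("spike times must be finite and non-negative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("spike times must be strictly increasing (no duplicates)",
         call. = FALSE)
  invisible(TRUE)
}
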