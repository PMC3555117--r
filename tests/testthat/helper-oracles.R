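# Independent oracles used to validate the event-driven synapse
# implementation. Both are deliberately implemented from the model equations
# only, without reusing any closed forms from the package.

# Instant-inactivation recursion (tau_in -> 0): after each spike the released
# fraction inactivates immediately, so per-pulse amplitudes follow the
# two-variable recursion in (p, x). Returns amplitudes normalized to pulse 1.
recursion_amplitudes <- function(U, tau_rec, tau_facil, n_pulses, frequency) {
  interval <- 1000 / frequency
  p <- 0
  x <- 1
  amps <- numeric(n_pulses)
  for (i in seq_len(n_pulses)) {
    p <- p + U * (1 - p)
    amps[i] <- p * x
    x <- x * (1 - p)
    x <- 1 - (1 - x) * exp(-interval / tau_rec)
    p <- p * exp(-interval / tau_facil)
  }
  amps / amps[1]
}

# post-spike fixed point of the use-variable under periodic drive
recursion_p_fixed_point <- function(U, tau_facil, frequency) {
  q <- exp(-(1000 / frequency) / tau_facil)
  U / (1 - (1 - U) * q)
}

# High-accuracy ODE integration of the four-state system between spikes
# (deSolve::lsoda, atol/rtol 1e-12) with the discrete spike map applied at
# each spike time. Returns pre- and post-spike states at every spike.
ode_states_at_spikes <- function(params, spike_times) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  deriv <- function(t, s, parms) {
    list(c(x = s[["z"]] / parms$tau_rec,
           y = -s[["y"]] / parms$tau_in,
           z = s[["y"]] / parms$tau_in - s[["z"]] / parms$tau_rec,
           p = -s[["p"]] / parms$tau_facil))
  }
  st <- c(x = 1, y = 0, z = 0, p = 0)
  t_prev <- 0
  pre <- post <- matrix(NA_real_, length(spike_times), 4,
                        dimnames = list(NULL, c("x", "y", "z", "p")))
  for (i in seq_along(spike_times)) {
    dt <- spike_times[i] - t_prev
    if (dt > 0) {
      sol <- deSolve::lsoda(st, c(0, dt), deriv, parms = params,
                            atol = 1e-12, rtol = 1e-12)
      st <- sol[nrow(sol), c("x", "y", "z", "p")]
    }
    pre[i, ] <- st
    p_new <- st[["p"]] + params$U * (1 - st[["p"]])
    delta <- p_new * st[["x"]]
    st[["p"]] <- p_new
    st[["x"]] <- st[["x"]] - delta
    st[["y"]] <- st[["y"]] + delta
    post[i, ] <- st
    t_prev <- spike_times[i]
  }
  list(pre = pre, post = post)
}

# Fixed-step classical RK4 integration of the same system (no adaptivity),
# used as a second, structurally different cross-check on short trains.
rk4_states_at_spikes <- function(params, spike_times, step = 1e-3) {
  f <- function(s) c(s[3] / params$tau_rec,
                     -s[2] / params$tau_in,
                     s[2] / params$tau_in - s[3] / params$tau_rec,
                     -s[4] / params$tau_facil)
  st <- c(1, 0, 0, 0)
  t_prev <- 0
  pre <- matrix(NA_real_, length(spike_times), 4)
  for (i in seq_along(spike_times)) {
    dt <- spike_times[i] - t_prev
    n <- round(dt / step)
    if (n > 0) {
      h <- dt / n
      for (k in seq_len(n)) {
        k1 <- f(st)
        k2 <- f(st + h / 2 * k1)
        k3 <- f(st + h / 2 * k2)
        k4 <- f(st + h * k3)
        st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    pre[i, ] <- st
    p_new <- st[4] + params$U * (1 - st[4])
    delta <- p_new * st[1]
    st <- c(st[1] - delta, st[2] + delta, st[3], p_new)
    t_prev <- spike_times[i]
  }
  pre
}
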