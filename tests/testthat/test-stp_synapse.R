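test_that("initial state is a fixed point of relaxation", {
  st <- stp_initial_state()
  expect_equal(st$x, 1)
  expect_equal(st$y, 0)
  expect_equal(st$z, 0)
  expect_equal(st$p, 0)
  expect_equal(st$x + st$y + st$z, 1)
  ctrl <- condition_params("control")
  for (dt in c(0.1, 5, 1000)) {
    rl <- stp_relax(st, dt, ctrl)
    expect_equal(rl$x, 1)
    expect_equal(rl$y, 0)
    expect_equal(rl$p, 0)
  }
  expect_identical(stp_relax(st, 0, ctrl), st)
  expect_error(stp_relax(st, -1, ctrl), "non-negative")
})

test_that("relaxation matches the closed-form exponentials", {
  ctrl <- condition_params("control")
  st <- structure(list(x = 0.85, y = 0, z = 0.15, p = 0.15, t = 0),
                  class = "stp_state")
  rl <- stp_relax(st, 10, ctrl)
  # with y = 0 the inactive pool decays as z0 * exp(-dt/tau_rec)
  expect_equal(rl$z, 0.15 * exp(-10 / 50), tolerance = 1e-12)
  expect_equal(rl$x, 1 - 0.15 * exp(-10 / 50), tolerance = 1e-12)
  expect_equal(rl$p, 0.15 * exp(-10 / 200), tolerance = 1e-12)
  expect_equal(rl$p, 0.14268, tolerance = 1e-4)
  expect_equal(rl$x, 0.8772, tolerance = 1e-4)
})

test_that("degenerate equal time constants agree with the ODE oracle", {
  skip_if_not_installed("deSolve")
  pars <- stp_params(U = 0.2, tau_in = 5, tau_rec = 5, tau_facil = 100)
  times <- constant_train(100, 5)
  prop <- stp_propagate(pars, times)
  ora <- ode_states_at_spikes(pars, times)
  expect_lt(max(abs(prop$x_pre - ora$pre[, "x"])), 1e-8)
  expect_lt(max(abs(prop$y_pre - ora$pre[, "y"])), 1e-8)
  expect_lt(max(abs(prop$z_pre - ora$pre[, "z"])), 1e-8)
})

test_that("spike update increments p before converting x to y", {
  ctrl <- condition_params("control")
  up <- stp_apply_spike(stp_initial_state(), ctrl)
  expect_equal(up$state$p, 0.15)
  expect_equal(up$released, 0.15)
  expect_equal(up$state$x, 0.85)
  # full release when U = 1
  up1 <- stp_apply_spike(stp_initial_state(), stp_params(U = 1))
  expect_equal(up1$state$p, 1)
  expect_equal(up1$released, 1)
  expect_equal(up1$state$x, 0)
  # second spike of a 100 Hz train: p+ from the facilitation increment
  prop <- stp_propagate(ctrl, c(0, 10))
  expect_equal(prop$p_pre[2], 0.15 * exp(-10 / 200), tolerance = 1e-12)
  expect_equal(prop$p_post[2], 0.27128, tolerance = 1e-4)
  expect_equal(prop$released[2], prop$p_post[2] * prop$x_pre[2],
               tolerance = 1e-12)
})

test_that("resource conservation holds over random spike sequences", {
  set.seed(42)
  for (rep in 1:20) {
    pars <- stp_params(U = runif(1, 0.05, 0.95),
                       tau_in = runif(1, 0.5, 20),
                       tau_rec = runif(1, 5, 300),
                       tau_facil = runif(1, 5, 500))
    times <- cumsum(rexp(30, rate = 1 / runif(1, 2, 50)))
    prop <- stp_propagate(pars, times)
    expect_lt(max(abs(prop$x_pre + prop$y_pre + prop$z_pre - 1)), 1e-9)
    expect_true(all(prop$x_pre >= 0 & prop$x_pre <= 1))
    expect_true(all(prop$y_pre >= 0 & prop$y_pre <= 1))
    expect_true(all(prop$p_post >= 0 & prop$p_post <= 1))
  }
})

test_that("event-driven states agree with high-accuracy ODE integration", {
  skip_if_not_installed("deSolve")
  for (cond in c("control", "abeta")) {
    pars <- condition_params(cond)
    for (f in c(5, 40, 100, 200)) {
      times <- constant_train(f, 5)
      prop <- stp_propagate(pars, times)
      ora <- ode_states_at_spikes(pars, times)
      err <- max(abs(cbind(prop$x_pre, prop$y_pre, prop$z_pre, prop$p_pre) -
                       ora$pre))
      expect_lt(err, 1e-6)
    }
  }
  # independent fixed-step RK4 cross-check on a short train
  pars <- condition_params("control")
  times <- constant_train(100, 5)
  rk <- rk4_states_at_spikes(pars, times, step = 1e-3)
  prop <- stp_propagate(pars, times)
  expect_lt(max(abs(cbind(prop$x_pre, prop$y_pre, prop$z_pre, prop$p_pre) -
                      rk)), 1e-6)
})

test_that("facilitation-only and depression-only limits behave as expected", {
  # instant recovery: normalized amplitudes equal p_n / U, non-decreasing
  fac <- stp_params(U = 0.15, tau_in = 1e-4, tau_rec = 1e-4, tau_facil = 200)
  amp <- train_amplitudes(fac, 8, 100)$normalized
  p <- 0
  p_seq <- numeric(8)
  for (i in 1:8) {
    p <- p + 0.15 * (1 - p)
    p_seq[i] <- p
    p <- p * exp(-10 / 200)
  }
  expect_equal(amp, p_seq / p_seq[1], tolerance = 1e-3)
  expect_true(all(diff(amp) >= -1e-9))
  # instant p decay: p resets to U each pulse, amplitudes non-increasing
  dep <- stp_params(U = 0.4, tau_in = 1, tau_rec = 200, tau_facil = 1e-4)
  amp2 <- train_amplitudes(dep, 8, 100)$normalized
  expect_true(all(diff(amp2) <= 1e-9))
})

test_that("periodic drive converges to the analytic fixed point", {
  U <- 0.15; f <- 40; interval <- 1000 / f
  p_star <- recursion_p_fixed_point(U, 200, f)
  # iterate the instant-inactivation recursion to stationarity
  p <- 0; x <- 1
  for (i in 1:400) {
    p <- p + U * (1 - p)
    if (i == 400) break
    x <- x * (1 - p)
    x <- 1 - (1 - x) * exp(-interval / 50)
    p <- p * exp(-interval / 200)
  }
  expect_equal(p, p_star, tolerance = 1e-6)
  # the use-variable fixed point is exact for the full kinetics too
  pars <- stp_params(U = U, tau_in = 1, tau_rec = 50, tau_facil = 200)
  prop <- stp_propagate(pars, constant_train(f, 400))
  expect_equal(prop$p_post[400], p_star, tolerance = 1e-6)
  # stationary amplitude matches the recursion within 1% (the finite
  # tau_in correction at this interval) and has converged
  amp <- train_amplitudes(pars, 400, f)$amplitude
  expect_equal(amp[400], p_star * x, tolerance = 0.01)
  expect_equal(amp[400], amp[350], tolerance = 1e-9)
})

test_that("EPSC traces follow A * y(t) with upward jumps at spikes", {
  pars <- stp_params(U = 0.15, A = 100)
  # no spikes: identically zero
  tr0 <- epsc_trace(pars, numeric(0), sample_step = 0.1, t_end = 5)
  expect_true(all(tr0$current == 0))
  # single spike: peak A * U at the spike sample
  tr1 <- epsc_trace(pars, 0, sample_step = 0.01)
  expect_equal(max(tr1$current), 15, tolerance = 1e-9)
  # inward-negative display convention
  tr1n <- epsc_trace(pars, 0, sample_step = 0.01, inward = TRUE)
  expect_equal(min(tr1n$current), -15, tolerance = 1e-9)
  # between spikes the trace decays; at a spike it jumps upward
  tr2 <- epsc_trace(pars, c(0, 10), sample_step = 0.5)
  i_spike <- which(tr2$time == 10)
  expect_gt(tr2$current[i_spike], tr2$current[i_spike - 1])
  pre <- tr2$current[2:(i_spike - 1)]
  expect_true(all(diff(pre) < 0))
  expect_error(epsc_trace(pars, c(5, 5), 0.1), "increasing")
  expect_error(epsc_trace(pars, c(5, 1), 0.1), "increasing")
})

test_that("train amplitudes reproduce the facilitation/depression contrast", {
  expect_equal(train_amplitudes(condition_params("control"), 1, 100)$normalized,
               1)
  ctrl <- train_amplitudes(condition_params("control"), 5, 100)$normalized
  ab <- train_amplitudes(condition_params("abeta"), 5, 100)$normalized
  ctrl_oracle <- recursion_amplitudes(0.15, 50, 200, 5, 100)
  ab_oracle <- recursion_amplitudes(0.36, 50, 200, 5, 100)
  expect_equal(ctrl, ctrl_oracle, tolerance = 0.05)
  expect_equal(ab, ab_oracle, tolerance = 0.05)
  # control facilitates throughout; elevated release probability facilitates
  # once then depresses
  expect_true(all(ctrl[2:5] > 1))
  expect_gt(ab[2], 1)
  expect_true(all(ab[3:5] < 1))
})
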