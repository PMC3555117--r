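make_obs <- function(pars, freqs = 100, n_pulses = 5) {
  lapply(freqs, function(f)
    list(frequency = f,
         amplitudes = train_amplitudes(pars, n_pulses, f)$normalized))
}

test_that("release probability is recovered from noiseless curves", {
  for (U_true in c(0.15, 0.36)) {
    gen <- stp_params(U = U_true)
    fit <- fit_stp(fit_spec("U", make_obs(gen)))
    expect_equal(unname(fit$par["U"]), U_true, tolerance = 0.005 / U_true)
    expect_lt(fit$sse, 1e-8)
  }
})

test_that("time constants are recovered from multi-frequency curves", {
  gen <- condition_params("control")
  obs <- make_obs(gen, freqs = c(5, 40, 100), n_pulses = 10)
  fit_rec <- fit_stp(fit_spec("tau_rec", obs))
  expect_equal(unname(fit_rec$par["tau_rec"]), 50, tolerance = 0.01)
  fit_fac <- fit_stp(fit_spec("tau_facil", obs))
  expect_equal(unname(fit_fac$par["tau_facil"]), 200, tolerance = 0.01)
  # joint two-parameter fit still identifies both
  fit2 <- fit_stp(fit_spec(c("U", "tau_rec"), obs))
  expect_equal(unname(fit2$par["U"]), 0.15, tolerance = 0.01)
  expect_equal(unname(fit2$par["tau_rec"]), 50, tolerance = 0.02)
})

test_that("fits are reproducible and robust to observation noise", {
  gen <- condition_params("control")
  clean <- make_obs(gen, freqs = c(40, 100), n_pulses = 10)
  f1 <- fit_stp(fit_spec("U", clean))
  f2 <- fit_stp(fit_spec("U", clean))
  expect_identical(f1$par, f2$par)
  # Gaussian noise sigma = 0.05, 10 replicates: mean recovered U within 0.02
  set.seed(123)
  rec <- vapply(1:10, function(r) {
    noisy <- lapply(clean, function(ob) {
      ob$amplitudes <- ob$amplitudes + rnorm(length(ob$amplitudes), 0, 0.05)
      ob
    })
    unname(fit_stp(fit_spec("U", noisy))$par["U"])
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.15), 0.02)
})

test_that("single observation point with one matching free parameter fits exactly", {
  obs <- list(list(frequency = 100, amplitudes = 1))
  fit <- fit_stp(fit_spec("U", obs))
  expect_equal(fit$sse, 0, tolerance = 1e-12)
})

test_that("fit specifications are validated", {
  expect_error(fit_spec("banana", list(list(frequency = 100, amplitudes = 1))),
               "free")
  expect_error(fit_spec(character(0),
                        list(list(frequency = 100, amplitudes = 1))), "free")
  expect_error(fit_spec(c("U", "tau_rec"),
                        list(list(frequency = 100, amplitudes = 1))),
               "observation points")
  expect_error(fit_spec("U", list(list(frequency = 100, amplitudes = 1)),
                        bounds = list(U = c(0.5, 0.1))), "bounds")
})

test_that("enlarging the free-parameter set never increases the SSE", {
  ref <- list(frequency = 100,
              amplitudes = train_amplitudes(stp_params(U = 0.3, tau_facil = 80),
                                            8, 100)$normalized)
  fit1 <- fit_stp(fit_spec("U", list(ref)))
  fit2 <- fit_stp(fit_spec(c("U", "tau_facil"), list(ref)))
  expect_lte(fit2$sse, fit1$sse + 1e-10)
})

test_that("a reduced-release scenario with faster facilitation decay mimics the elevated-release curve", {
  ref <- list(frequency = 100,
              amplitudes = train_amplitudes(condition_params("abeta"), 5,
                                            100)$normalized)
  scen <- list(
    lower_U_free_tau = fit_spec("tau_facil", list(ref),
                                fixed = stp_params(U = 0.3)),
    exact = fit_spec("U", list(ref), fixed = stp_params(U = 0.2)),
    wrong_fixed = fit_spec("tau_in", list(ref),
                           fixed = stp_params(U = 0.15),
                           bounds = list(tau_in = c(0.9, 1.1))))
  tab <- compare_scenarios(ref, scen)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$sse) >= 0))
  # U = 0.3 with tau_facil refit stays within 0.1 of the reference everywhere
  expect_lte(tab[tab$scenario == "lower_U_free_tau", "max_abs_diff"], 0.1)
  # the scenario able to match the generator exactly wins with SSE ~ 0
  expect_equal(tab$scenario[1], "exact")
  expect_lt(tab$sse[1], 1e-8)
  # a scenario pinned to wrong kinetics cannot reach zero error
  expect_gt(tab[tab$scenario == "wrong_fixed", "sse"], 1e-4)
})

test_that("sigmoid gain curves are recovered and degenerate data rejected", {
  x <- seq(5, 80, by = 5)
  y <- 90 / (1 + 50 * exp(-0.15 * x))
  fit <- fit_sigmoid(x, y)
  expect_equal(fit$a, 90, tolerance = 0.01)
  expect_equal(fit$b, 50, tolerance = 0.01)
  expect_equal(fit$c, 0.15, tolerance = 0.01)
  # the fitted curve tends to a as x grows
  expect_equal(fit$a / (1 + fit$b * exp(-fit$c * 1e4)), fit$a,
               tolerance = 1e-6)
  # asymptote can be pinned to the empirical saturating probability
  fit90 <- fit_sigmoid(x, y, a_fixed = 90)
  expect_true(fit90$a_was_fixed)
  expect_equal(fit90$b, 50, tolerance = 0.01)
  # constant response: slope unidentifiable
  expect_error(fit_sigmoid(x, rep(90, length(x))), "constant")
  expect_error(fit_sigmoid(c(1, 2), c(10, 20)), "at least 3")
})
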