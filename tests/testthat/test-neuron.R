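# small deterministic population helper: n identical synapses
fixed_population <- function(n = 1, params = condition_params("control"),
                             weight = 1, attenuation = 1) {
  structure(list(params = params, weights = rep(weight, n),
                 attenuation = rep(attenuation, n), multiplicity = 15,
                 hold = -70, reversal = 0, n = n),
            class = "synapse_population")
}

test_that("clamp current is linear in the population", {
  events <- constant_train(100, 5)
  one <- run_voltage_clamp(fixed_population(1), events)
  two <- run_voltage_clamp(fixed_population(2), events)
  expect_equal(two$trace$current, 2 * one$trace$current, tolerance = 1e-12)
  expect_equal(two$pulse_peaks, 2 * one$pulse_peaks, tolerance = 1e-12)
  # mixed weights: total equals the weighted sum of single-synapse traces
  mixed <- fixed_population(2)
  mixed$weights <- c(1, 3)
  tot <- run_voltage_clamp(mixed, events)
  expect_equal(tot$trace$current, 4 * one$trace$current, tolerance = 1e-12)
  expect_error(run_voltage_clamp(fixed_population(0), events), "empty")
})

test_that("absolute strength can be set from the first-response magnitude", {
  # A = weight * driving force chosen so the first peak is 17.6 pA at U = 0.15
  pop <- fixed_population(1, weight = (17.6 / 0.15) / 70)
  clamp <- run_voltage_clamp(pop, constant_train(100, 5), hold = -70)
  expect_equal(clamp$pulse_peaks[1], 17.6, tolerance = 1e-9)
})

test_that("normalized clamp peaks equal the single-synapse amplitude curve", {
  events <- constant_train(100, 5)
  clamp <- run_voltage_clamp(fixed_population(1, weight = 2.5), events)
  direct <- train_amplitudes(condition_params("control"), 5, 100)$normalized
  expect_equal(clamp$normalized, direct, tolerance = 1e-9)
})

test_that("a silent population leaves the neuron at rest", {
  pop <- fixed_population(2, weight = 0)
  run <- run_free(pop, constant_train(50, 20), record_trace = TRUE)
  expect_equal(run$n_spikes, 0)
  expect_equal(tail(run$trace$v, 1), -70, tolerance = 1e-6)
})

test_that("the absolute refractory period caps output", {
  pop <- fixed_population(10, weight = 50) # far supra-threshold
  events <- constant_train(250, 100)
  run <- run_free(pop, events, duration = 500)
  expect_gt(run$n_spikes, 0)
  t_ref <- neuron_params()$refractory_period
  expect_true(all(diff(run$spikes) >= t_ref - 1e-9))
  expect_lte(run$n_spikes, 500 / t_ref + 1)
})

test_that("integration step must resolve the membrane time constant", {
  pop <- fixed_population(1)
  expect_error(run_free(pop, c(0, 10), sample_step = 5), "sample_step")
})

test_that("spike probability grows with a uniform weight scale", {
  pats <- lapply(1:3, function(s)
    generate_ca3_pattern(ca3_pattern_params(duration = 10, seed = s)))
  mean_prob <- function(scale) {
    probs <- vapply(seq_along(pats), function(k) {
      pop <- synapse_population(params = condition_params("control"),
                                seed = 50 + k)
      pop$weights <- pop$weights * scale
      r <- run_free(pop, pats[[k]]$times * 1000)
      r$n_spikes / length(pats[[k]]$times)
    }, numeric(1))
    mean(probs)
  }
  p <- vapply(c(0, 4, 16, 64), mean_prob, numeric(1))
  expect_equal(p[1], 0)
  expect_true(all(diff(p) >= 0))
  expect_gt(p[4], p[1])
})

test_that("regime calibration brackets both probability bands", {
  pats <- lapply(1:2, function(s)
    generate_ca3_pattern(ca3_pattern_params(duration = 20, seed = s)))
  cal <- calibrate_regimes(pats, condition_params("control"),
                           bands = list(integrative = c(20, 45),
                                        saturating = c(75, 95)),
                           n_seeds = 4, seed = 1)
  expect_lt(cal$integrative$scale, cal$saturating$scale)
  expect_gte(cal$integrative$probability, 20)
  expect_lte(cal$integrative$probability, 45)
  expect_gte(cal$saturating$probability, 75)
  expect_lte(cal$saturating$probability, 95)
  # a band above anything the cell can reach fails with a clear error
  expect_error(
    calibrate_regimes(pats, condition_params("control"),
                      bands = list(impossible = c(5e4, 5e4 + 1)),
                      n_seeds = 2, seed = 1, max_scale = 64),
    "calibration failure")
})
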