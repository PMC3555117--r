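test_that("named conditions resolve to the shared kinetics", {
  ctrl <- condition_params("control")
  ab <- condition_params("abeta")
  expect_equal(ctrl$U, 0.15)
  expect_equal(ab$U, 0.36)
  for (p in list(ctrl, ab)) {
    expect_equal(p$tau_in, 1)
    expect_equal(p$tau_rec, 50)
    expect_equal(p$tau_facil, 200)
  }
})

test_that("trial seeds derive deterministically from the master seed", {
  expect_identical(ca1stp:::derive_seed(1, 5, 3), ca1stp:::derive_seed(1, 5, 3))
  expect_false(ca1stp:::derive_seed(1, 5, 3) == ca1stp:::derive_seed(1, 5, 4))
  expect_false(ca1stp:::derive_seed(1, 5, 3) == ca1stp:::derive_seed(2, 5, 3))
  s <- vapply(1:100, function(i) ca1stp:::derive_seed(7, 1, i), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
})

test_that("the validation protocol contrasts the two conditions", {
  cfg <- experiment_config(n_trials = 3)
  res <- run_validation(cfg)
  ctrl <- res$aggregate[res$aggregate$condition == "control", ]
  ab <- res$aggregate[res$aggregate$condition == "abeta", ]
  expect_equal(ctrl$mean[ctrl$pulse == 1], 1)
  expect_true(all(ctrl$mean[ctrl$pulse >= 2] > 1))
  expect_gt(ab$mean[ab$pulse == 2], 1)
  expect_true(all(ab$mean[ab$pulse >= 3] < 1))
  # byte-identical rerun under the same config and master seed
  res2 <- run_validation(cfg)
  expect_identical(res$per_trial, res2$per_trial)
  # aggregates recomputable from the per-trial table
  sub <- res$per_trial[res$per_trial$condition == "control" &
                         res$per_trial$pulse == 3, "normalized"]
  expect_identical(mean(sub), ctrl$mean[ctrl$pulse == 3])
  expect_identical(sem(sub), ctrl$sem[ctrl$pulse == 3])
  # single-pulse protocol is flat
  flat <- run_validation(experiment_config(n_trials = 1), n_pulses = 1)
  expect_true(all(flat$aggregate$mean == 1))
})

test_that("the frequency sweep reproduces the qualitative regimes", {
  cfg <- experiment_config(n_trials = 2)
  res <- run_frequency_sweep(cfg, frequencies = c(10, 40, 150))
  get <- function(cond, f) {
    sub <- res$aggregate[res$aggregate$condition == cond &
                           res$aggregate$frequency == f, ]
    sub$mean[order(sub$pulse)]
  }
  # 10 Hz: both facilitate, control more strongly
  expect_true(all(get("control", 10)[-1] > 1))
  expect_true(all(get("abeta", 10)[-1] > 1))
  expect_gt(max(get("control", 10)), max(get("abeta", 10)))
  # 40 Hz: elevated release probability turns bimodal, control still grows
  ab40 <- get("abeta", 40)
  expect_gt(max(ab40), ab40[1])
  expect_lt(ab40[10], max(ab40))
  ctrl40 <- get("control", 40)
  expect_true(all(diff(ctrl40) > -1e-9))
  # 150 Hz: under elevated release the curve declines monotonically from
  # the pulse-2 peak into deep depression, ending below control
  ab150 <- get("abeta", 150)
  expect_true(all(diff(ab150[-1]) < 0))
  expect_true(all(ab150[3:10] < 1))
  expect_lt(ab150[10], get("control", 150)[10])
  expect_warning(run_frequency_sweep(experiment_config(n_trials = 1),
                                     frequencies = 300, n_pulses = 2),
                 "5-200")
})

test_that("weight sweeps produce monotone gain curves with sigmoid fits", {
  pats <- lapply(1:2, function(s)
    generate_ca3_pattern(ca3_pattern_params(duration = 15, seed = s)))
  cfg <- experiment_config(n_trials = 2)
  res <- run_weight_sweep(cfg, weight_scales = c(0, 2, 8, 24, 64),
                          patterns = pats)
  for (cond in c("control", "abeta")) {
    sub <- res$aggregate[res$aggregate$condition == cond, ]
    sub <- sub[order(sub$scale), ]
    expect_equal(sub$mean[sub$scale == 0], 0)
    expect_true(all(diff(sub$mean) >= -1e-9))
  }
  expect_named(res$fits, c("control", "abeta"))
  expect_error(run_weight_sweep(cfg, weight_scales = c(1, 2), patterns = pats),
               "5 weight scales")
})

test_that("natural-drive runs aggregate per pattern and compare conditions", {
  pats <- lapply(1:3, function(s)
    generate_ca3_pattern(ca3_pattern_params(duration = 15, seed = s)))
  cfg <- experiment_config(n_trials = 2)
  res <- run_natural_drive(cfg, "integrative",
                           scales = list(integrative = 8, saturating = 24),
                           patterns = pats)
  expect_equal(sort(unique(res$per_trial$pattern)), 1:3)
  expect_equal(nrow(res$per_trial), 2 * 3 * 2)
  expect_true(all(c("spike_probability", "isi_cv", "theta_probability",
                    "gamma_probability") %in% res$per_pattern$metric))
  sp <- res$tests$spike_probability
  expect_true(is.null(sp) || (sp$p_value >= 0 && sp$p_value <= 1))
  # deterministic rerun
  res2 <- run_natural_drive(cfg, "integrative",
                            scales = list(integrative = 8, saturating = 24),
                            patterns = pats)
  expect_identical(res$per_trial, res2$per_trial)
})
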