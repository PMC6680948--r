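test_that("seizure times honor rate zero, the refractory gap and the seed", {
  cfg <- sim_config(duration = 90 * 86400, sampling_rate = 10, n_channels = 1,
                    seizure_rate = 0)
  expect_identical(simulate_seizure_times(cfg), numeric(0))

  cfg <- sim_config(duration = 90 * 86400, sampling_rate = 10, n_channels = 1,
                    seizure_rate = 4, seed = 11)
  ev <- simulate_seizure_times(cfg)
  expect_gt(length(ev), 0)
  expect_false(is.unsorted(ev, strictly = TRUE))
  expect_true(all(diff(ev) >= 8 * 3600))
  expect_true(all(ev >= 0 & ev < cfg$duration))
  expect_identical(ev, simulate_seizure_times(cfg))
})

test_that("the dead-time corrected process recovers the nominal monthly rate", {
  months <- 10000
  cfg <- sim_config(duration = months * 30 * 86400, sampling_rate = 1,
                    n_channels = 1, seizure_rate = 4, seed = 5)
  ev <- simulate_seizure_times(cfg)
  counts <- tabulate(floor(ev / (30 * 86400)) + 1, nbins = months)
  se <- sd(counts) / sqrt(months)
  expect_lt(abs(mean(counts) - 4), 3 * se)
})

test_that("an unservable rate/refractory combination reports infeasibility", {
  cfg <- sim_config(duration = 30 * 86400, sampling_rate = 1, n_channels = 1,
                    seizure_rate = 100)
  expect_error(simulate_seizure_times(cfg), "infeasible")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration = -1, sampling_rate = 10), "duration")
  expect_error(sim_config(duration = 10, sampling_rate = 10,
                          diary_report_prob = 1.5), "diary_report_prob")
  expect_error(sim_config(duration = 10, sampling_rate = 10,
                          refractory = 600, preictal_horizon = 700),
               "preictal_horizon")
  expect_error(sim_config(duration = 10, sampling_rate = 10,
                          aed_halflife = 0), "aed_halflife")
})

test_that("AED levels follow first-order decay with periodic dosing", {
  # one half-life after a dose, that dose has decayed to half
  cfg <- sim_config(duration = 10 * 3600, sampling_rate = 1, n_channels = 1,
                    aed_halflife = 4 * 3600, aed_dose_interval = 1e9)
  lv <- simulate_aed_levels(cfg, times = c(0, 4 * 3600))
  expect_equal(lv$level[2] / lv$level[1], 0.5, tolerance = 1e-12)

  # dosing interval >> half-life: sawtooth with near-zero troughs
  cfg <- sim_config(duration = 20 * 86400, sampling_rate = 1, n_channels = 1,
                    aed_halflife = 3600, aed_dose_interval = 12 * 3600)
  tt <- seq(0, cfg$duration - 1, by = 600)
  lv <- simulate_aed_levels(cfg, times = tt)$level
  expect_true(all(lv > 0))
  trough <- min(lv[tt %% (12 * 3600) > 11 * 3600])
  expect_lt(trough, 2^(-11) * 1.01)

  # dosing interval << half-life: approaches the geometric plateau
  cfg <- sim_config(duration = 30 * 86400, sampling_rate = 1, n_channels = 1,
                    aed_halflife = 24 * 3600, aed_dose_interval = 3600)
  plateau <- 1 / (1 - 2^(-1 / 24))
  lv <- simulate_aed_levels(cfg, times = 29 * 86400)$level
  expect_equal(lv, plateau, tolerance = 0.05)
})

test_that("diary reporting is thinned and contaminated as configured", {
  ev <- seq(0, 89 * 86400, by = 86400)
  cfg <- sim_config(duration = 90 * 86400, sampling_rate = 1, n_channels = 1,
                    diary_report_prob = 1, diary_false_rate = 0)
  d <- simulate_diary(ev, cfg)
  expect_equal(d$time_s, ev)
  expect_true(all(d$provenance == "true-report"))

  cfg <- sim_config(duration = 3000 * 86400, sampling_rate = 1, n_channels = 1,
                    diary_report_prob = 0.5, diary_false_rate = 0, seed = 9)
  ev <- seq(0, cfg$duration - 1, by = 86400 / 2)
  d <- simulate_diary(ev, cfg)
  ratio <- nrow(d) / length(ev)
  expect_lt(abs(ratio - 0.5), 3 * sqrt(0.25 / length(ev)))
})

test_that("diary distortion spans the observed 0.06-13.51 discrepancy range", {
  # sparse true seizures with frequent spurious entries: ratio above 13
  cfg <- sim_config(duration = 60 * 30 * 86400, sampling_rate = 1,
                    n_channels = 1, diary_report_prob = 0.37,
                    diary_false_rate = 5, seed = 21)
  true_ev <- sort(runif(20, 0, cfg$duration))  # ~0.33 per month
  d <- simulate_diary(true_ev, cfg)
  expect_gt(nrow(d) / length(true_ev), 13)

  # frequent true seizures mostly unreported: ratio below 0.1
  cfg <- sim_config(duration = 60 * 30 * 86400, sampling_rate = 1,
                    n_channels = 1, diary_report_prob = 0.05,
                    diary_false_rate = 0, seed = 22)
  true_ev <- sort(runif(60 * 60, 0, cfg$duration))  # 60 per month
  d <- simulate_diary(true_ev, cfg)
  expect_lt(nrow(d) / length(true_ev), 0.1)
})
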