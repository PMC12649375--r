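test_that("simulated trials honour the shape contract and determinism", {
  p <- sim_profile(n_controls = 2, n_patients = 1, postures = "ST",
                   T_samples = 2000, seed = 1)
  tr <- simulate_trial(p, "control", seed = 10)
  expect_s3_class(tr, "cop_trial")
  expect_equal(names(tr$channels), cop_channel_names)
  expect_true(all(vapply(tr$channels, length, integer(1)) == 2000))
  expect_equal(tr$sampling_rate_hz, 100)
  expect_identical(simulate_trial(p, "control", seed = 10), tr)
  expect_error(simulate_trial(sim_profile(T_samples = 2), "control"),
               NA)  # T = 2 is the minimum
  expect_error(sim_profile(T_samples = 1))
})

test_that("reserve = 1 disables every pathology term exactly", {
  p <- sim_profile(n_controls = 1, n_patients = 1, T_samples = 500,
                   drift_per_sample = 0.01, delay_samples = 50,
                   sway_scale = 3, seed = 2)
  ctrl <- simulate_trial(p, "control", seed = 77)
  pat1 <- simulate_trial(p, "patient", reserve = 1, seed = 77)
  expect_identical(pat1$channels, ctrl$channels)
  pat0 <- simulate_trial(p, "patient", reserve = 0, seed = 77)
  expect_false(isTRUE(all.equal(pat0$channels, ctrl$channels)))
})

test_that("injected drift is recovered by the OLS slope (Monte Carlo)", {
  for (d in c(0.001, 0.005)) {
    p <- sim_profile(n_controls = 1, n_patients = 1, T_samples = 2000,
                     drift_per_sample = d, delay_samples = 0,
                     sway_scale = 1, seed = 3)
    slopes <- unlist(lapply(1:12, function(s) {
      tr <- simulate_trial(p, "patient", reserve = 0, seed = 1000 + s)
      vapply(tr$channels, function(x)
        statistical_features(x)$slope, numeric(1))
    }))
    se <- sd(slopes) / sqrt(length(slopes))
    expect_lt(abs(mean(slopes) - d), 3 * se + 1e-6)
  }
})

test_that("control series are trend-free and dispersion scales as injected", {
  p <- sim_profile(n_controls = 1, n_patients = 1, T_samples = 2000,
                   sway_scale = 2, drift_per_sample = 0,
                   delay_samples = 0, seed = 4)
  ctrl_slopes <- unlist(lapply(1:12, function(s) {
    tr <- simulate_trial(p, "control", seed = 2000 + s)
    vapply(tr$channels, function(x) statistical_features(x)$slope,
           numeric(1))
  }))
  se <- sd(ctrl_slopes) / sqrt(length(ctrl_slopes))
  expect_lt(abs(mean(ctrl_slopes)), 3 * se + 1e-6)

  # patient/control SD ratio approaches sway_scale at reserve = 0
  ratios <- vapply(1:10, function(s) {
    c0 <- simulate_trial(p, "control", seed = 3000 + s)
    p0 <- simulate_trial(p, "patient", reserve = 0, seed = 3000 + s)
    sd(p0$channels[[1]]) / sd(c0$channels[[1]])
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("simulate_cohort counts, labels, clinical gradients and determinism", {
  p <- sim_profile(n_controls = 5, n_patients = 4, postures = c("FT", "ST"),
                   trials_per_posture = 2, T_samples = 100, seed = 6)
  co <- simulate_cohort(p)
  expect_length(co$subjects, 9)
  expect_length(co$trials, 9 * 2 * 2)
  labs <- vapply(co$subjects, function(s) s$label, integer(1))
  expect_equal(sum(labs), 4)

  co2 <- simulate_cohort(p)
  expect_identical(co2, co)

  # clinical gradient: at strong severity, patients average lower
  # grip/ASMI/6MW and higher 5TCS than controls
  p2 <- sim_profile(n_controls = 25, n_patients = 25, postures = "ST",
                    trials_per_posture = 1, T_samples = 10, reserve = 0,
                    seed = 8)
  co3 <- simulate_cohort(p2)
  lab3 <- vapply(co3$subjects, function(s) s$label, integer(1))
  clin <- function(k) vapply(co3$subjects, function(s)
    as.numeric(s$clinical[[k]]), numeric(1))
  expect_lt(mean(clin("grip")[lab3 == 1]), mean(clin("grip")[lab3 == 0]))
  expect_lt(mean(clin("ASMI")[lab3 == 1]), mean(clin("ASMI")[lab3 == 0]))
  expect_lt(mean(clin("MW6")[lab3 == 1]), mean(clin("MW6")[lab3 == 0]))
  expect_gt(mean(clin("TCS5")[lab3 == 1]), mean(clin("TCS5")[lab3 == 0]))
})
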