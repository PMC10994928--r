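test_that("zero-rate simulation produces empty trains", {
  cfg <- sim_config(background_rate = 0, nb_rate = 0, duration_s = 600)
  w <- simulate_well(cfg, treatment_profile("untreated"), 0, seed = 1)
  expect_equal(nrow(w$spikes), 0L)
})

test_that("background spike counts follow the Poisson mean", {
  cfg <- sim_config(background_rate = 2, nb_rate = 0, duration_s = 600,
                    electrodes_per_well = 12)
  w <- simulate_well(cfg, treatment_profile("untreated"), 0, seed = 12)
  counts <- dplyr::count(w$spikes, electrode_id)$n
  expect_length(counts, 12)
  # Poisson(1200): mean 1200, SD sqrt(1200)
  expect_true(all(abs(counts - 1200) <= 3 * sqrt(1200)))
})

test_that("simulated spike trains are sorted, unique and within the recording", {
  cfg <- sim_config(duration_s = 120)
  w <- simulate_well(cfg, treatment_profile("astro_activation"), 6, seed = 3)
  by_el <- split(w$spikes$spike_time_s, w$spikes$electrode_id)
  for (t in by_el) {
    expect_true(all(diff(t) > 0))
    expect_true(all(t >= 0 & t <= 120))
  }
})

test_that("identical seeds give identical simulations", {
  cfg <- sim_config(duration_s = 60)
  a <- simulate_well(cfg, treatment_profile("neuro_activation"), 12, seed = 77)
  b <- simulate_well(cfg, treatment_profile("neuro_activation"), 12, seed = 77)
  expect_identical(a, b)
  tc1 <- simulate_timecourse(sim_config(n_wells = 2, duration_s = 30),
                             treatment_profile("untreated"),
                             timepoints_h = c(0, 2), seed = 9)
  tc2 <- simulate_timecourse(sim_config(n_wells = 2, duration_s = 30),
                             treatment_profile("untreated"),
                             timepoints_h = c(0, 2), seed = 9)
  expect_identical(tc1, tc2)
})

test_that("treatment profiles respect their contracts", {
  for (nm in c("untreated", "neuro_activation", "astro_activation", "lactate")) {
    p <- treatment_profile(nm)
    expect_equal(p$mfr_multiplier(0), 1)
    expect_equal(p$nbr_multiplier(0), 1)
    expect_equal(p$nbd_multiplier(0), 1)
    tt <- seq(0, 48, by = 2)
    expect_true(all(p$mfr_multiplier(tt) >= 0))
    expect_true(all(p$nbr_multiplier(tt) >= 0))
    expect_true(all(p$nbd_multiplier(tt) > 0))
  }
  # untreated: network bursting fully inhibited at 24 h
  expect_equal(treatment_profile("untreated")$nbr_multiplier(24), 0)
  # neuronal activation: baseline network bursting through 18 h
  p <- treatment_profile("neuro_activation")
  expect_true(all(p$nbr_multiplier(seq(0, 18, by = 2)) == 1))
})

test_that("untreated simulation at 24 h contains no ground-truth events", {
  w <- simulate_well(sim_config(duration_s = 600), treatment_profile("untreated"),
                     24, seed = 4)
  expect_equal(nrow(w$ground_truth$events), 0L)
})

test_that("simulated events recruit at least 4 spikes per participant", {
  cfg <- sim_config(duration_s = 300, nb_participation = 1)
  w <- simulate_well(cfg, treatment_profile("untreated"), 0, seed = 15)
  ev <- w$ground_truth$events
  for (k in seq_len(nrow(ev))) {
    for (el in w$ground_truth$participants[[k]]) {
      t <- w$spikes$spike_time_s[w$spikes$electrode_id == el]
      n_in <- sum(t >= ev$start_s[k] - 1e-9 & t <= ev$end_s[k] + 1e-9)
      expect_gte(n_in, 4)
    }
  }
})

test_that("non-finite profile multipliers are rejected", {
  bad <- treatment_profile("untreated")
  bad$nbr_multiplier <- function(t) NaN
  expect_error(simulate_well(sim_config(), bad, 2, seed = 1), "multiplier")
})

test_that("stimulated profiles carry 3-minute epochs in hypoxia recordings only", {
  tc <- simulate_timecourse(sim_config(n_wells = 1, duration_s = 600),
                            treatment_profile("neuro_activation"),
                            timepoints_h = c(0, 2, 4), seed = 2)
  expect_null(tc$stim_epochs[[1]])
  expect_equal(tc$stim_epochs[[2]][[1]], c(0, 180))
  tc0 <- simulate_timecourse(sim_config(n_wells = 1, duration_s = 600),
                             treatment_profile("untreated"),
                             timepoints_h = c(0, 2), seed = 2)
  expect_null(tc0$stim_epochs[[2]])
  expect_error(simulate_timecourse(sim_config(), treatment_profile("untreated"),
                                   timepoints_h = c(2, 4)), "baseline")
})

test_that("empirical firing rates match the generative rates", {
  # rate calibration at a reduced seed count (3 SE band, background only)
  cfg <- sim_config(background_rate = 2, nb_rate = 0, duration_s = 60,
                    electrodes_per_well = 4)
  rates <- unlist(lapply(1:50, function(s) {
    w <- simulate_well(cfg, treatment_profile("untreated"), 0, seed = 100 + s)
    dplyr::count(w$spikes, electrode_id)$n / 60
  }))
  se <- sqrt(2 / 60) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 2), 3 * se)
})

test_that("rendered traces embed spikes recoverable by the detector", {
  # empty train: pure noise, almost no detections
  tr0 <- render_voltage_trace(numeric(0), 10, noise_sd = 1, seed = 8)
  expect_lt(nrow(detect_spikes(tr0)), 3)

  # zero amplitude: distributionally identical to noise
  trA <- render_voltage_trace(seq(1, 9), 10, noise_sd = 1, spike_amplitude = 0,
                              seed = 8)
  expect_identical(trA$voltage_uv, tr0$voltage_uv)

  truth <- seq(0.5, 9.5, length.out = 100)
  tr <- render_voltage_trace(truth, 10, noise_sd = 1, spike_amplitude = 8,
                             seed = 8)
  det <- detect_spikes(tr)
  hits <- sum(vapply(truth, function(t)
    any(abs(det$spike_time_s - t) <= 5e-4), logical(1)))
  expect_gte(hits, 99)

  expect_error(render_voltage_trace(11, 10), "within")
})
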