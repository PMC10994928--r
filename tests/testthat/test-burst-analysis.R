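test_that("max-interval burst detection applies the spike-count, ISI and duration rules", {
  # 4 spikes at 40 ms ISI: one burst, 4 spikes, 120 ms
  b <- detect_bursts(spike_tbl(burst_run(1, 4, 0.04)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 4L)
  expect_equal(b$duration_s, 0.12, tolerance = 1e-12)

  # 3 spikes only: below the minimum
  expect_equal(nrow(detect_bursts(spike_tbl(burst_run(1, 3, 0.04)))), 0L)

  # 10 spikes at 200 ms ISI: above the ISI ceiling
  expect_equal(nrow(detect_bursts(spike_tbl(burst_run(1, 10, 0.2)))), 0L)

  # two 5-spike runs separated by an 80 ms gap merge into one 10-spike burst
  run1 <- burst_run(1, 5, 0.04)
  run2 <- burst_run(max(run1) + 0.08, 5, 0.04)
  merged <- detect_bursts(spike_tbl(c(run1, run2)))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_spikes, 10L)

  # a 30 ms run of 4 spikes fails the 50 ms minimum duration
  expect_equal(nrow(detect_bursts(spike_tbl(burst_run(1, 4, 0.01)))), 0L)
  # 6 spikes at 10 ms span exactly 50 ms and are retained
  b6 <- detect_bursts(spike_tbl(burst_run(1, 6, 0.01)))
  expect_equal(nrow(b6), 1L)
})

test_that("emitted bursts satisfy their invariants on random trains", {
  cfg <- burst_config()
  withr::with_seed(42, {
    for (rep in 1:25) {
      t <- sort(runif(rpois(1, 400), 0, 60))
      bb <- detect_bursts(spike_tbl(t))
      if (nrow(bb)) {
        expect_true(all(bb$n_spikes >= cfg$min_spikes))
        expect_true(all(bb$duration_s >= cfg$min_burst_duration - 1e-9))
        if (nrow(bb) > 1) {
          gaps <- bb$start_s[-1] - bb$end_s[-nrow(bb)]
          expect_true(all(gaps >= cfg$min_interburst_interval - 1e-9))
        }
        # every burst's spikes are really in the train's span
        expect_true(all(bb$start_s >= min(t) & bb$end_s <= max(t)))
      }
    }
  })
})

test_that("bursting-channel classification uses the 0.4 bursts/min boundary inclusively", {
  mk <- function(n_bursts) {
    times <- unlist(lapply(seq_len(n_bursts), function(k) burst_run(k * 60, 5, 0.04)))
    detect_bursts(spike_tbl(times))
  }
  expect_true(bursting_channels(mk(4), 600)$bursting)    # 0.4 / min
  expect_false(bursting_channels(mk(3), 600)$bursting)   # 0.3 / min
  empty <- detect_bursts(spike_tbl(numeric(0)))
  expect_equal(nrow(bursting_channels(empty, 600)), 0L)
})

test_that("network bursts need >= 8 distinct channels simultaneously bursting", {
  common <- function(n) dplyr::bind_rows(lapply(seq_len(n), function(i)
    spike_tbl(burst_run(1, 5, 0.04), sprintf("E%02d", i))))

  nb8 <- detect_network_bursts(detect_bursts(common(8)))
  expect_equal(nrow(nb8), 1L)
  expect_equal(nb8$n_channels, 8L)
  expect_equal(nb8$max_simultaneous, 8L)

  expect_equal(nrow(detect_network_bursts(detect_bursts(common(7)))), 0L)

  # 8 channels staggered so only neighbours overlap: fails simultaneity
  staggered <- dplyr::bind_rows(lapply(1:8, function(i)
    spike_tbl(burst_run(1 + (i - 1) * 0.1, 5, 0.04), sprintf("E%02d", i))))
  expect_equal(nrow(detect_network_bursts(detect_bursts(staggered))), 0L)

  expect_equal(nrow(detect_network_bursts(detect_bursts(spike_tbl(numeric(0))))), 0L)
})

test_that("zero-length contact between bursts is not overlap", {
  b <- tibble::tibble(
    electrode_id = c("a", "b"),
    start_s = c(0, 1), end_s = c(1, 2)
  )
  nb <- detect_network_bursts(b, burst_config(nb_min_channels = 2,
                                              nb_min_simultaneous = 2))
  expect_equal(nrow(nb), 0L)
})

test_that("raising the distinct-channel threshold never creates events", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      b <- random_burst_well()
      counts <- vapply(1:12, function(k)
        nrow(detect_network_bursts(b, burst_config(nb_min_channels = k,
                                                   nb_min_simultaneous = 1))),
        integer(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("sweep detector matches the brute-force grid oracle on random wells", {
  cfg <- burst_config()
  withr::with_seed(99, {
    for (rep in 1:60) {
      b <- random_burst_well()
      fast <- detect_network_bursts(b, cfg)
      slow <- brute_force_nb(b, cfg)
      expect_equal(nrow(fast), nrow(slow))
      if (nrow(fast)) {
        expect_equal(unname(fast$channels), slow$channels)
        expect_equal(fast$max_simultaneous, slow$max_simultaneous)
      }
    }
  })
})

test_that("well metrics compute NBR per minute and mean NBD, flagging empty wells", {
  # six synchronized events across 8 channels in 600 s -> NBR 0.6 / min
  sp <- dplyr::bind_rows(lapply(1:8, function(i) {
    spike_tbl(unlist(lapply(0:5, function(k) burst_run(50 + k * 90, 6, 0.04))),
              sprintf("E%02d", i))
  }))
  m <- well_metrics(sp, 600)
  expect_equal(m$nbr, 0.6)
  expect_equal(m$nbd, 0.2, tolerance = 1e-9)  # each event spans 5 * 40 ms
  expect_equal(m$n_events, 6L)

  silent <- well_metrics(spike_tbl(tonic_train(0.2, 600)), 600)
  expect_equal(silent$nbr, 0)
  expect_true(is.na(silent$nbd))
})

test_that("event durations average arithmetically", {
  # two events with durations 0.5 s and 1.5 s -> NBD 1.0 s
  mk_event <- function(t0, dur, n_ch = 8) {
    n_spikes <- round(dur / 0.05) + 1
    dplyr::bind_rows(lapply(seq_len(n_ch), function(i)
      spike_tbl(burst_run(t0, n_spikes, 0.05), sprintf("E%02d", i))))
  }
  sp <- dplyr::bind_rows(mk_event(10, 0.5), mk_event(20, 1.5))
  m <- well_metrics(sp, 600)
  expect_equal(m$nbd, 1.0, tolerance = 1e-9)
})

test_that("pipeline recovers ground-truth event counts on clean synthetic wells", {
  cfg <- sim_config(duration_s = 600, nb_rate = 0.5, nb_participation = 1,
                    background_rate = 0.1)
  hits <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    w <- simulate_well(cfg, treatment_profile("untreated"), 0, seed = 5000 + s)
    m <- well_metrics(w$spikes, 600)
    if (m$n_events == nrow(w$ground_truth$events)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})
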