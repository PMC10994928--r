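# Synthetic MEA recordings with ground truth. Background activity is
# homogeneous Poisson per electrode; network bursts arrive as a Poisson
# process in time, each event recruiting electrodes independently and
# emitting a fast run of spikes with gamma-distributed intra-burst ISIs.
# Treatment profiles scale the generative rates as a function of hours in
# hypoxia, emulating the phenomenology of an untreated decline, optogenetic
# neuronal activation, astrocyte activation and exogenous lactate.

#' Simulation settings for synthetic MEA wells
#'
#' The default geometry and schedule emulate a 24-well MEA plate with 12
#' electrodes per well and 10-minute recordings. Default activity levels
#' describe a functionally mature culture: ~2 spikes/s background per
#' electrode, 6 network bursts/min of ~0.5 s recruiting ~90% of
#' electrodes with 20 ms mean intra-burst ISIs. Defaults are chosen so
#' recovery experiments measure the detectors rather than generator
#' marginality: the intra-burst ISI sits well inside the burst detector's
#' ISI window, and the event rate gives a 10-minute recording enough
#' events (~60) that per-well normalized rates carry only a few percent of
#' sampling noise.
#'
#' @param n_wells Number of wells per simulated plate (default 24).
#' @param electrodes_per_well Electrodes per well (default 12).
#' @param duration_s Recording duration, seconds (default 600).
#' @param background_rate Background firing, spikes/s per electrode
#'   (default 2).
#' @param nb_rate Network-burst events per minute (default 6).
#' @param nb_duration_mean Mean network-burst duration, seconds
#'   (default 0.5).
#' @param nb_participation Probability that an electrode joins an event
#'   (default 0.9).
#' @param intra_burst_isi_mean Mean intra-burst inter-spike interval,
#'   seconds (default 0.02).
#' @param seed Optional integer seed giving fully reproducible output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_wells = 24,
                       electrodes_per_well = 12,
                       duration_s = 600,
                       background_rate = 2,
                       nb_rate = 6,
                       nb_duration_mean = 0.5,
                       nb_participation = 0.9,
                       intra_burst_isi_mean = 0.02,
                       seed = NULL) {
  stopifnot(
    n_wells >= 1, electrodes_per_well >= 1, duration_s > 0,
    background_rate >= 0, nb_rate >= 0, nb_duration_mean > 0,
    nb_participation >= 0, nb_participation <= 1, intra_burst_isi_mean > 0
  )
  structure(
    list(
      n_wells = as.integer(n_wells),
      electrodes_per_well = as.integer(electrodes_per_well),
      duration_s = duration_s,
      background_rate = background_rate,
      nb_rate = nb_rate,
      nb_duration_mean = nb_duration_mean,
      nb_participation = nb_participation,
      intra_burst_isi_mean = intra_burst_isi_mean,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Treatment profiles for the hypoxia time-course
#'
#' A profile is a set of multiplier functions of hours-in-hypoxia applied
#' to the generative mean firing rate, network-burst rate and
#' network-burst duration. All multipliers equal 1 at t = 0 (normoxia
#' baseline) and are non-negative. Built-in profiles encode figure-level
#' phenomenology:
#'
#' * `untreated` — NBR follows a smooth cosine ramp reaching exactly 0 at
#'   24 h (complete inhibition of network bursts); MFR decays
#'   exponentially with time constant `mfr_tau_h` (default 12 h).
#' * `neuro_activation` — NBR held at baseline (multiplier 1) through 18 h,
#'   then declining linearly to 0.7 at 24 h; MFR maintained at higher
#'   levels (time constant 48 h). Stimulated (3-min light epochs).
#' * `astro_activation` — network bursts become slightly more frequent and
#'   markedly shorter (NBD multiplier falling to 0.7); MFR time constant
#'   36 h. Stimulated.
#' * `lactate` — immediate concentration-dependent blunting of activity
#'   before hypoxia onset: MFR and NBR drop rapidly towards 30%/50% of
#'   baseline.
#'
#' @param name One of `"untreated"`, `"neuro_activation"`,
#'   `"astro_activation"`, `"lactate"`.
#' @param mfr_tau_h Exponential MFR decay time constant in hours for the
#'   untreated profile (default 12).
#' @return A list of class `treatment_profile` with elements `name`,
#'   `mfr_multiplier`, `nbr_multiplier`, `nbd_multiplier` (functions of
#'   hours) and `stimulated` (logical).
#' @export
treatment_profile <- function(name = c("untreated", "neuro_activation",
                                       "astro_activation", "lactate"),
                              mfr_tau_h = 12) {
  name <- match.arg(name)
  prof <- switch(name,
    untreated = list(
      mfr = function(t) exp(-t / mfr_tau_h),
      nbr = function(t) ifelse(t >= 24, 0, 0.5 * (1 + cos(pi * t / 24))),
      nbd = function(t) rep(1, length(t)),
      stimulated = FALSE
    ),
    neuro_activation = list(
      mfr = function(t) exp(-t / 48),
      nbr = function(t) ifelse(t <= 18, 1, pmax(0.7, 1 - 0.05 * (t - 18))),
      nbd = function(t) rep(1, length(t)),
      stimulated = TRUE
    ),
    astro_activation = list(
      mfr = function(t) exp(-t / 36),
      nbr = function(t) 1 + 0.15 * pmin(t, 6) / 6,
      nbd = function(t) 1 - 0.3 * pmin(t, 6) / 6,
      stimulated = TRUE
    ),
    lactate = list(
      mfr = function(t) 0.3 + 0.7 * exp(-t / 0.5),
      nbr = function(t) 0.5 + 0.5 * exp(-t / 0.5),
      nbd = function(t) rep(1, length(t)),
      stimulated = FALSE
    )
  )
  structure(
    list(name = name, mfr_multiplier = prof$mfr, nbr_multiplier = prof$nbr,
         nbd_multiplier = prof$nbd, stimulated = prof$stimulated),
    class = "treatment_profile"
  )
}

.check_multiplier <- function(m, what) {
  if (!is.finite(m) || m < 0)
    stop("profile ", what, " multiplier must be finite and non-negative")
  m
}

# gamma-ISI spike run of length >= 4 over [start, start + dur]
.burst_train <- function(start, dur, isi_mean) {
  k <- max(8L, ceiling(3 * dur / isi_mean))
  isis <- stats::rgamma(k, shape = 2, rate = 2 / isi_mean)
  tt <- cumsum(isis)
  tt <- tt[tt <= dur]
  if (length(tt) < 3L) tt <- seq_len(3L) * dur / 3  # degenerate fallback
  start + c(0, tt)
}

.simulate_well_impl <- function(cfg, profile, hours, well_id) {
  m_mfr <- .check_multiplier(profile$mfr_multiplier(hours), "MFR")
  m_nbr <- .check_multiplier(profile$nbr_multiplier(hours), "NBR")
  m_nbd <- .check_multiplier(profile$nbd_multiplier(hours), "NBD")
  D <- cfg$duration_s
  ne <- cfg$electrodes_per_well
  eids <- sprintf("E%02d", seq_len(ne))
  # background: homogeneous Poisson per electrode
  bg_rate <- cfg$background_rate * m_mfr
  bg <- lapply(seq_len(ne), function(i) {
    n <- stats::rpois(1, bg_rate * D)
    sort(stats::runif(n, 0, D))
  })
  # network-burst events: Poisson process in time
  ev_dur <- cfg$nb_duration_mean * m_nbd
  n_ev <- stats::rpois(1, cfg$nb_rate / 60 * m_nbr * D)
  ev_start <- sort(stats::runif(n_ev, 0, max(D - ev_dur, 0)))
  ev_spikes <- vector("list", ne)
  participants <- vector("list", max(n_ev, 0L))
  if (n_ev > 0) {
    for (k in seq_len(n_ev)) {
      joins <- stats::runif(ne) < cfg$nb_participation
      participants[[k]] <- eids[joins]
      for (i in which(joins)) {
        ev_spikes[[i]] <- c(ev_spikes[[i]],
                            .burst_train(ev_start[k], ev_dur, cfg$intra_burst_isi_mean))
      }
    }
  }
  spikes <- dplyr::bind_rows(lapply(seq_len(ne), function(i) {
    t <- sort(unique(c(bg[[i]], ev_spikes[[i]])))
    t <- t[t >= 0 & t <= D]
    tibble::tibble(well_id = well_id, electrode_id = eids[i], spike_time_s = t)
  }))
  ground_truth <- list(
    events = tibble::tibble(
      start_s = ev_start, end_s = ev_start + ev_dur,
      n_participants = vapply(participants, length, integer(1))[seq_len(n_ev)]
    ),
    participants = participants,
    multipliers = c(mfr = m_mfr, nbr = m_nbr, nbd = m_nbd),
    hours = hours
  )
  list(spikes = spikes, ground_truth = ground_truth, duration_s = D)
}

#' Simulate one MEA well
#'
#' Generates per-electrode spike trains as homogeneous Poisson background
#' (rate `background_rate * mfr_multiplier(hours)`) superposed with
#' network-burst events arriving as a Poisson process at
#' `nb_rate * nbr_multiplier(hours)`; each event recruits each electrode
#' independently with probability `nb_participation` and emits at least 4
#' spikes at gamma-distributed ISIs over
#' `nb_duration_mean * nbd_multiplier(hours)` seconds. Identical seeds
#' give identical output.
#'
#' @param cfg A [sim_config()].
#' @param profile A [treatment_profile()].
#' @param hours Hours in hypoxia (0 = normoxia baseline).
#' @param well_id Well label.
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @return List with `spikes` (tibble `well_id`, `electrode_id`,
#'   `spike_time_s`), `ground_truth` (true event intervals, participants
#'   and generative multipliers) and `duration_s`.
#' @export
simulate_well <- function(cfg = sim_config(), profile = treatment_profile("untreated"),
                          hours = 0, well_id = "W01", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(profile, "treatment_profile"),
            is.numeric(hours), hours >= 0)
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed)) {
    withr::with_seed(as.integer(seed), .simulate_well_impl(cfg, profile, hours, well_id))
  } else {
    .simulate_well_impl(cfg, profile, hours, well_id)
  }
}

#' Simulate a hypoxia time-course for a plate of wells
#'
#' One recording per well per timepoint, sharing the well's base
#' parameters; for stimulated profiles a 3-minute stimulation epoch (the
#' optogenetic light window delivered every 2 h) is inserted at the start
#' of each hypoxia recording.
#'
#' @param cfg A [sim_config()]; `cfg$n_wells` wells are generated.
#' @param profile A [treatment_profile()].
#' @param timepoints_h Sorted hours, first element 0 (normoxia baseline).
#'   Default: every 2 h over 24 h.
#' @param seed Optional integer master seed; per-recording seeds are
#'   derived from it.
#' @return Tibble with one row per well x timepoint: `well_id`,
#'   `condition`, `timepoint_h`, `duration_s`, and list-columns `spikes`,
#'   `ground_truth`, `stim_epochs`.
#' @export
simulate_timecourse <- function(cfg = sim_config(), profile = treatment_profile("untreated"),
                                timepoints_h = seq(0, 24, by = 2), seed = NULL) {
  stopifnot(length(timepoints_h) >= 1)
  if (is.unsorted(timepoints_h)) stop("timepoints must be sorted")
  if (timepoints_h[1] != 0) stop("first timepoint must be the normoxia baseline (0 h)")
  seed <- if (!is.null(seed)) seed else cfg$seed
  epochs <- if (profile$stimulated) list(c(0, 180)) else NULL
  grid <- tidyr::expand_grid(
    well = seq_len(cfg$n_wells),
    timepoint_h = timepoints_h
  )
  # per-recording sub-seeds drawn from the master-seeded RNG (arithmetic
  # seed schedules give poorly decorrelated Mersenne-Twister streams)
  sub_seeds <- if (is.null(seed)) NULL else
    withr::with_seed(as.integer(seed), sample.int(2147483646L, nrow(grid)))
  rows <- purrr::pmap(cbind(grid, i = seq_len(nrow(grid))),
                      function(well, timepoint_h, i) {
    rec <- simulate_well(cfg, profile, hours = timepoint_h,
                         well_id = sprintf("W%02d", well),
                         seed = if (is.null(sub_seeds)) NULL else sub_seeds[i])
    tibble::tibble(
      well_id = sprintf("W%02d", well),
      condition = profile$name,
      timepoint_h = timepoint_h,
      duration_s = rec$duration_s,
      spikes = list(rec$spikes),
      ground_truth = list(rec$ground_truth),
      stim_epochs = list(if (timepoint_h > 0) epochs else NULL)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-well metrics for a simulated (or assembled) time-course
#'
#' Runs [well_metrics()] on every row of a [simulate_timecourse()] table,
#' masking the row's stimulation epochs, and returns a flat metrics tibble
#' ready for [normalize_to_baseline()].
#'
#' @param tc Tibble as returned by [simulate_timecourse()].
#' @param detection A [detection_config()].
#' @param burst A [burst_config()].
#' @return Tibble: `well_id`, `condition`, `timepoint_h`, `mfr`, `nbr`,
#'   `nbd`, `n_active`, `n_bursting`, `n_events`, `analyzed_duration_s`.
#' @export
timecourse_metrics <- function(tc, detection = detection_config(),
                               burst = burst_config()) {
  stopifnot(is.data.frame(tc),
            all(c("well_id", "timepoint_h", "spikes", "duration_s") %in% names(tc)))
  rows <- purrr::pmap(
    list(tc$spikes, tc$duration_s, tc$stim_epochs, tc$well_id,
         tc$timepoint_h, tc$condition),
    function(sp, dur, ep, w, tp, cond) {
      m <- well_metrics(sp, dur, stim_epochs = ep,
                        detection = detection, burst = burst)
      m$well_id <- w
      m$timepoint_h <- tp
      m$condition <- cond
      m
    }
  )
  dplyr::bind_rows(rows) |>
    dplyr::select("well_id", "condition", "timepoint_h", dplyr::everything())
}

#' Default biphasic spike waveform template
#'
#' A short biphasic extracellular spike shape with a single dominant
#' positive peak normalized to 1 (total span ~0.7 ms at 10 kHz); used by
#' [render_voltage_trace()].
#'
#' @return Numeric vector of template samples, peak absolute value 1.
#' @export
biphasic_template <- function() {
  c(-0.10, -0.35, 1.00, -0.40, -0.15, -0.05)
}

#' Render a spike train as a raw voltage trace
#'
#' Gaussian noise of standard deviation `noise_sd` plus a scaled biphasic
#' waveform at each spike time, sampled at `sampling_rate`. The template
#' peak coincides with the spike time.
#'
#' @param spike_times Numeric vector of spike times, seconds, within
#'   `[0, duration_s]`.
#' @param duration_s Trace duration, seconds.
#' @param noise_sd Noise SD in µV (default 10).
#' @param spike_amplitude Peak absolute spike amplitude in µV (default 80).
#' @param sampling_rate Hz (default 10000).
#' @param waveform Template samples with peak absolute value 1.
#' @param seed Optional integer seed for the noise.
#' @return Tibble with `time_s`, `voltage_uv`.
#' @export
render_voltage_trace <- function(spike_times, duration_s,
                                 noise_sd = 10, spike_amplitude = 80,
                                 sampling_rate = 10000,
                                 waveform = biphasic_template(),
                                 seed = NULL) {
  stopifnot(duration_s > 0, noise_sd >= 0, sampling_rate > 0)
  if (length(spike_times) && (min(spike_times) < 0 || max(spike_times) > duration_s))
    stop("spike times must lie within [0, duration_s]")
  render <- function() {
    n <- as.integer(round(duration_s * sampling_rate))
    v <- stats::rnorm(n, 0, noise_sd)
    if (length(spike_times)) {
      peak_off <- which.max(abs(waveform)) - 1L
      w <- spike_amplitude * waveform
      for (t in spike_times) {
        i0 <- as.integer(round(t * sampling_rate)) + 1L - peak_off
        ii <- i0:(i0 + length(w) - 1L)
        ok <- ii >= 1L & ii <= n
        v[ii[ok]] <- v[ii[ok]] + w[ok]
      }
    }
    tibble::tibble(time_s = (seq_len(n) - 1L) / sampling_rate, voltage_uv = v)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), render()) else render()
}
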