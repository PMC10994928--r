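# Threshold-based multi-unit spike detection on extracellular MEA traces.
# Traces are tibbles with columns `time_s` and `voltage_uv`, sampled at a
# constant rate (10 kHz by default throughout the package).

# comparisons of continuous quantities against printed thresholds use a small
# absolute tolerance so exact boundary constructions are not lost to rounding
.EPS <- 1e-9

#' Spike-detection settings
#'
#' Bundles the parameters of the threshold-crossing spike detector. The
#' defaults reproduce a standard multiwell-MEA analysis chain: signals
#' band-passed at 100–3500 Hz, events detected when the trace exceeds 4.5
#' times the standard deviation of the baseline noise, and an electrode
#' called active when it fires at least 0.1 spikes/s.
#'
#' @param threshold_multiplier Detection threshold as a multiple of the
#'   baseline-noise standard deviation (default 4.5).
#' @param filter_band Two-element numeric vector, band-pass edges in Hz
#'   (default `c(100, 3500)`).
#' @param dead_time Seconds; threshold excursions closer than this are
#'   collapsed to the first event (default 1 ms). Prevents double-counting
#'   the two lobes of a biphasic waveform.
#' @param active_rate_threshold Spikes/s at or above which an electrode is
#'   classified as active (default 0.1).
#' @param polarity Which excursions count: `"both"` (default), `"negative"`
#'   or `"positive"`.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_multiplier = 4.5,
                             filter_band = c(100, 3500),
                             dead_time = 0.001,
                             active_rate_threshold = 0.1,
                             polarity = c("both", "negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(
    is.numeric(threshold_multiplier), threshold_multiplier > 0,
    length(filter_band) == 2L, filter_band[1] > 0, filter_band[2] > filter_band[1],
    dead_time >= 0, active_rate_threshold >= 0
  )
  structure(
    list(
      threshold_multiplier = threshold_multiplier,
      filter_band = as.numeric(filter_band),
      dead_time = dead_time,
      active_rate_threshold = active_rate_threshold,
      polarity = polarity
    ),
    class = "detection_config"
  )
}

.trace_fs <- function(trace, sampling_rate = NULL) {
  if (!is.null(sampling_rate)) return(sampling_rate)
  dt <- stats::median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from `time_s`")
  round(1 / dt)
}

#' Zero-phase band-pass filter for a voltage trace
#'
#' Applies an order-4 Butterworth-magnitude band-pass in the frequency
#' domain. Because only the magnitude response is applied, the filter is
#' exactly zero-phase: spike times are not shifted. Trace length is
#' preserved.
#'
#' @param trace Tibble with columns `time_s`, `voltage_uv`.
#' @param band Band edges in Hz; both must lie below the Nyquist frequency.
#' @param order Butterworth order (default 4).
#' @param sampling_rate Hz; inferred from `time_s` when `NULL`.
#' @return The trace tibble with `voltage_uv` replaced by the filtered signal.
#' @export
band_pass_filter <- function(trace, band = c(100, 3500), order = 4,
                             sampling_rate = NULL) {
  stopifnot(is.data.frame(trace), all(c("time_s", "voltage_uv") %in% names(trace)))
  fs <- .trace_fs(trace, sampling_rate)
  if (band[2] >= fs / 2) stop("upper band edge must be below the Nyquist frequency")
  x <- trace$voltage_uv
  if (!all(is.finite(x))) stop("trace contains non-finite samples")
  n <- length(x)
  freqs <- seq(0, n - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum folds at Nyquist
  hp <- 1 / sqrt(1 + (band[1] / pmax(freqs, .EPS))^(2 * order))
  lp <- 1 / sqrt(1 + (freqs / band[2])^(2 * order))
  h <- hp * lp
  h[1] <- 0  # DC removed
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  trace$voltage_uv <- y
  trace
}

#' Robust estimate of the baseline-noise standard deviation
#'
#' Median-absolute-deviation estimate scaled to the Gaussian SD, so that
#' sparse large spikes do not inflate the estimate of the noise floor.
#' An all-constant trace returns 0.
#'
#' @param trace Tibble with a `voltage_uv` column (already band-passed).
#' @return Noise SD in the units of `voltage_uv`.
#' @export
estimate_noise_sd <- function(trace) {
  stopifnot(is.data.frame(trace), "voltage_uv" %in% names(trace))
  stats::mad(trace$voltage_uv)
}

#' Detect spikes by threshold crossing
#'
#' Marks one event per excursion of the trace beyond
#' `threshold_multiplier` times the baseline-noise SD (estimated robustly
#' from the same trace). The event time is the sample at the excursion's
#' extremum; excursions closer than `dead_time` are collapsed to the first.
#' The trace is assumed already band-passed; set `filter = TRUE` to apply
#' [band_pass_filter()] with `config$filter_band` first.
#'
#' @param trace Tibble with `time_s`, `voltage_uv`.
#' @param config A [detection_config()].
#' @param filter Band-pass the trace internally first? Default `FALSE`.
#' @param sampling_rate Hz; inferred when `NULL`.
#' @return Tibble with columns `spike_time_s`, `amplitude_uv` (signed value
#'   at the extremum), sorted by time.
#' @export
detect_spikes <- function(trace, config = detection_config(), filter = FALSE,
                          sampling_rate = NULL) {
  stopifnot(is.data.frame(trace), all(c("time_s", "voltage_uv") %in% names(trace)))
  fs <- .trace_fs(trace, sampling_rate)
  if (isTRUE(filter)) trace <- band_pass_filter(trace, config$filter_band, sampling_rate = fs)
  x <- trace$voltage_uv
  sd_noise <- estimate_noise_sd(trace)
  thr <- config$threshold_multiplier * sd_noise
  over <- switch(config$polarity,
    both = abs(x) > thr,
    negative = x < -thr,
    positive = x > thr
  )
  idx <- which(over)
  if (length(idx) == 0L || thr <= 0) {
    return(tibble::tibble(spike_time_s = numeric(0), amplitude_uv = numeric(0)))
  }
  gap <- max(1L, as.integer(round(config$dead_time * fs)))
  grp <- cumsum(c(1L, as.integer(diff(idx) > gap)))
  peak <- vapply(split(idx, grp), function(ii) ii[which.max(abs(x[ii]))], integer(1))
  peak <- sort(unname(peak))
  # final pass: enforce the dead time between the emitted events themselves
  if (length(peak) > 1L && config$dead_time > 0) {
    keep <- logical(length(peak))
    last <- -Inf
    tt <- trace$time_s[peak]
    for (i in seq_along(peak)) {
      if (tt[i] - last > config$dead_time - .EPS) {
        keep[i] <- TRUE
        last <- tt[i]
      }
    }
    peak <- peak[keep]
  }
  tibble::tibble(spike_time_s = trace$time_s[peak], amplitude_uv = x[peak])
}

.group_cols <- function(spikes) intersect(c("well_id", "electrode_id"), names(spikes))

#' Classify active electrodes
#'
#' An electrode is active when its mean firing rate over the analyzed
#' window is at least `active_rate_threshold` (0.1 spikes/s by default).
#'
#' @param spikes Tibble of spike times with columns `electrode_id`,
#'   `spike_time_s` and optionally `well_id`.
#' @param duration_s Analyzed duration in seconds (after any stimulation
#'   masking); must be > 0.
#' @param config A [detection_config()].
#' @param electrodes Optional vector of all electrode ids in the well(s);
#'   electrodes with no spikes are then reported as inactive rather than
#'   dropped.
#' @return Tibble with `electrode_id` (and `well_id` when present),
#'   `n_spikes`, `rate_hz`, `active`.
#' @export
active_electrodes <- function(spikes, duration_s, config = detection_config(),
                              electrodes = NULL) {
  stopifnot(is.data.frame(spikes), "electrode_id" %in% names(spikes))
  if (!is.numeric(duration_s) || duration_s <= 0) stop("`duration_s` must be > 0")
  gc <- .group_cols(spikes)
  out <- spikes |>
    dplyr::count(dplyr::across(dplyr::all_of(gc)), name = "n_spikes")
  if (!is.null(electrodes)) {
    if ("well_id" %in% gc) {
      wells <- unique(spikes$well_id)
      full <- tidyr::expand_grid(well_id = wells, electrode_id = electrodes)
    } else {
      full <- tibble::tibble(electrode_id = electrodes)
    }
    out <- dplyr::left_join(full, out, by = gc) |>
      dplyr::mutate(n_spikes = dplyr::coalesce(.data$n_spikes, 0L))
  }
  out |>
    dplyr::mutate(
      rate_hz = .data$n_spikes / duration_s,
      active = .data$rate_hz >= config$active_rate_threshold - .EPS
    )
}

#' Mean firing rate over active electrodes
#'
#' The well-level mean firing rate (MFR) is the average spikes-per-second
#' over the electrodes classified as active; inactive electrodes are
#' excluded. A well with no active electrode has MFR 0 (so that normalized
#' time-courses can reach full silencing).
#'
#' @inheritParams active_electrodes
#' @return Tibble with one row per well (`well_id` if present): `mfr`,
#'   `n_active`.
#' @export
mean_firing_rate <- function(spikes, duration_s, config = detection_config(),
                             electrodes = NULL) {
  act <- active_electrodes(spikes, duration_s, config, electrodes)
  wc <- intersect("well_id", names(act))
  act |>
    dplyr::group_by(dplyr::across(dplyr::all_of(wc))) |>
    dplyr::summarise(
      mfr = if (any(.data$active)) mean(.data$rate_hz[.data$active]) else 0,
      n_active = sum(.data$active),
      .groups = "drop"
    )
}

#' Empirical decision boundary of the spike-amplitude threshold
#'
#' Behavioral sweep recovering the detector's amplitude threshold (in
#' units of the true noise SD) from synthetic traces: for each amplitude,
#' isolated biphasic pulses are injected into unit-SD Gaussian noise and
#' the fraction recovered (a detected spike within 0.5 ms of a pulse) is
#' measured; a probit regression of recovery against amplitude pools the
#' whole sweep and the boundary is its 50% point (the amplitude equally
#' likely to be detected or missed).
#'
#' @param amplitudes Pulse amplitudes to sweep, in units of the noise SD.
#' @param n_pulses Pulses injected per amplitude (default 100).
#' @param duration_s Trace duration per amplitude (default 10 s at 10 kHz).
#' @param config A [detection_config()].
#' @param seed Optional integer seed.
#' @return The empirical boundary (noise-SD multiples).
#' @export
spike_threshold_boundary <- function(amplitudes = seq(2, 7, by = 0.1),
                                     n_pulses = 100, duration_s = 10,
                                     config = detection_config(),
                                     seed = NULL) {
  run <- function() {
    times <- seq(0.05, duration_s - 0.05, length.out = n_pulses)
    frac <- vapply(amplitudes, function(a) {
      tr <- render_voltage_trace(times, duration_s, noise_sd = 1,
                                 spike_amplitude = a)
      det <- detect_spikes(tr, config)
      mean(vapply(times, function(t)
        any(abs(det$spike_time_s - t) <= 5e-4), logical(1)))
    }, numeric(1))
    if (max(frac) < 0.5 || min(frac) >= 0.5)
      stop("sweep range does not bracket the decision boundary")
    k <- round(frac * n_pulses)
    fit <- stats::glm(cbind(k, n_pulses - k) ~ amplitudes,
                      family = stats::binomial("probit"))
    unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}
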