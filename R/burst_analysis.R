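# Single-channel burst detection (max-interval scheme) and network-burst
# detection by temporal-overlap chaining, with per-well summary metrics.

#' Burst and network-burst detection settings
#'
#' Defaults mirror a standard multiwell-MEA analyzer configuration: a burst
#' needs at least 4 spikes, opens at an inter-spike interval (ISI) of at
#' most 50 ms and continues while ISIs stay within 100 ms; candidate bursts
#' separated by less than 100 ms are merged and bursts shorter than 50 ms
#' are discarded. A channel bursting at >= 0.4 bursts/min is a "bursting
#' channel". A network burst requires at least 8 distinct channels and at
#' least 8 simultaneously open bursts at some instant.
#'
#' @param min_spikes Minimum spikes per burst (default 4).
#' @param start_isi_max Seconds; ISI at or below which a burst opens
#'   (default 0.050).
#' @param continue_isi_max Seconds; ISI at or below which an open burst
#'   continues (default 0.100).
#' @param min_interburst_interval Seconds; candidate bursts closer than this
#'   are merged (default 0.100).
#' @param min_burst_duration Seconds; shorter bursts are discarded
#'   (default 0.050).
#' @param bursting_channel_rate Bursts/min at or above which a channel is a
#'   bursting channel (default 0.4).
#' @param nb_min_channels Minimum distinct channels in a network burst
#'   (default 8).
#' @param nb_min_simultaneous Minimum simultaneously bursting channels at
#'   some instant of the event (default 8).
#' @return A list of class `burst_config`.
#' @export
burst_config <- function(min_spikes = 4,
                         start_isi_max = 0.050,
                         continue_isi_max = 0.100,
                         min_interburst_interval = 0.100,
                         min_burst_duration = 0.050,
                         bursting_channel_rate = 0.4,
                         nb_min_channels = 8,
                         nb_min_simultaneous = 8) {
  stopifnot(
    start_isi_max > 0, continue_isi_max > 0, start_isi_max <= continue_isi_max,
    min_interburst_interval > 0, min_burst_duration > 0,
    min_spikes >= 1, bursting_channel_rate >= 0,
    nb_min_channels >= 1, nb_min_simultaneous >= 1
  )
  structure(
    list(
      min_spikes = as.integer(min_spikes),
      start_isi_max = start_isi_max,
      continue_isi_max = continue_isi_max,
      min_interburst_interval = min_interburst_interval,
      min_burst_duration = min_burst_duration,
      bursting_channel_rate = bursting_channel_rate,
      nb_min_channels = as.integer(nb_min_channels),
      nb_min_simultaneous = as.integer(nb_min_simultaneous)
    ),
    class = "burst_config"
  )
}

# max-interval burst scan on one sorted spike-time vector
.max_interval_bursts <- function(t, cfg) {
  empty <- tibble::tibble(
    start_s = numeric(0), end_s = numeric(0),
    n_spikes = integer(0), duration_s = numeric(0)
  )
  n <- length(t)
  if (n < 2L) return(empty)
  isi <- diff(t)
  runs <- rle(isi <= cfg$continue_isi_max + .EPS)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  cs <- integer(0); ce <- integer(0)
  for (k in which(runs$values)) {
    a <- run_start[k]; b <- run_end[k]
    open <- which(isi[a:b] <= cfg$start_isi_max + .EPS)
    if (length(open)) {
      cs <- c(cs, a + open[1L] - 1L)  # index of first spike of the burst
      ce <- c(ce, b + 1L)             # index of last spike of the run
    }
  }
  if (length(cs) == 0L) return(empty)
  # merge candidates separated by less than the minimum inter-burst interval
  if (length(cs) > 1L) {
    ms <- cs[1L]; me <- ce[1L]
    out_s <- integer(0); out_e <- integer(0)
    for (k in 2L:length(cs)) {
      if (t[cs[k]] - t[me] < cfg$min_interburst_interval - .EPS) {
        me <- ce[k]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- cs[k]; me <- ce[k]
      }
    }
    cs <- c(out_s, ms); ce <- c(out_e, me)
  }
  dur <- t[ce] - t[cs]
  nsp <- ce - cs + 1L
  keep <- nsp >= cfg$min_spikes & dur >= cfg$min_burst_duration - .EPS
  tibble::tibble(
    start_s = t[cs[keep]], end_s = t[ce[keep]],
    n_spikes = nsp[keep], duration_s = dur[keep]
  )
}

#' Detect single-channel bursts (max-interval scheme)
#'
#' A burst opens at a spike pair with ISI at most `start_isi_max` and
#' extends while ISIs stay within `continue_isi_max`; candidate bursts
#' separated by less than `min_interburst_interval` are merged, then bursts
#' with fewer than `min_spikes` spikes or shorter than `min_burst_duration`
#' are discarded. The burst span runs from its first to its last spike.
#'
#' @param spikes Tibble with `electrode_id`, `spike_time_s` and optionally
#'   `well_id`; times sorted within electrode (sorted internally otherwise).
#' @param config A [burst_config()].
#' @return Tibble with `well_id` (if present), `electrode_id`, `start_s`,
#'   `end_s`, `n_spikes`, `duration_s`.
#' @export
detect_bursts <- function(spikes, config = burst_config()) {
  stopifnot(is.data.frame(spikes),
            all(c("electrode_id", "spike_time_s") %in% names(spikes)))
  gc <- .group_cols(spikes)
  spikes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gc))) |>
    dplyr::reframe(.max_interval_bursts(sort(.data$spike_time_s), config))
}

#' Classify bursting channels
#'
#' A channel is a bursting channel when it emits at least
#' `bursting_channel_rate` bursts per minute over the analyzed window.
#'
#' @param bursts Burst tibble from [detect_bursts()].
#' @param duration_s Analyzed duration in seconds; must be > 0.
#' @param config A [burst_config()].
#' @return Tibble with `electrode_id` (and `well_id` when present),
#'   `n_bursts`, `burst_rate_min`, `bursting`.
#' @export
bursting_channels <- function(bursts, duration_s, config = burst_config()) {
  stopifnot(is.data.frame(bursts), "electrode_id" %in% names(bursts))
  if (!is.numeric(duration_s) || duration_s <= 0) stop("`duration_s` must be > 0")
  gc <- .group_cols(bursts)
  bursts |>
    dplyr::count(dplyr::across(dplyr::all_of(gc)), name = "n_bursts") |>
    dplyr::mutate(
      burst_rate_min = .data$n_bursts / (duration_s / 60),
      bursting = .data$burst_rate_min >= config$bursting_channel_rate - .EPS
    )
}

# network-burst detection on one well's burst table
.nb_one_well <- function(b, cfg) {
  empty <- tibble::tibble(
    start_s = numeric(0), end_s = numeric(0), n_channels = integer(0),
    max_simultaneous = integer(0), duration_s = numeric(0), channels = list()
  )
  if (nrow(b) == 0L) return(empty)
  b <- b[order(b$start_s, b$end_s), ]
  n <- nrow(b)
  # chains under the transitive closure of strictly positive temporal overlap:
  # a burst joins the current chain iff it starts before the running max end
  # (zero-length contact is not overlap)
  if (n == 1L) {
    chain <- 1L
  } else {
    maxend <- cummax(b$end_s)
    chain <- cumsum(c(TRUE, b$start_s[-1L] >= maxend[-n] - .EPS))
  }
  res <- lapply(split(seq_len(n), chain), function(ii) {
    bb <- b[ii, ]
    chans <- unique(bb$electrode_id)
    # boundary sweep with open intervals: ends processed before starts at ties
    ev <- data.frame(
      time = c(bb$start_s, bb$end_s),
      delta = c(rep(1L, nrow(bb)), rep(-1L, nrow(bb)))
    )
    ev <- ev[order(ev$time, ev$delta), ]
    ms <- max(cumsum(ev$delta))
    list(
      start_s = min(bb$start_s), end_s = max(bb$end_s),
      n_channels = length(chans), max_simultaneous = as.integer(ms),
      channels = list(sort(chans))
    )
  })
  out <- tibble::tibble(
    start_s = unname(vapply(res, `[[`, numeric(1), "start_s")),
    end_s = unname(vapply(res, `[[`, numeric(1), "end_s")),
    n_channels = unname(vapply(res, `[[`, integer(1), "n_channels")),
    max_simultaneous = unname(vapply(res, `[[`, integer(1), "max_simultaneous")),
    channels = unname(lapply(res, function(r) r$channels[[1]]))
  )
  out$duration_s <- out$end_s - out$start_s
  out <- out[out$n_channels >= cfg$nb_min_channels &
               out$max_simultaneous >= cfg$nb_min_simultaneous, ]
  out[order(out$start_s), c("start_s", "end_s", "n_channels",
                            "max_simultaneous", "duration_s", "channels")]
}

#' Detect network bursts
#'
#' Builds chains of single-channel bursts connected by strictly positive
#' temporal overlap (transitively), and emits a network-burst event for each
#' chain that involves at least `nb_min_channels` distinct channels and in
#' which at least `nb_min_simultaneous` bursts are open at some instant
#' (computed by a boundary sweep with open intervals). The event spans from
#' the chain's earliest burst start to its latest burst end.
#'
#' By default all detected bursts participate; pass the subset of bursts on
#' bursting channels if a gated analysis is wanted.
#'
#' @param bursts Burst tibble from [detect_bursts()] (columns
#'   `electrode_id`, `start_s`, `end_s`, optionally `well_id`).
#' @param config A [burst_config()].
#' @return Tibble with `well_id` (if present), `start_s`, `end_s`,
#'   `n_channels`, `max_simultaneous`, `duration_s` and a `channels`
#'   list-column of participating electrode ids.
#' @export
detect_network_bursts <- function(bursts, config = burst_config()) {
  stopifnot(is.data.frame(bursts),
            all(c("electrode_id", "start_s", "end_s") %in% names(bursts)))
  if ("well_id" %in% names(bursts)) {
    bursts |>
      dplyr::group_by(.data$well_id) |>
      dplyr::reframe(.nb_one_well(dplyr::pick(dplyr::everything()), config))
  } else {
    .nb_one_well(bursts, config)
  }
}

#' Per-well activity metrics
#'
#' Computes, per well: mean firing rate over active electrodes (MFR,
#' spikes/s), network-burst rate (NBR, events/min), mean network-burst
#' duration (NBD, s; `NA` when the well has no events), number of active
#' electrodes, number of bursting channels and the analyzed duration.
#' When `stim_epochs` is given, spikes inside the epochs are removed first
#' and all rates use the reduced analyzed duration.
#'
#' @param spikes Spike tibble (`electrode_id`, `spike_time_s`, optionally
#'   `well_id`).
#' @param duration_s Recording duration in seconds.
#' @param stim_epochs Optional stimulation epochs: a two-column matrix /
#'   data frame or list of `c(start, end)` pairs, in seconds.
#' @param detection A [detection_config()].
#' @param burst A [burst_config()].
#' @return Tibble with one row per well.
#' @export
well_metrics <- function(spikes, duration_s, stim_epochs = NULL,
                         detection = detection_config(),
                         burst = burst_config()) {
  stopifnot(is.data.frame(spikes))
  if (!is.null(stim_epochs)) {
    spikes <- mask_stimulation(spikes, stim_epochs)
    duration_s <- analyzed_duration(duration_s, stim_epochs)
  }
  if (duration_s <= 0) stop("analyzed duration must be > 0")
  has_well <- "well_id" %in% names(spikes)
  if (!has_well) spikes <- dplyr::mutate(spikes, well_id = "well")
  mfr <- mean_firing_rate(spikes, duration_s, detection)
  bursts <- detect_bursts(spikes, burst)
  out <- lapply(split(spikes, spikes$well_id), function(sp) {
    w <- sp$well_id[1]
    bw <- bursts[bursts$well_id == w, , drop = FALSE]
    nb <- detect_network_bursts(bw, burst)
    bc <- if (nrow(bw)) bursting_channels(bw, duration_s, burst) else NULL
    tibble::tibble(
      well_id = w,
      nbr = nrow(nb) / (duration_s / 60),
      nbd = if (nrow(nb)) mean(nb$duration_s) else NA_real_,
      n_bursting = if (is.null(bc)) 0L else sum(bc$bursting),
      n_events = nrow(nb)
    )
  })
  res <- dplyr::bind_rows(out) |>
    dplyr::left_join(mfr, by = "well_id") |>
    dplyr::mutate(analyzed_duration_s = duration_s) |>
    dplyr::select("well_id", "mfr", "nbr", "nbd", "n_active", "n_bursting",
                  "n_events", "analyzed_duration_s")
  if (!has_well) res$well_id <- NULL
  res
}
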