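# Shared fixtures and independent oracles, all built in code.

# spike tibble for one electrode
spike_tbl <- function(times, electrode = "E01", well = NULL) {
  out <- tibble::tibble(electrode_id = electrode, spike_time_s = times)
  if (!is.null(well)) out <- dplyr::mutate(out, well_id = well, .before = 1)
  out
}

# a compliant burst run: n spikes at a fixed ISI starting at t0
burst_run <- function(t0, n = 5, isi = 0.04) t0 + (seq_len(n) - 1) * isi

# regular (tonic) train with exactly round(rate * duration) spikes
tonic_train <- function(rate, duration) {
  n <- round(rate * duration)
  if (n == 0) return(numeric(0))
  seq(0, duration, length.out = n + 2)[2:(n + 1)]
}

# independent brute-force network-burst detector on a 1 ms grid:
# at each grid point count channels with an open burst (strict interior);
# events are maximal grid regions with >= 1 open burst (overlap chaining),
# qualified by the same distinct-channel and simultaneity thresholds.
brute_force_nb <- function(bursts, config = burst_config(), grid_ms = 1) {
  if (nrow(bursts) == 0) {
    return(tibble::tibble(n_channels = integer(0), max_simultaneous = integer(0),
                          channels = list()))
  }
  step <- grid_ms / 1000
  tmin <- min(bursts$start_s) - step
  tmax <- max(bursts$end_s) + step
  grid <- seq(tmin, tmax, by = step / 2)  # half-step so interiors are sampled
  open <- sapply(seq_len(nrow(bursts)), function(i)
    grid > bursts$start_s[i] & grid < bursts$end_s[i])
  if (is.null(dim(open))) open <- matrix(open, nrow = length(grid))
  count <- rowSums(open)
  on <- count > 0
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    members <- which(colSums(open[seg, , drop = FALSE]) > 0)
    chans <- sort(unique(bursts$electrode_id[members]))
    ms <- max(count[seg])
    if (length(chans) >= config$nb_min_channels && ms >= config$nb_min_simultaneous) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        n_channels = length(chans), max_simultaneous = as.integer(ms),
        channels = list(chans)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(n_channels = integer(0), max_simultaneous = integer(0),
                          channels = list()))
  }
  dplyr::bind_rows(rows)
}

# random small well of burst intervals on a coarse grid (multiples of 5 ms,
# durations >= 10 ms) so the 1 ms brute-force grid resolves every overlap
random_burst_well <- function(n_channels = 12, max_bursts = 50) {
  n <- sample.int(max_bursts, 1)
  ch <- sprintf("E%02d", sample.int(n_channels, n, replace = TRUE))
  start <- sample.int(4000, n, replace = TRUE) * 0.005
  dur <- sample.int(60, n, replace = TRUE) * 0.005 + 0.005
  tibble::tibble(electrode_id = ch, start_s = start, end_s = start + dur)
}
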