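# Plain-text interchange: spike-time tables as CSV, metrics as JSON.

#' Write / read a spike-time table
#'
#' The CSV layout is `well_id, electrode_id, spike_time_s`, one row per
#' spike.
#'
#' @param spikes Spike tibble.
#' @param path File path.
#' @return `write_spikes_csv()` returns `spikes` invisibly;
#'   `read_spikes_csv()` returns the spike tibble.
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(is.data.frame(spikes), "spike_time_s" %in% names(spikes))
  readr::write_csv(spikes, path)
  invisible(spikes)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write per-well metrics as JSON
#'
#' @param metrics Metrics tibble (e.g. from [well_metrics()] or
#'   [timecourse_metrics()]).
#' @param path File path.
#' @return `metrics`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  jsonlite::write_json(metrics, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}
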