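# Hypoxia time-course assembly: stimulation-window masking, normalization
# of per-well metrics to the normoxia baseline, condition aggregates and
# the statistical comparison harness.

.as_epoch_matrix <- function(epochs) {
  if (is.null(epochs)) return(matrix(numeric(0), ncol = 2))
  if (is.list(epochs) && !is.data.frame(epochs)) epochs <- do.call(rbind, epochs)
  if (is.data.frame(epochs)) epochs <- as.matrix(epochs[, 1:2])
  if (is.vector(epochs)) epochs <- matrix(epochs, ncol = 2, byrow = TRUE)
  storage.mode(epochs) <- "double"
  if (ncol(epochs) != 2 || any(epochs[, 2] <= epochs[, 1]))
    stop("epochs must be (start, end) pairs with end > start")
  epochs <- epochs[order(epochs[, 1]), , drop = FALSE]
  if (nrow(epochs) > 1 && any(epochs[-1, 1] < epochs[-nrow(epochs), 2]))
    stop("stimulation epochs must be disjoint")
  epochs
}

#' Remove spikes that fall inside stimulation windows
#'
#' Spikes with times inside any `[start, end)` epoch are dropped; spike
#' times are not shifted. Use [analyzed_duration()] for the matching
#' duration so downstream rates stay correct.
#'
#' @param spikes Spike tibble with a `spike_time_s` column.
#' @param epochs Stimulation epochs: two-column matrix / data frame or list
#'   of `c(start, end)` pairs, seconds, disjoint.
#' @return The spike tibble with masked rows removed.
#' @export
mask_stimulation <- function(spikes, epochs) {
  stopifnot(is.data.frame(spikes), "spike_time_s" %in% names(spikes))
  ep <- .as_epoch_matrix(epochs)
  if (nrow(ep) == 0L) return(spikes)
  t <- spikes$spike_time_s
  inside <- rep(FALSE, length(t))
  for (k in seq_len(nrow(ep))) inside <- inside | (t >= ep[k, 1] & t < ep[k, 2])
  spikes[!inside, , drop = FALSE]
}

#' Analyzed duration after stimulation masking
#'
#' @param duration_s Full recording duration, seconds.
#' @param epochs Stimulation epochs as in [mask_stimulation()].
#' @return `duration_s` minus the total epoch length; errors if the epochs
#'   cover the whole recording.
#' @export
analyzed_duration <- function(duration_s, epochs) {
  ep <- .as_epoch_matrix(epochs)
  if (nrow(ep) && (min(ep) < 0 || max(ep) > duration_s + .EPS))
    stop("epochs must lie within the recording")
  out <- duration_s - sum(ep[, 2] - ep[, 1])
  if (out <= 0) stop("stimulation epochs cover the whole recording")
  out
}

#' Normalize per-well metric time-courses to the normoxia baseline
#'
#' Each well's MFR, NBR and NBD at every timepoint are divided by that
#' well's value at the baseline timepoint (normoxia). Metrics whose
#' baseline is zero or missing are flagged by an `NA` normalized value and
#' are excluded from that metric's aggregates; the other metrics of the
#' well are still normalized.
#'
#' @param metrics Tibble with columns `well_id`, `timepoint_h` and one or
#'   more of `mfr`, `nbr`, `nbd` (e.g. stacked [well_metrics()] output);
#'   extra columns such as `condition` are carried through.
#' @param baseline_timepoint Hours; the normoxia timepoint (default 0).
#' @param metrics_cols Metric columns to normalize.
#' @return The input tibble with added `<metric>_norm` and
#'   `baseline_<metric>` columns.
#' @export
normalize_to_baseline <- function(metrics, baseline_timepoint = 0,
                                  metrics_cols = c("mfr", "nbr", "nbd")) {
  stopifnot(is.data.frame(metrics),
            all(c("well_id", "timepoint_h") %in% names(metrics)))
  metrics_cols <- intersect(metrics_cols, names(metrics))
  if (length(metrics_cols) == 0L) stop("no metric columns to normalize")
  base <- metrics |>
    dplyr::filter(.data$timepoint_h == baseline_timepoint) |>
    dplyr::select("well_id", dplyr::all_of(metrics_cols)) |>
    dplyr::rename_with(~ paste0("baseline_", .x), dplyr::all_of(metrics_cols))
  missing <- setdiff(unique(metrics$well_id), base$well_id)
  if (length(missing))
    stop("no baseline recording for well(s): ", paste(missing, collapse = ", "))
  out <- dplyr::left_join(metrics, base, by = "well_id")
  for (m in metrics_cols) {
    b <- out[[paste0("baseline_", m)]]
    v <- out[[m]]
    out[[paste0(m, "_norm")]] <- ifelse(!is.na(b) & b > 0, v / b, NA_real_)
  }
  out
}

#' Aggregate normalized metrics by condition
#'
#' Per condition, timepoint and metric: mean, standard error of the mean
#' (sample SD / sqrt(n); `NA` for a single well) and number of contributing
#' wells. Wells flagged `NA` for a metric (zero baseline) are excluded from
#' that metric only.
#'
#' @param normalized Output of [normalize_to_baseline()] with a `condition`
#'   column.
#' @param metrics_cols Normalized metric columns to aggregate.
#' @return Tidy tibble: `condition`, `timepoint_h`, `metric`, `mean`,
#'   `sem`, `n_wells`.
#' @export
aggregate_condition <- function(normalized,
                                metrics_cols = c("mfr_norm", "nbr_norm", "nbd_norm")) {
  stopifnot(is.data.frame(normalized),
            all(c("condition", "timepoint_h") %in% names(normalized)))
  metrics_cols <- intersect(metrics_cols, names(normalized))
  normalized |>
    tidyr::pivot_longer(dplyr::all_of(metrics_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$condition, .data$timepoint_h, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n_wells = dplyr::n(),
      .groups = "drop"
    )
}

.ks_normal_p <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

#' Compare conditions across a time-course
#'
#' Statistical comparison harness over per-well normalized metric values.
#' In `two_group` mode, each timepoint is tested between the two
#' conditions; a Kolmogorov–Smirnov normality screen on both groups picks
#' an unpaired t-test (both normal) or a Mann–Whitney test. In `factorial`
#' mode a two-way ANOVA (condition x timepoint) is fitted and per-timepoint
#' pairwise Welch t-tests are reported post hoc. In both modes Bonferroni
#' adjustment multiplies each p-value by the family size (the number of
#' per-timepoint comparisons), capped at 1.
#'
#' @param data Tibble with columns `condition`, `well_id`, `timepoint_h`
#'   and the value column.
#' @param value_col Name of the value column (default `"nbr_norm"`).
#' @param design `"two_group"` or `"factorial"`.
#' @param normality_alpha Significance level of the KS normality screen
#'   (default 0.05).
#' @return An object of class `mea_comparison`; see [tidy.mea_comparison()]
#'   and [glance.mea_comparison()].
#' @export
compare_conditions <- function(data, value_col = "nbr_norm",
                               design = c("two_group", "factorial"),
                               normality_alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(is.data.frame(data),
            all(c("condition", "timepoint_h", value_col) %in% names(data)))
  df <- data |>
    dplyr::select(condition = "condition", timepoint_h = "timepoint_h",
                  value = dplyr::all_of(value_col)) |>
    dplyr::filter(!is.na(.data$value))
  conds <- sort(unique(df$condition))
  tps <- sort(unique(df$timepoint_h))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  anova_tbl <- NULL
  if (design == "factorial") {
    if (length(conds) < 2) stop("factorial design needs >= 2 conditions")
    fit <- stats::aov(value ~ condition * factor(timepoint_h), data = df)
    s <- summary(fit)[[1]]
    anova_tbl <- tibble::tibble(
      term = trimws(rownames(s)),
      df = s$Df, statistic = s$`F value`, p_value = s$`Pr(>F)`
    )
  }
  rows <- list()
  for (pr in pairs) {
    for (tp in tps) {
      x <- df$value[df$condition == pr[1] & df$timepoint_h == tp]
      y <- df$value[df$condition == pr[2] & df$timepoint_h == tp]
      if (length(x) < 2 || length(y) < 2)
        stop("need >= 2 wells per condition at every timepoint (t = ", tp, " h)")
      if (design == "two_group") {
        normal <- .ks_normal_p(x) > normality_alpha && .ks_normal_p(y) > normality_alpha
        if (normal) {
          tst <- stats::t.test(x, y)
          test_name <- "t-test"
        } else {
          tst <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
          test_name <- "Mann-Whitney"
        }
      } else {
        tst <- stats::t.test(x, y)
        test_name <- "t-test (post hoc)"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        comparison = paste(pr[1], "vs", pr[2]),
        timepoint_h = tp,
        test = test_name,
        statistic = unname(tst$statistic),
        p_value = tst$p.value
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  m <- nrow(res)  # family: every per-timepoint comparison
  res$adjusted_p <- pmin(1, m * res$p_value)
  structure(
    list(results = res, anova = anova_tbl, design = design,
         value_col = value_col, family_size = m),
    class = "mea_comparison"
  )
}

#' @export
print.mea_comparison <- function(x, ...) {
  cat("<mea_comparison> design:", x$design, "| metric:", x$value_col,
      "| Bonferroni family m =", x$family_size, "\n")
  if (!is.null(x$anova)) {
    cat("Two-way ANOVA:\n")
    print(x$anova)
  }
  print(x$results)
  invisible(x)
}

#' Tidy a condition comparison
#'
#' @param x A `mea_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return Tibble with one row per per-timepoint comparison: `comparison`,
#'   `timepoint_h`, `test`, `statistic`, `p_value`, `adjusted_p`.
#' @export
tidy.mea_comparison <- function(x, ...) x$results

#' One-row summary of a condition comparison
#'
#' @param x A `mea_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return Tibble with design, metric, family size, number of significant
#'   comparisons after Bonferroni and the smallest adjusted p-value.
#' @export
glance.mea_comparison <- function(x, ...) {
  tibble::tibble(
    design = x$design,
    metric = x$value_col,
    family_size = x$family_size,
    n_significant = sum(x$results$adjusted_p < 0.05),
    min_adjusted_p = min(x$results$adjusted_p)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
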