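# Live / apoptotic / dead quantification from three-channel fluorescence
# micrographs: per-channel intensity thresholding, nucleus segmentation by
# connected components, reporter-overlap classification and group summaries.
#
# Channel semantics follow the two staining schemes used for hypoxia
# cultures: a nuclear counterstain marks every cell; an apoptosis reporter
# (caspase-3/7) marks apoptotic cells; a death reporter (propidium iodide,
# or a dead-cell nuclear stain) marks dead cells. A nucleus positive in
# both reporter channels counts as dead, not apoptotic; live cells are
# total minus apoptotic minus dead.

#' Threshold a fluorescence channel
#'
#' Otsu's method by default, with a bimodality guard: when the two classes
#' found by Otsu are not separated by more than twice the sum of their
#' within-class standard deviations (as happens on a noise-only channel),
#' no pixel is called foreground. A constant saturated channel returns a
#' full foreground mask with a warning. Fixed thresholds are supported for
#' exact reproduction workflows.
#'
#' @param channel Numeric matrix of intensities (16-bit scale).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold intensity, required when `method = "fixed"`;
#'   pixels strictly above it are foreground.
#' @return Logical matrix, with the threshold used stored in attribute
#'   `"threshold"`.
#' @export
threshold_channel <- function(channel, method = c("otsu", "fixed"),
                              fixed_value = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(channel), is.numeric(channel), length(channel) > 0)
  if (any(channel < 0)) stop("intensities must be non-negative")
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("`fixed_value` is required for method = \"fixed\"")
    mask <- channel > fixed_value
    return(structure(mask, threshold = fixed_value))
  }
  rng <- range(channel)
  if (diff(rng) == 0) {
    warning("constant channel: degenerate threshold, full foreground returned")
    mask <- channel > 0
    return(structure(mask, threshold = rng[1]))
  }
  thr <- .otsu_threshold(channel)
  fg <- channel > thr
  mu0 <- mean(channel[!fg]); mu1 <- mean(channel[fg])
  s0 <- stats::sd(channel[!fg]); s1 <- stats::sd(channel[fg])
  if (is.na(s0)) s0 <- 0
  if (is.na(s1)) s1 <- 0
  if ((mu1 - mu0) <= 2 * (s0 + s1)) {
    # unimodal: Otsu merely bisects the noise — call nothing foreground
    fg <- matrix(FALSE, nrow(channel), ncol(channel))
  }
  structure(fg, threshold = thr)
}

.otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment nuclei from a binary mask
#'
#' Connected-component labeling (4-connectivity) with an area filter.
#' Components much larger than the typical nucleus are counted as multiple
#' touching nuclei: each object's `n_nuclei` is its area divided by the
#' median object area, rounded (minimum 1). This replaces a watershed
#' split, which no installed package provides, and is adequate at the low
#' overlap these sparse 40x images show.
#'
#' @param mask Logical matrix from [threshold_channel()].
#' @param min_area Minimum object area in pixels; default 20% of the area
#'   of a disk of radius `nucleus_radius`.
#' @param max_area Maximum object area (default `Inf`).
#' @param nucleus_radius Typical nucleus radius in pixels (default 6),
#'   used only for the `min_area` default.
#' @return Tibble with `object_id`, `area`, `x`, `y` (centroid, pixels)
#'   and `n_nuclei`; the integer label matrix is stored in attribute
#'   `"labels"` (0 = background).
#' @export
segment_nuclei <- function(mask, min_area = NULL, max_area = Inf,
                           nucleus_radius = 6) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (is.null(min_area)) min_area <- round(0.2 * pi * nucleus_radius^2)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  empty <- tibble::tibble(object_id = integer(0), area = integer(0),
                          x = numeric(0), y = numeric(0), n_nuclei = integer(0))
  if (length(idx) == 0L) {
    return(structure(empty, labels = matrix(0L, nr, nc)))
  }
  # 4-connectivity edges among foreground pixels (column-major indexing)
  ri <- ((idx - 1L) %% nr) + 1L
  down <- idx[ri < nr & mask[pmin(idx + 1L, nr * nc)]]
  right <- idx[idx + nr <= nr * nc]
  right <- right[mask[right + nr]]
  e_from <- c(down, right)
  e_to <- c(down + 1L, right + nr)
  g <- igraph::make_empty_graph(length(idx), directed = FALSE)
  if (length(e_from)) {
    ends <- rbind(match(e_from, idx), match(e_to, idx))
    g <- igraph::add_edges(g, as.vector(ends))
  }
  memb <- igraph::components(g)$membership
  labels <- matrix(0L, nr, nc)
  labels[idx] <- memb
  area <- tabulate(memb)
  keep <- which(area >= min_area & area <= max_area)
  if (length(keep) == 0L) {
    return(structure(empty, labels = matrix(0L, nr, nc)))
  }
  relab <- integer(length(area))
  relab[keep] <- seq_along(keep)
  labels[idx] <- relab[memb]
  memb_kept <- relab[memb]
  inb <- memb_kept > 0L
  rows <- ri[inb]
  cols <- ((idx[inb] - 1L) %/% nr) + 1L
  m <- memb_kept[inb]
  obj <- tibble::tibble(
    object_id = seq_along(keep),
    area = area[keep],
    x = as.numeric(tapply(cols, m, mean)),
    y = as.numeric(tapply(rows, m, mean))
  )
  ref_area <- stats::median(obj$area)
  ratio <- obj$area / ref_area
  # split only clearly oversized components: natural size jitter (~10% in
  # radius) keeps singles below ~1.5x the median area, a touching pair at
  # the 10% overlap cap sits near 1.9x
  obj$n_nuclei <- ifelse(ratio < 1.65, 1L, pmax(2L, as.integer(round(ratio))))
  structure(obj, labels = labels)
}

#' Classify nuclei as live, apoptotic or dead
#'
#' A nucleus is death-positive when at least `overlap_fraction` of its
#' area lies inside the death-reporter mask, and apoptosis-positive
#' likewise for the apoptosis reporter. Dead = death-positive (including
#' double-positive "yellow" nuclei); apoptotic = apoptosis-positive and
#' not death-positive; live = total − apoptotic − dead. Both assay
#' variants (caspase + PI; live/dead nuclear stains) share this rule.
#'
#' @param segmentation Output of [segment_nuclei()] (its `"labels"`
#'   attribute is used).
#' @param apoptosis_mask,death_mask Logical matrices aligned with the
#'   nuclei channel.
#' @param overlap_fraction Minimum nucleus-area overlap to call a reporter
#'   positive (default 0.3).
#' @return One-row tibble: `total`, `live`, `apoptotic`, `dead`,
#'   `pct_live`, `pct_apoptotic`, `pct_dead`.
#' @export
classify_cells <- function(segmentation, apoptosis_mask, death_mask,
                           overlap_fraction = 0.3) {
  labels <- attr(segmentation, "labels")
  if (is.null(labels)) stop("`segmentation` must come from segment_nuclei()")
  stopifnot(is.matrix(apoptosis_mask), is.matrix(death_mask))
  if (!all(dim(labels) == dim(apoptosis_mask)) ||
      !all(dim(labels) == dim(death_mask)))
    stop("mask shapes do not match the segmentation")
  n_obj <- nrow(segmentation)
  if (n_obj == 0L) {
    return(tibble::tibble(total = 0L, live = 0L, apoptotic = 0L, dead = 0L,
                          pct_live = NA_real_, pct_apoptotic = NA_real_,
                          pct_dead = NA_real_))
  }
  inb <- labels > 0L
  lab <- labels[inb]
  frac_a <- as.numeric(tapply(apoptosis_mask[inb], lab, mean))
  frac_d <- as.numeric(tapply(death_mask[inb], lab, mean))
  # apoptosis-only fraction: reporter pixels outside the death mask, so a
  # double-positive ("yellow") nucleus is not also counted apoptotic
  frac_ao <- as.numeric(tapply(apoptosis_mask[inb] & !death_mask[inb], lab, mean))
  w <- segmentation$n_nuclei
  single <- w == 1L
  dead_n <- integer(n_obj)
  apop_n <- integer(n_obj)
  # single nuclei: the binary overlap rule
  dead_n[single] <- as.integer(frac_d[single] >= overlap_fraction)
  apop_n[single] <- as.integer(frac_a[single] >= overlap_fraction &
                                 dead_n[single] == 0L)
  # merged components: attribute the estimated nucleus count in proportion
  # to the reporter-covered area
  if (any(!single)) {
    k <- which(!single)
    dead_n[k] <- pmin(w[k], as.integer(round(w[k] * frac_d[k])))
    apop_n[k] <- pmin(w[k] - dead_n[k], as.integer(round(w[k] * frac_ao[k])))
  }
  total <- sum(w)
  dead <- sum(dead_n)
  apoptotic <- sum(apop_n)
  live <- total - apoptotic - dead
  tibble::tibble(
    total = total, live = live, apoptotic = apoptotic, dead = dead,
    pct_live = 100 * live / total,
    pct_apoptotic = 100 * apoptotic / total,
    pct_dead = 100 * dead / total
  )
}

#' Quantify one three-channel image end to end
#'
#' Convenience wrapper: thresholds the three channels, segments nuclei and
#' classifies them. Accepts a `cell_image_set` from
#' [simulate_viability_image()] or a plain list with `nuclei`, `apoptosis`
#' and `death` matrices.
#'
#' @param image A `cell_image_set` (or compatible list).
#' @param method Threshold method passed to [threshold_channel()].
#' @param nucleus_radius Typical nucleus radius in pixels.
#' @param overlap_fraction Reporter-positivity overlap fraction.
#' @return One-row counts tibble as in [classify_cells()].
#' @export
quantify_viability <- function(image, method = "otsu", nucleus_radius = 6,
                               overlap_fraction = 0.3) {
  stopifnot(all(c("nuclei", "apoptosis", "death") %in% names(image)))
  nuc <- threshold_channel(image$nuclei, method)
  apo <- threshold_channel(image$apoptosis, method)
  dea <- threshold_channel(image$death, method)
  seg <- segment_nuclei(nuc, nucleus_radius = nucleus_radius)
  classify_cells(seg, apo, dea, overlap_fraction)
}

#' Summarize viability percentages per group
#'
#' Averages per-image percentages within each group and reports the
#' standard error of the mean across images (NA for a single image).
#'
#' @param counts Tibble of per-image counts (rows from [classify_cells()])
#'   with any grouping columns added.
#' @param by Character vector of grouping column names (default none: one
#'   overall group).
#' @return Tidy tibble: grouping columns, `metric` (`pct_live`,
#'   `pct_apoptotic`, `pct_dead`), `mean`, `sem`, `n_images`.
#' @export
summarize_viability <- function(counts, by = character(0)) {
  stopifnot(is.data.frame(counts),
            all(c("pct_live", "pct_apoptotic", "pct_dead") %in% names(counts)))
  if (nrow(counts) == 0L) stop("empty group")
  counts |>
    tidyr::pivot_longer(c("pct_live", "pct_apoptotic", "pct_dead"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n_images = dplyr::n(),
      .groups = "drop"
    )
}
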