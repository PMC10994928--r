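# Synthetic three-channel viability micrographs with ground truth.
# Nuclei are rendered as 2-D Gaussian blobs on a noisy background, at the
# 16-bit intensity scale of an epifluorescence camera; placements are
# rejection-sampled so pairwise overlap stays below a configurable cap.

#' Simulation settings for synthetic viability images
#'
#' Defaults emulate a sparse 40x field (0.085 µm/pixel) with 130 nuclei:
#' 100 live, 20 apoptotic, 10 dead, nucleus radius ~6 px on a 512 x 512
#' canvas — bright nuclei (amplitude 3000) over a dim noisy background
#' (level 300, SD 50) on the 16-bit scale, with 2% channel bleed-through.
#'
#' @param image_size Two-element integer vector, pixels (rows, cols).
#' @param n_live,n_apoptotic,n_dead Ground-truth counts per class.
#' @param nucleus_radius_mean Mean nucleus radius, pixels (default 6;
#'   radii jitter by 10%).
#' @param background_level Background intensity (default 300).
#' @param background_noise_sd Gaussian background noise SD (default 50).
#' @param amplitude Peak nucleus intensity above background (default 3000).
#' @param channel_bleed Fraction of each channel's signal leaking into the
#'   others (default 0.02).
#' @param max_overlap Maximum pairwise disk-overlap fraction allowed when
#'   placing nuclei (default 0.1); placement fails with an error when the
#'   density is infeasible after bounded retries.
#' @param dead_double_positive_frac Fraction of dead nuclei that are also
#'   apoptosis-reporter positive ("yellow" cells; default 0.5).
#' @param assay_variant `"caspase_pi"` or `"nucblue_nucgreen"`; channel
#'   semantics are identical downstream.
#' @param pixel_size µm per pixel (default 0.085).
#' @param seed Optional integer seed.
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(image_size = c(512, 512),
                             n_live = 100, n_apoptotic = 20, n_dead = 10,
                             nucleus_radius_mean = 6,
                             background_level = 300,
                             background_noise_sd = 50,
                             amplitude = 3000,
                             channel_bleed = 0.02,
                             max_overlap = 0.1,
                             dead_double_positive_frac = 0.5,
                             assay_variant = c("caspase_pi", "nucblue_nucgreen"),
                             pixel_size = 0.085,
                             seed = NULL) {
  assay_variant <- match.arg(assay_variant)
  stopifnot(
    length(image_size) == 2, all(image_size >= 16),
    n_live >= 0, n_apoptotic >= 0, n_dead >= 0,
    nucleus_radius_mean > 0, background_noise_sd >= 0,
    channel_bleed >= 0, channel_bleed < 1,
    max_overlap >= 0, max_overlap < 1,
    dead_double_positive_frac >= 0, dead_double_positive_frac <= 1
  )
  n_total <- n_live + n_apoptotic + n_dead
  # rough feasibility check: nuclei must fit without mandatory overlap
  if (n_total * pi * (1.2 * nucleus_radius_mean)^2 > 0.5 * prod(image_size))
    stop("image too small to place all nuclei at the stated radius")
  structure(
    list(image_size = as.integer(image_size), n_live = as.integer(n_live),
         n_apoptotic = as.integer(n_apoptotic), n_dead = as.integer(n_dead),
         nucleus_radius_mean = nucleus_radius_mean,
         background_level = background_level,
         background_noise_sd = background_noise_sd,
         amplitude = amplitude, channel_bleed = channel_bleed,
         max_overlap = max_overlap,
         dead_double_positive_frac = dead_double_positive_frac,
         assay_variant = assay_variant, pixel_size = pixel_size,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "image_sim_config"
  )
}

# overlap fraction of two disks relative to the smaller one
.disk_overlap_frac <- function(d, r1, r2) {
  r <- min(r1, r2); R <- max(r1, r2)
  if (d >= r + R) return(0)
  if (d <= R - r) return(1)
  a1 <- r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r))
  a2 <- R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R))
  a3 <- 0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
  (a1 + a2 - a3) / (pi * r^2)
}

.add_blob <- function(img, cx, cy, r, amp) {
  sigma <- r / 2
  half <- ceiling(3 * sigma)
  rows <- max(1, round(cy) - half):min(nrow(img), round(cy) + half)
  cols <- max(1, round(cx) - half):min(ncol(img), round(cx) + half)
  gy <- exp(-(rows - cy)^2 / (2 * sigma^2))
  gx <- exp(-(cols - cx)^2 / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amp * (gy %o% gx)
  img
}

.simulate_image_impl <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  n_total <- cfg$n_live + cfg$n_apoptotic + cfg$n_dead
  labels <- c(rep("live", cfg$n_live), rep("apoptotic", cfg$n_apoptotic),
              rep("dead", cfg$n_dead))
  labels <- sample(labels)
  radii <- pmax(2, stats::rnorm(n_total, cfg$nucleus_radius_mean,
                                0.1 * cfg$nucleus_radius_mean))
  xs <- numeric(n_total); ys <- numeric(n_total)
  for (i in seq_len(n_total)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      x <- stats::runif(1, radii[i] + 1, W - radii[i])
      y <- stats::runif(1, radii[i] + 1, H - radii[i])
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt((xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2)
        near <- which(d < radii[seq_len(i - 1L)] + radii[i])
        for (j in near) {
          if (.disk_overlap_frac(d[j], radii[j], radii[i]) > cfg$max_overlap) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        xs[i] <- x; ys[i] <- y
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("nucleus placement failed: density infeasible at the stated overlap cap")
  }
  nuc <- matrix(0, H, W); apo <- matrix(0, H, W); dea <- matrix(0, H, W)
  yellow <- stats::runif(n_total) < cfg$dead_double_positive_frac
  for (i in seq_len(n_total)) {
    nuc <- .add_blob(nuc, xs[i], ys[i], radii[i], cfg$amplitude)
    if (labels[i] == "apoptotic" || (labels[i] == "dead" && yellow[i]))
      apo <- .add_blob(apo, xs[i], ys[i], radii[i], cfg$amplitude)
    if (labels[i] == "dead")
      dea <- .add_blob(dea, xs[i], ys[i], radii[i], cfg$amplitude)
  }
  finish <- function(ch, others) {
    out <- ch + cfg$channel_bleed * others + cfg$background_level +
      stats::rnorm(H * W, 0, cfg$background_noise_sd)
    pmin(pmax(out, 0), 65535)
  }
  image <- structure(
    list(nuclei = finish(nuc, apo + dea),
         apoptosis = finish(apo, nuc + dea),
         death = finish(dea, nuc + apo),
         pixel_size = cfg$pixel_size, assay_variant = cfg$assay_variant),
    class = "cell_image_set"
  )
  truth <- tibble::tibble(x = xs, y = ys, radius = radii, label = labels,
                          double_positive = labels == "dead" & yellow)
  list(image = image, ground_truth = truth)
}

#' Simulate a three-channel viability micrograph
#'
#' Every nucleus appears in the nuclei channel; apoptotic nuclei also in
#' the apoptosis channel; dead nuclei also in the death channel (a
#' configurable fraction of dead nuclei are additionally apoptosis
#' positive, emulating double-positive "yellow" cells). Ground-truth
#' labels and positions are returned. Identical seeds give identical
#' images.
#'
#' @param cfg An [image_sim_config()].
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @return List with `image` (a `cell_image_set`: `nuclei`, `apoptosis`,
#'   `death` matrices plus metadata) and `ground_truth` (tibble `x`, `y`,
#'   `radius`, `label`, `double_positive`).
#' @export
simulate_viability_image <- function(cfg = image_sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "image_sim_config"))
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed)) {
    withr::with_seed(as.integer(seed), .simulate_image_impl(cfg))
  } else {
    .simulate_image_impl(cfg)
  }
}
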