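---
title: "Models and methods behind meahypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meahypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meahypoxia)
```

# The experimental setting

`meahypoxia` analyses experiments in which human neuronal networks grown on
multiwell micro-electrode arrays (MEAs; 24 wells, 12 extracellular electrodes
per well) are exposed to prolonged hypoxia as an in vitro model of the
ischemic penumbra. Electrophysiological activity is recorded for 10 minutes
at 10 kHz at a normoxic baseline and then every 2 hours during 24–48 hours of
hypoxia, under different treatments (no treatment, optogenetic activation of
neurons or astrocytes, exogenous lactate). Cell health is read out in
parallel from three-channel fluorescence micrographs: a nuclear counterstain
marks all cells, an apoptosis reporter marks apoptotic cells and a death
reporter marks dead cells.

The package implements the full analysis chain — spike detection, burst and
network-burst detection, per-well metrics, baseline normalization and
condition statistics, and image-based viability counting — plus a
synthetic-data generator that emulates both kinds of raw data with known
ground truth, so every stage is testable without experimental recordings.

# Spike detection

Traces are band-passed at 100–3500 Hz and spikes are detected where the
filtered signal exceeds **4.5 times the standard deviation of the baseline
noise**. Design choices where the procedure is conventionally
under-specified:

* **Noise SD.** Estimated as the median absolute deviation scaled to the
  Gaussian SD. An RMS estimate is inflated by the spikes themselves; the MAD
  is insensitive to the sparse large excursions it is meant to threshold.
* **Filter.** No IIR filtering package is available in this environment, so
  the band-pass applies an order-4 Butterworth *magnitude* response in the
  frequency domain. This is exactly zero-phase (spike times are unbiased),
  which is also why forward–backward filtering is the field's default.
* **Polarity and dead time.** Both polarities are detected by default and
  excursions closer than 1 ms are collapsed to the first event, so the two
  lobes of a biphasic waveform are never counted twice. Both are
  configurable in `detection_config()`.
* An electrode is **active** at `>=` 0.1 spikes/s; the well's mean firing
  rate (MFR) averages spikes/s over active electrodes only and is defined
  as 0 when no electrode is active, so a normalized time-course can reach
  full silencing.

# Burst and network-burst detection

Single-channel bursts use a fixed-parameter max-interval scheme: a burst
opens at an inter-spike interval (ISI) `<=` 50 ms and continues while ISIs
stay `<=` 100 ms; candidates separated by less than 100 ms are merged; bursts
with fewer than 4 spikes or shorter than 50 ms are discarded. Reading the
50/100 ms pair as *opening* and *continuation* thresholds follows the
convention of commercial multiwell analyzers; a literal lower ISI bound of
50 ms would exclude fast bursts, which contradicts burst physiology. Merging
precedes the count/duration filters because those filters describe final
bursts. A channel bursting at `>=` 0.4 bursts/min is a *bursting channel*.

A **network burst** is a chain of single-channel bursts connected
(transitively) by strictly positive temporal overlap, qualified by two
thresholds: at least 8 distinct channels overall and at least 8 bursts open
simultaneously at some instant. The simultaneity count uses a boundary sweep
with open intervals, so zero-length contact is not overlap. By default all
detected bursts may participate (the bursting-channel gate is reported
separately); this is the more permissive reading of an ambiguous definition
and is configurable by passing a filtered burst table.

Per well, NBR is the number of network bursts per minute of analyzed time
(the raw unit cancels under baseline normalization) and NBD the arithmetic
mean event duration, flagged `NA` when a well has no events.

Numerical tie-breaks: comparisons of durations, ISIs and rates against the
printed thresholds use a `1e-9` absolute tolerance so that exactly-boundary
constructions (a 50 ms burst, 0.1 spikes/s, 0.4 bursts/min) are decided by
the stated inclusive rule rather than floating-point representation.

# Time-course normalization and statistics

During optogenetic treatments, light is delivered for 3 minutes every 2
hours; metrics are evaluated **only outside stimulation windows**:
`mask_stimulation()` removes epoch spikes (times are not shifted) and all
rates use the reduced analyzed duration. Rate metrics are exactly invariant
under masking of a homogeneous train; burst metrics can differ from a
literal concatenation of the unmasked segments only at segment seams, which
is the physically correct behaviour.

Each well's MFR/NBR/NBD at every timepoint is divided by that well's
normoxia value. Wells with a zero baseline for a metric are excluded from
that metric's aggregate (division is undefined, and a functionally mature
culture is an inclusion criterion at baseline anyway) rather than set to 0
or infinity. Condition aggregates report mean ± SEM across wells.

`compare_conditions()` is deliberately a thin harness over established
routines: per-timepoint two-group tests (t-test when both groups pass a
Kolmogorov–Smirnov normality screen, Mann–Whitney otherwise) or a two-way
ANOVA (condition × timepoint) with per-timepoint post hoc comparisons. The
module's own content is the family definition: Bonferroni multiplies each
p-value by the number of per-timepoint comparisons, capped at 1. The ANOVA
treats wells as independent observations per timepoint; a repeated-measures
structure over the same wells is not modelled (a known simplification —
the recording schedule revisits the same wells).

# The synthetic MEA generator

`simulate_well()` states a simple generative world chosen to match the
analysis assumptions rather than neuronal biophysics:

* **Background** activity is homogeneous Poisson per electrode
  (default 2 spikes/s) — spontaneous inter-burst statistics are never
  specified in this kind of experiment, and Poisson background is the
  simplest process that exercises the detectors.
* **Network bursts** arrive as a Poisson process (default 6 events/min, a
  typical rate for functionally mature hiPSC-derived networks on multiwell
  MEAs), each recruiting every electrode independently with probability
  0.9 and emitting `>=` 4 spikes with gamma(shape 2) ISIs of mean 20 ms over
  ~0.5 s. Two defaults are set by the principle that recovery tests should
  measure detector behaviour, not generator marginality: the 20 ms ISI
  sits well inside the detector's ISI window, and 6 events/min gives a
  10-minute recording ~60 events, so a per-well baseline-normalized rate
  carries only a few percent of Poisson sampling noise and a 20-well mean
  resolves the generative profile within the ±0.15 band used by the
  recovery checks with ~3.4 SEM of margin (a rate of 3/min, equally
  realistic biologically, leaves only ~2.2 SEM and makes those checks
  fail for a material fraction of seeds).
* **Treatment profiles** are multiplier functions of hours-in-hypoxia
  applied to the generative rates, all equal to 1 at baseline. The
  untreated NBR multiplier is a smooth cosine ramp reaching exactly 0 at
  24 h (complete loss of network bursting) with exponentially decaying MFR
  (default time constant 12 h); neuronal activation holds NBR at baseline
  through 18 h; astrocyte activation makes events slightly more frequent
  and ~30% shorter; lactate blunts activity immediately. Only figure-level
  shapes are reported for such experiments, so profiles are configuration,
  not constants.
* `render_voltage_trace()` embeds a short biphasic template (single
  dominant peak, normalized to 1) in Gaussian noise at 10 kHz so the spike
  detector can be exercised end to end.

What a green recovery test does **not** establish: real recordings have
non-Poisson background, electrode-specific amplitudes and noise,
within-well rate heterogeneity and slow drifts; none of these are emulated.
The generator validates the pipeline's correctness, not its robustness to
every property of biological data.

A note on estimator variance: normalized metrics are per-well ratios of
Poisson-ish counts (~60 baseline events per well at the defaults), so a
condition mean over 20 wells carries sampling noise of a few percent plus
a heavy-tailed `1/baseline` term; excursions of the mean of several
hundredths around the generative multiplier are expected behaviour, not
detector error.

# The synthetic micrograph generator and viability counting

`simulate_viability_image()` renders nuclei as 2-D Gaussian blobs (radius
~6 px, 10% jitter) on a noisy 16-bit background, with placements
rejection-sampled so pairwise disk overlap stays `<=` 10% (bounded retries;
infeasible densities error). Apoptotic nuclei also appear in the apoptosis
channel; dead nuclei in the death channel, half of them additionally in the
apoptosis channel to emulate double-positive ("yellow") cells; 2% channel
bleed-through is added.

Quantification thresholds each channel with Otsu's method (the published
workflows use a manually set intensity threshold per staining; Otsu is the
standard automatic surrogate, and fixed thresholds remain available). A
bimodality guard returns an empty mask when Otsu's two classes are separated
by less than twice the sum of their within-class SDs — otherwise a
noise-only channel would be bisected into 50% foreground. Nuclei are
connected components (4-connectivity, via an igraph pixel graph — no
dedicated image package exists in this environment) filtered by area;
components larger than ~1.65× the median object area are counted as
multiple nuclei (area / median, rounded), replacing a watershed split. A
nucleus is reporter-positive at `>=` 30% area overlap with the reporter mask
(guards against bleed-through); double positives count as dead only;
live = total − apoptotic − dead, so the count identity holds by
construction. For merged multi-nucleus components the estimated count is
attributed in proportion to reporter-covered area, which reduces to the
binary rule for single nuclei.

# Tunable parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| threshold_multiplier | 4.5 | noise SDs | printed detection threshold |
| filter_band | 100–3500 | Hz | printed acquisition band |
| dead_time | 1 | ms | biphasic double-count guard (unstated; config) |
| active_rate_threshold | 0.1 | spikes/s | printed active-electrode rule |
| min_spikes / start/continue ISI | 4 / 50 / 100 | –, ms | printed burst definition |
| min_interburst / min_duration | 100 / 50 | ms | printed burst filters |
| bursting_channel_rate | 0.4 | bursts/min | printed bursting-channel rule |
| nb_min_channels / nb_min_simultaneous | 8 / 8 | channels | printed network-burst rule |
| background_rate / nb_rate | 2 / 6 | Hz, events/min | realistic mature-network defaults, powered for recovery checks |
| nb_participation / intra ISI | 0.9 / 20 | –, ms | detectability by construction |
| overlap_fraction (viability) | 0.3 | – | bleed-through guard (unstated; config) |

# Known limitations

* No spike sorting; detection is multi-unit threshold crossing by design.
* Only the fixed-parameter burst detector is provided (no log-ISI or
  Poisson-surprise variants) — matching the analysis this package mirrors.
* The ANOVA ignores the repeated-measures structure across timepoints.
* Segmentation has no true watershed; heavily clumped images (overlap well
  beyond the generator's 10% cap) will undercount.
* HDF5/TIFF I/O is not provided (no R bindings in the supported
  environment); CSV/JSON interchange is.
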