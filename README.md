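# meahypoxia

Analysis toolkit for in vitro hypoxia ("ischemic penumbra") experiments on
neuronal cultures: multiwell micro-electrode array (MEA) electrophysiology
and fluorescence-based cell viability, with a synthetic-data generator that
makes the whole pipeline testable offline.

In these experiments, human neuronal networks on 24-well MEAs (12
electrodes per well, 10 kHz sampling) are recorded for 10 minutes at a
normoxic baseline and every 2 hours during 24–48 h of hypoxia, under
treatments such as optogenetic activation of neurons or astrocytes or
exogenous lactate. The scientific readouts are:

* **MFR** — mean firing rate: average spikes/s over *active* electrodes
  (≥ 0.1 spikes/s) in a well.
* **NBR / NBD** — network-burst rate and mean duration. A single-channel
  burst is ≥ 4 spikes under a max-interval ISI rule (open ≤ 50 ms,
  continue ≤ 100 ms, merge gaps < 100 ms, duration ≥ 50 ms); a network
  burst is a chain of temporally overlapping bursts with ≥ 8 distinct
  channels and ≥ 8 simultaneously open bursts at some instant.
* Spikes are threshold crossings at **4.5 × the baseline-noise SD** on
  100–3500 Hz band-passed traces.
* Per-well metrics are masked for stimulation windows (3 min every 2 h),
  normalized to the normoxia baseline, aggregated as mean ± SEM per
  condition, and compared with t-test / Mann–Whitney / two-way ANOVA with
  Bonferroni correction.
* **Viability**: nuclei are counted from a counterstain channel; a nucleus
  ≥ 30% covered by the death-reporter mask is dead (double positives count
  as dead), apoptosis-reporter-only nuclei are apoptotic, and
  live = total − apoptotic − dead.

## Worked example

Simulate a small untreated hypoxia time-course, run the analysis chain and
aggregate the normalized network-burst rate:

```r
library(meahypoxia)

cfg <- sim_config(n_wells = 3, duration_s = 300)
tc  <- simulate_timecourse(cfg, treatment_profile("untreated"),
                           timepoints_h = seq(0, 24, by = 6), seed = 42)
metrics <- timecourse_metrics(tc)            # spike -> burst -> network burst
norm    <- normalize_to_baseline(metrics)    # per-well ratio to normoxia
aggregate_condition(norm, metrics_cols = "nbr_norm")
#> # A tibble: 5 × 6
#>   condition timepoint_h metric    mean    sem n_wells
#>   <chr>           <dbl> <chr>    <dbl>  <dbl>   <int>
#> 1 untreated           0 nbr_norm 1     0            3
#> 2 untreated           6 nbr_norm 0.855 0.164        3
#> 3 untreated          12 nbr_norm 0.506 0.164        3
#> 4 untreated          18 nbr_norm 0.134 0.0346       3
#> 5 untreated          24 nbr_norm 0     0            3
```

The normalized NBR starts at 1 by construction, declines as the untreated
generative profile collapses, and reaches exactly 0 at 24 h — the complete
loss of network bursting the untreated condition is defined by. (With only
3 short wells the intermediate points are noisy; the SEM column says how
much.)

Viability on a synthetic micrograph with known ground truth
(100 live / 20 apoptotic / 10 dead):

```r
sim <- simulate_viability_image(image_sim_config(seed = 42))
quantify_viability(sim$image)
#> # A tibble: 1 × 7
#>   total  live apoptotic  dead pct_live pct_apoptotic pct_dead
#>   <int> <int>     <int> <int>    <dbl>         <dbl>    <dbl>
#> 1   131  101        20    10     77.1          15.3     7.63
```

`plot_raster()`, `plot_timecourse()` and `autoplot()` on a
`compare_conditions()` result draw the standard figures; `tidy()` /
`glance()` give broom-style summaries of the statistics.

## Acceptance script

`scripts/acceptance.R` recomputes each printed detection parameter from
scratch as the empirical decision boundary of the corresponding operation
on synthetic input — the spike threshold from an amplitude sweep on seeded
noise, and the burst/network-burst/activity thresholds from behavioral
sweeps of constructed spike trains:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/meahypoxia-methods.Rmd` for the models, assumptions,
parameter rationale and known limitations.
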