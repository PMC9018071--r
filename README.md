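# atpflux

Single-cell ATP dynamics and protein-aggregation kinetics from
ratiometric biosensor time-lapse imaging.

## The problem

Budding yeast keeps cytoplasmic ATP near 4 mM. In mutants of the
energy-sensing machinery (AMPK/Snf1, adenylate kinase Adk1, the purine
regulator Bas1) this homeostasis breaks in ways that population-level
biochemistry cannot see: individual cells undergo sudden, transient ATP
depletions ("ATP dips"), irreversible downward shifts, or slow
oscillations, and transient depletion is followed within hours by an
accelerated accumulation of protein aggregates. Quantifying this requires
per-cell time series from dual-excitation QUEEN biosensor imaging
(excitation 410/490 nm; the intensity ratio is proportional to [ATP]),
per-cell aggregate-reporter (Hsp104 fusion) intensities, and a small set
of statistics tying the two together.

`atpflux` implements that analysis as a tested, reusable pipeline:

- **Ratiometry & QC** — per-cell mean-intensity traces under label masks,
  the QUEEN ratio `R_t = I410_t / I490_t`, detection of single-channel
  acquisition errors (one channel anomalously intense in a single frame,
  ~1 frame in 70) and their correction by the adjacent-frame average
  `R_k <- (R_{k-1} + R_{k+1})/2`, and linear or Hill calibration of ratio
  to mM ATP.
- **Dynamics classification** — lag differences
  `Δratio(t, l) = R_t − R_{t−l}`, event detection against a frozen
  running-median baseline, and the fixed-threshold classifier: **dip** =
  drop > 0.5 ratio units spanning > 2 frames with recovery; **shallow
  dip** = drop in 0.33–0.5 with recovery; **shift** = drop > 0.33 without
  recovery; **stable** = neither, observed for at least twice the strain's
  doubling time.
- **Foci & RMSD** — prominence-based local-maxima detection of aggregate
  foci (a maximum counts if it stands more than a noise tolerance, default
  4000, above the highest saddle connecting it to higher terrain; 3-px
  circle mean intensities), per-cell reporter intensity traces, an OLS fit
  to the pre-dip segment, and
  `RMSD(W) = sqrt(mean_{t∈W} (y_t − ŷ_t)^2)` over windows before the dip
  and cumulative 30-min windows after it, summarized as fold changes and
  the maximum fold within 3 h.
- **Oscillation** — autocorrelation of the ratio trace and the period from
  the first significant positive-lag ACF peak.
- **Synthetic data** — a ground-truth generator for all of the above
  (traces, two-channel + reporter image stacks, label masks), so the whole
  pipeline is validated closed-loop without any microscopy data.

## Worked example

```r
library(atpflux)

cfg <- synthetic_config(n_cells = 1)              # reference study conditions
g   <- gen_dip_trace(cfg, seed = 8, depth = 0.65, onset = 60)
ev  <- detect_dip_events(g$trace)
ev
#>   onset nadir end  baseline   depth duration_frames duration_min recovered
#> 1    59    63  63 0.9699579 0.70903               5           20      TRUE
classify_trace(g$trace, ev, doubling_time = 4.8)$label
#> [1] "dip"

ga  <- gen_aggregation_trace(cfg, seed = 8, dip_onset = ev$onset[1])
fit <- fit_pre_dip_regression(ga$agg, ev$onset[1])
rc  <- rmsd_timecourse(ga$agg, fit, ev$onset[1])
sprintf("pre-dip r = %.3f; RMSD before %.1f; max fold within 3 h = %.2f",
        fit$pearson_r, rc$rmsd_before, rc$max_fold)
#> [1] "pre-dip r = 0.944; RMSD before 24.0; max fold within 3 h = 5.31"
```

The injected 0.65-deep dip at frame 60 is detected one frame early with a
measured depth of 0.709: with Gaussian ratio noise of SD 0.05 the event
boundary extends into the preceding noise excursion and the
baseline-to-nadir depth takes the deepest noisy frame, both expected
properties of the estimator (noiseless traces recover depth and duration
exactly). The paired reporter trace, generated with a post-dip
acceleration calibrated to a 5.6-fold expected maximum RMSD change,
measures 5.31-fold here.

## The analysis workflow

`analysis/` contains numbered drivers that run the full study on
synthetic cohorts and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohorts + ground truth
Rscript analysis/02_ratiometry_qc.R     # ratio traces, error QC, calibration
Rscript analysis/03_classify_dynamics.R # dip/shallow/shift/stable fractions
Rscript analysis/04_aggregation_rmsd.R  # linearity + RMSD fold time courses
Rscript analysis/05_oscillation.R       # ACF period recovery
Rscript analysis/06_report.R            # end-to-end run, reference report
```

`run_pipeline()` performs the same stages programmatically and emits a
byte-reproducible JSON run report; `run_pipeline(reference_config())`
reproduces `inst/extdata/reference_report.json` exactly.

## Limitations

The synthetic generator reproduces the statistical structure the analysis
assumes (event geometry, noise levels, linearity, error rates), not real
microscopy: no segmentation errors, photobleaching, focus drift, cell
division or motion. Masks are inputs throughout; segmentation and group
hypothesis testing (Welch, Dunnett) are deliberately out of scope — the
pipeline emits the per-cell tables those tests consume.
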