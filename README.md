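# gaitvar

Linear and nonlinear gait-variability metrics from a single lower-back
(and optionally foot) accelerometer.

## The problem

Wearable gait analysis in daily life typically relies on one triaxial
accelerometer at the lumbar spine.  At that vantage point individual gait
events are hard to pin down, so the informative measures are signal-level:
how intense the movement is, how similar one step is to the next, and —
the nonlinear layer — how fast nearby trajectories of the reconstructed
gait dynamics diverge.  The short-horizon divergence rate (**local dynamic
stability, LDS**) indexes resilience to perturbations; the long-horizon
rate (**attractor complexity index, ACI**) tracks the temporal *structure*
of stride-to-stride variability, which in healthy self-paced walking is
persistent/fractal (DFA scaling exponent α ≈ 0.7–1.0) and flips
anti-persistent (α < 0.5) when walking is paced by a metronome — a
signature of increased attentional load on gait control.  `gaitvar`
implements the full chain for researchers studying aging gait, fall risk
and gait automaticity.

## What it computes

Given a raw 256 Hz triaxial record (delimited text, in g):

1. **Segmentation** — walking bouts by a moving-variance + dominant-
   frequency gate, with a manual-override path (`detect_walking_bouts`).
2. **Calibration** — Moe-Nilssen-style two-rotation tilt correction onto
   anatomical AP/V/ML axes, plus the rotation-invariant gravity-free
   vector norm `sqrt(ax²+ay²+az²) − 1` (`calibrate_tilt`, `vector_norm`).
3. **Standardization** — step frequency from the FFT of the vertical
   axis, truncation to 250 steps (`round(250/SF·fs)` samples), cubic-
   spline resampling to 18,750 samples = 75/step = 150/stride
   (`standardize_bout`).
4. **Linear metrics** — RMS of the norm, RMS ratio (ML/norm), and
   step/stride regularity from the unbiased autocorrelation at lags
   ~75/~150, Fisher-transformed (`movement_intensity`, `acf_regularity`).
5. **Nonlinear metrics** — Takens delay embedding (default m = 6,
   τ = 15), Rosenstein nearest-neighbour divergence curves with a
   one-stride Theiler window, and OLS slopes over 0–0.5 strides
   (LDS-ML) and 5–12 strides (ACI-AP/V/N), in nats/stride
   (`compute_lds_aci`).
6. **Stride DFA** — impact-peak stride intervals from a foot sensor and
   DFA1 with boxes 16…N/2, giving α (`detect_strides`, `dfa`,
   `classify_persistence`).
7. **Cohort statistics** — tidy per-segment metric tables, segment
   aggregation, Hedges' g with bias-corrected bootstrap 99% CIs
   (`cohort_table`, `hedges_g`).

A seeded synthetic generator (`synth_spec`, `gen_stride_series`,
`gen_trunk_accel`, `gen_foot_accel`, `gen_lorenz`) produces
ground-truthed gait-like signals with controllable stride-interval
scaling exponent, so the whole pipeline is testable offline.

## Worked example

```r
library(gaitvar)
spec    <- synth_spec(n_strides = 132, target_alpha = 0.9, seed = 2)
strides <- gen_stride_series(spec)          # fGn stride intervals, α = 0.9
trunk   <- gen_trunk_accel(strides, spec)   # tilted, noisy lumbar trace
foot    <- gen_foot_accel(strides, spec)    # impact spikes per stride

cal <- calibrate_tilt(trunk)
seg <- standardize_bout(cal)                # 250 steps -> 18,750 samples
mi  <- movement_intensity(seg)
rg  <- acf_regularity(seg)
nl  <- compute_lds_aci(seg)
al  <- dfa(detect_strides(foot))
```

Printed output:

```
step frequency: 1.907 Hz
RMS (norm): 0.293 g   RMS ratio: 0.654
step regularity r: 0.995   stride regularity r: 0.985
LDS-ML: 0.881   ACI-AP: 0.0868   ACI-V: 0.0893   ACI-N: 0.0846  [nats/stride]
DFA alpha: 0.871  -> persistent
```

Reading it: cadence ~1.9 Hz and movement intensity ~0.29 g are typical of
steady adult walking; the RMS ratio ~0.65 says roughly two-thirds of the
movement intensity is mediolateral; regularity near 1 reflects the
generator's nearly periodic waveform; the positive ACI slopes say
neighbouring trajectories keep diverging over 5–12 strides, as expected
when stride intervals are persistently correlated — and DFA on the foot
intervals confirms the imposed persistence (α = 0.87, "persistent").

Command-line entry points wrap the same pipeline:

```sh
Rscript -e 'gaitvar::gait_cli()' analyze  manifest.csv out/
Rscript -e 'gaitvar::gait_cli()' simulate spec.json    sim/
Rscript -e 'gaitvar::gait_cli()' compare  out/metrics.csv summary/
Rscript -e 'gaitvar::gait_cli()' dfa      strides.tsv
```

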