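---
title: "Linear and nonlinear gait variability from a single trunk accelerometer: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait variability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

A single triaxial accelerometer worn at the lower back (L4--L5) is the
de-facto standard for gait monitoring outside the laboratory.  It cannot
resolve individual gait events reliably, so classical stride-by-stride
variability measures are noisy; instead, a family of signal-level metrics
has emerged that operate on the continuous acceleration record: movement
intensity (RMS), the mediolateral RMS ratio, step/stride regularity from
the autocorrelation function, the local dynamic stability (LDS, a
short-horizon maximal-Lyapunov-exponent estimate), and the attractor
complexity index (ACI, the long-horizon slope of the same divergence
curve).  The stride-interval scaling exponent from detrended fluctuation
analysis (DFA) of a foot-worn sensor serves as the reference standard for
the *temporal structure* of gait variability: healthy self-paced walking
shows persistent, fractal-like stride correlations (alpha roughly
0.7--1.0), while cued (metronome) walking flips them anti-persistent
(alpha below 0.5).  The ACI was designed as an acceleration-domain
surrogate for that structure.

`gaitvar` implements this entire chain, plus a seeded synthetic-signal
generator so that every stage is testable without sensor recordings.

# Pipeline model and assumptions

## Calibration and the vector norm

Raw channels are mapped to anatomical axes by configuration, never
auto-inferred (device mounting varies); only a guess-the-vertical fallback
exists, and it warns.  Tilt correction follows the classical two-rotation
scheme: the per-bout mean acceleration estimates gravity, a sagittal
rotation zeroes the anteroposterior mean, then a frontal rotation zeroes
the mediolateral mean.  The procedure assumes the sensor is, on average
over a bout, static relative to gravity; we reject bouts whose mean
acceleration magnitude leaves [0.5, 1.5] g.  Exactness properties (a
statically tilted sensor maps to v = 1 g, ap = ml = 0; idempotence) are
tested to 1e-9.

The gravity-free vector norm, sqrt(ax^2 + ay^2 + az^2) - 1 (in g), is
rotation-invariant by construction and is the input to intensity and
regularity metrics.  No prefiltering is applied anywhere; any filtering
must be requested explicitly.

## Standardization

Step frequency (SF) is the dominant frequency of the vertical-axis
magnitude spectrum inside 1.2--3.0 Hz, refined by parabolic interpolation
of the log magnitude around the peak bin (refinement method is a design
choice; it removes up to half a bin of quantization, ~0.002 Hz at typical
lengths).  A spectrum whose peak bin carries less than 10% of the band
power is rejected as having no dominant peak.

Each bout is truncated to the first `round(250 / SF * fs)` samples --
250 steps at the bout's own cadence -- then resampled onto 18,750 points
(75 samples per step, 150 per stride) with a cubic spline on a uniform
grid (linear interpolation available).  Rounding of the truncation length
is half-away-from-zero; both choices are deterministic and phase-neutral
for band-limited signals.  After standardization every participant's step
occupies exactly 75 samples, so autocorrelation lags and divergence-curve
time axes are directly comparable across subjects.

## Linear metrics

RMS of the norm over the 250 steps measures movement intensity; the RMS
ratio (ML RMS over norm RMS) normalizes away most of the speed dependence.
Regularity uses the *unbiased* autocorrelation estimator (lag-k sum
divided by N - k), normalized by lag 0, with the signal mean removed
before the ACF (mean handling is unstated in the source literature; we
center and document it).  The step peak is the ACF maximum within
0.5--1.5 nominal step lags, the stride peak within 1.5--2.5; windows are
wide because standardization pins the nominal lags at exactly 75/150.
Peaks are plain maxima, ties break toward the smaller lag, and a maximum
sitting on a window edge is flagged rather than silently reported.  The
unbiased estimator is ill-behaved at large lags, so search never exceeds
lag 250 (far below N/2).  Fisher's transform z = atanh(r) (r clamped to
1 - 1e-12) is reported alongside r for group statistics.

## Nonlinear metrics

Each standardized axis is delay-embedded (Takens); for every attractor
point the Euclidean nearest neighbour outside a Theiler window is tracked
forward, and the mean log separation forms the divergence curve
(Rosenstein's estimator).  LDS is the least-squares slope of that curve
over 0--0.5 strides; ACI over 5--12 strides; both in nats/stride.  LDS is
reported for ML, ACI for AP, V and the norm, matching trunk-accelerometry
practice.

Embedding parameters are not prescribed by the source study (they live in
a companion article we do not reproduce); our defaults, m = 6 and tau =
15 samples (0.1 stride), were fixed once from the standard
average-mutual-information / false-nearest-neighbour heuristics run on
synthetic gait, are plain arguments, and are echoed into every result.
The Theiler window defaults to one stride (150 samples).  Numerical
policy: nearest-neighbour ties break toward the smaller index (runs are
bit-reproducible); pairs whose forward track leaves the data are dropped
from the mean at that horizon rather than truncating the curve; exact
zero distances are floored at the smallest positive distance observed and
counted.  Amplitude scaling shifts log distances by a constant, so both
exponents are scale-invariant to 1e-9 -- a property test, not an
assumption.

The estimator is validated against an independent oracle: on a Lorenz
trajectory (canonical parameters, dt = 0.01, m = 3, tau = 11, Theiler
200) the short-range divergence slope is compared with a Benettin
variational estimate computed from the Jacobian with the same integrator.
The divergence curve of a chaotic system is linear only after the
nearest-neighbour transient and before folding saturates it; we fit over
0.5--3 s, squarely inside the linear region, and require agreement within
10% (observed: about 2%).

## Stride intervals and DFA

Foot-sensor impact peaks are detected on the gravity-free norm: local
maxima at least 1 g above the running median (+-0.5 s window), separated
by at least half the running median stride time (a first greedy pass at
0.3 s bootstraps that estimate).  Intervals outside 0.4--2.5 s are
excluded and logged.  DFA integrates the mean-centred series, detrends
linearly (DFA1, the literature default) in non-overlapping boxes placed
from both ends of the series (the two coverages averaged, so no samples
are discarded when N is not a multiple of the box size), and fits
log F(n) versus log n over 16 box sizes log-spaced between 16 and N/2,
deduplicated after rounding.  Forward-only coverage is selectable.

# The synthetic world

The generator states one world and the tests live in it:

* stride-interval series: exact fractional Gaussian noise (Davies--Harte
  circulant embedding) with Hurst exponent equal to the target DFA alpha
  for alpha in (0, 1), random-phase spectral synthesis of 1/f^(2 alpha - 1)
  noise otherwise; rescaled to the requested mean and SD exactly.
* trunk waveform: per-stride sum of 3 harmonics -- AP and V at step
  frequency, ML at stride frequency (left--right asymmetry) -- time-warped
  to each stride's interval, with a narrow zero-mean impact transient at
  every step onset, per-stride amplitude jitter (CV 5%), a known pure
  rotation for sensor tilt, +1 g of gravity on the raw vertical channel,
  and white sensor noise.
* foot trace: baseline gravity and noise with a 4 g impact spike at every
  stride boundary; ground-truth spike indices are attached.

Defaults: 1.9 Hz step frequency, 256 Hz sampling, stride SD 0.01 s,
noise 0.005 g, amplitudes tuned once so that pipeline intensity lands
near 0.29 g and the RMS ratio near 0.65 -- the magnitudes reported for
real cohorts.

Two defaults deserve their "why".  The sensor-noise SD (0.005 g) is the
wide-band noise floor of a MEMS accelerometer over a ~128 Hz bandwidth;
the generator's contract is that the *imposed stride-interval structure*
is the dominant stochastic component, which an inflated noise floor would
mask.  The stride-time SD (0.01 s, CV ~1%, the low end of the healthy
steady-walking range of roughly 1--3%) was fixed after a diagnostic that
is worth recording: the synthetic attractor is essentially a
one-dimensional phase loop, so the distance between two phase-shifted
trajectories saturates once their phase difference reaches about a
radian.  Neighbour phase drift grows like sqrt(2) * sigma * t^alpha
strides; at sigma = 0.02 s it saturates *inside* the 5--12-stride ACI
window, capping the persistent member's slope and masking the imposed
correlation structure the generator exists to express.  Real gait
attractors are higher-dimensional and saturate later, which is why real
recordings tolerate larger timing variability; the synthetic world must
compensate with a cleaner clock.  At sigma = 0.01 s the log-slope of the
divergence curve follows the timing structure (slope roughly proportional
to alpha below saturation), persistent/anti-persistent pairs separate in
100% of runs, and the mean ACI reduction between alpha 0.9 and alpha 0.25
twins is about 63% -- the same order as the two-thirds reduction reported
when correlated and anticorrelated stride series are imposed on real
acceleration signals.

What a green test does *not* establish: the waveform is phenomenological,
not biomechanical.  Its regularity is higher than real cohorts (step
regularity r ~0.98 versus ~0.85--0.9 in the field), its LDS is lower
(the ML axis is nearly deterministic), and it contains no turning,
no speed drift, no soft-tissue artefact.  Tests against this world
establish that the estimators respond correctly to imposed, known
structure -- not that the generator reproduces human gait.

# Statistics layer

Per-segment metrics land in a tidy table (participant, group, condition,
segment, metric, value), segments are aggregated by mean (singletons kept
and flagged), and group contrasts use Hedges' g (pooled-SD standardized
mean difference with the small-sample correction) with a bias-corrected
percentile bootstrap CI -- 5,000 resamples, seeded, 99% by default; the
bootstrap variant and resample count are design choices, the literature
stating only "bootstrapping".  An optional pre-aggregation 3-SD outlier
filter is off by default and logs removals.  Mixed-effects modelling is
deliberately out of scope: the tidy table is the hand-off boundary to
lme4 or any modelling package.

# Known limitations

* Embedding parameters are declared defaults, not values matched to any
  particular published cohort; full reproduction of published ACI/LDS
  means would require the original parameterization.
* Bout segmentation is automated (variance gate + dominant-frequency
  check) with a manual-override path; the original workflows segmented by
  eye.  A mid-bout pause splits the bout by default (`merge_gap_s`
  bridges only gaps under 2 s).
* The DFA floor of 64 strides is a hard precondition; short free-living
  bouts are out of reach by design.
* The stride detector is validated against the generator's
  impact-spike convention only; real heel-strike morphology differs.
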