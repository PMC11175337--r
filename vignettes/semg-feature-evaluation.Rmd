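---
title: "Methods: sEMG feature extraction, evaluation and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG feature extraction, evaluation and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`semgsel` implements a complete comparative pipeline for surface
electromyography (sEMG) gesture classification: per-channel extraction of 37
time- and frequency-domain signal features, six filter and wrapper
feature-evaluation methods, and a k-nearest-neighbour (kNN) evaluation
protocol with n-best sweeps, channel-membership reporting, and greedy subset
refinement. Because multi-subject sEMG recordings of this kind are rarely
deposited, the package ships a synthetic generator with known ground truth
that emulates the acquisition geometry (15 gestures x 14 subjects x 20
repetitions, 8 channels, 4-second trials at 500 Hz) so the whole analysis
surface is testable end to end.

## The feature set

Each single-channel window `x_1..x_N` (one trial, N = 2000 by default) is
summarized by 37 features. Amplitude descriptors (MAV, IEMG, RMS, SSI, VAR,
RSSQ, MAXAV, MINAV, P2P, MAD0, MAD1, IQR, LD, MMAV1/2), variability and
change descriptors (WL, AAC, DAMV, DASDV, SD, COV), event counts (ZC, SSC,
WAMP), distribution shape (SKEW, KURT, ENTROPY), higher moments (TM3, TM5,
V0), fractional-power sums (AVSER, AVSSR, MVSR), and spectral descriptors
(MNF, MDF, PKF, BP). Column naming is fixed: `ch<c>_<NAME>` in channel-major
canonical order, so 8 channels give the 296-column design matrix.

Several definitions in the myoelectric literature circulate in mutually
inconsistent printed forms; the conventions used here are fixed and
regression-tested:

* **VAR** uses the uncentered sum of squares with an `N + 1` denominator, and
  **AAC** divides its `N - 1`-term sum by `N` — both kept as printed in the
  source literature rather than "corrected", to make results reproducible
  against that literature.
* **MAD1** is the *mean* absolute deviation about the median, despite its
  customary name.
* **MMAV2** uses the standard trapezoidal weights `4i/L`, `1`, `4(L - i)/L`;
  a `paper-literal` mode replaces the trailing ramp by the 0.5 weight of
  MMAV1.
* **Kurtosis** is excess kurtosis (fourth standardized moment minus 3,
  configurable via `kurtosis_offset`), computed on centered samples.
* **Detection thresholds** for ZC, SSC and WAMP default to 0. The comparisons
  are strict (`> 0`), so constant signals produce zero counts; ZC requires
  both a sign change and an amplitude gap at least the threshold.
* **Fractional powers** (AVSER, AVSSR, MVSR, V0) are applied to `|x_i|` and
  summed over all N samples, keeping results real on signed signals.
* **Shannon entropy** uses an equal-width 64-bin amplitude histogram over
  `[min, max]` and natural logarithms; empty bins contribute nothing and a
  constant window has entropy 0.
* **COV** is `100 * sd / mean` with `|mean|` floored at `1e-12 * sd`. On
  signals whose mean is exactly zero this quantity is intrinsically unstable
  (see the generator notes below).
* **Spectral estimates** default to the full-window rectangular periodogram
  (deterministic, resolution `fs/N`); Welch averaging (Hann, 50% overlap) is
  available. MNF is the power-weighted mean frequency, MDF the smallest
  frequency at which cumulative power reaches half the total, PKF by default
  the maximum of the power spectrum (`pkf_mode = "frequency"` returns its
  location). All-zero windows report MNF = MDF = 0 with a warning rather than
  NaN so downstream matrices stay finite.

The scalar definitions are verified against an independent loop-transcription
oracle on 200 seeded random windows (N in 16/500/2000) to 1e-9 relative
tolerance; the compiled batch extractor used by `extract_dataset()` is
asserted equal to the scalar path.

## The six evaluation methods

* **MI** — nearest-neighbour (Kraskov-style) mutual information between each
  feature and the class label (k = 3 neighbours by default). Features are
  rescaled to unit variance and perturbed with tiny seeded noise to break
  ties, the standard treatment for this estimator.
* **UST** — one-way ANOVA F statistic per feature. The statistic is computed
  vectorized across columns and cross-checked against `stats::aov` in the
  tests. Zero within-class variance with separated means yields an infinite
  sentinel ranked first.
* **RFE** — recursive feature elimination with a multinomial
  logistic-regression base model (ridge-regularized, lambda = 0.05 on
  internally standardized features; retried with a stronger penalty if a fit
  fails). Per-feature importance is the L2 norm of the class coefficients;
  the `rfe_step` lowest are dropped each round. The elimination order doubles
  as a full ranking whose top-n prefix equals RFE stopped at n.
* **FI** — impurity importances from an extremely-randomized-trees ensemble
  (100 trees, no bootstrap, sqrt(p) candidates per split, one random split
  point), normalized to sum to one.
* **mRMR** — greedy selection with ANOVA-F relevance and mean absolute
  Pearson correlation redundancy, combined as the quotient
  relevance/redundancy (a difference scheme is available). Exact duplicates
  of already-selected features are deferred while any non-duplicate remains;
  zero-variance features are excluded.
* **BE** — backward elimination on an ordinary-least-squares fit of the
  numerically coded label: repeatedly drop the feature with the largest
  p-value while any p >= alpha (0.05 default). Aliased (perfectly collinear)
  columns are removed first, later columns first.

Ties everywhere are broken by (score descending, column index ascending), so
all rankings are deterministic given data and seed.

## Evaluation protocol

The validation protocol is a single stratified hold-out with
`test_fraction = 0.2`: the total test size is `ceiling(0.2 n)` apportioned by
largest remainder across classes. This granularity is consistent with the
accuracies a 20% hold-out produces on small benchmark datasets (e.g. 20/21 =
95.24%). The classifier is kNN with K = 3 and Euclidean distance; feature
scaling is **off by default**, mirroring a default kNN pipeline on raw
features — it materially affects the results and can be switched on via
`eval_config(standardize = TRUE)`. kNN vote ties are broken with a seeded
RNG, so evaluations are reproducible.

`sweep_n_best()` evaluates the top-n subsets of one ranking on one fixed
split; the default grid is the 15 sizes 35, 45, 55, 65, 75, 85, 100, 115,
130, 140, 160, 175, 200, 225, 250, and best-n ties resolve to the smallest n
(parsimony). For the benchmark harness (`run_benchmark()`), RFE is scored at
`floor(p/2)` features, BE at its significance-determined size, and the
rankers at their accuracy-maximizing n (all n up to 25 features, a coarse
25-point grid beyond) — how the original comparison chose n for rankers is
not documented, so the accuracy-maximizing convention is this package's
choice. `refine_subset()` implements the priority-channel refinement: discard
candidates outside the priority channels, score each singleton addition,
then greedily accept additions that strictly improve accuracy on the same
split; the returned set therefore attains the maximum accuracy among all
evaluated combinations.

## The synthetic generator

Each trial channel is amplitude-modulated band-limited Gaussian noise — the
standard surrogate for sEMG interference patterns — shaped in the frequency
domain to a 20-240 Hz band (the upper edge stays below the 250 Hz Nyquist),
with a per-gesture exponential tilt of the in-band spectrum on informative
channels. Separability is injected only through the gesture-by-channel gain
map and the tilt: there are no within-trial dynamics, matching the
one-window-per-trial analysis. The default gain map gives each informative
channel a cyclic ladder of gains in [0.5, 2] with channel-specific periods
(3, 4, 5, 7, 11, 13), so any two gestures differ on at least two channels;
channels 7 and 8 are globally non-informative negative controls for the
membership analysis. Multiplicative log-normal subject gains (sd 0.1) and
per-trial jitter (sd 0.05) plus a white measurement-noise floor (sd 0.05)
provide realistic nuisance variation while keeping the generator's
self-check: on informative channels the between-gesture spread of mean RMS
exceeds three times the within-gesture RMS standard deviation.

The generator also adds a constant baseline offset (`dc_offset = 0.5`) to
every channel. Raw exports from single-supply commercial sEMG front-ends are
biased away from zero (mid-rail sensor bias, ADC offset), and this matters
for one feature: on an *exactly* zero-mean signal the coefficient of
variation `100 * sd / mean` divides by a near-zero sample mean and becomes
unbounded heavy-tailed noise, which no physical acquisition produces and
which would dominate every raw-scale Euclidean distance. With the baseline
retained, COV is a bounded, amplitude-informative quantity and the
raw-feature kNN protocol behaves as it does on real recordings.

What the generator does **not** emulate: electrode placement and crosstalk,
non-stationarity within a trial (bursts, fatigue drift), motion artifacts,
and realistic class overlap — the synthetic task is considerably easier than
real gesture data (hold-out accuracies saturate near 100% at the default
4200-trial geometry). Passing the end-to-end tests therefore demonstrates
that the pipeline is correct and that the selectors recover known structure,
not that real-data accuracies would match.

## Numerical and cost choices

* Degenerate inputs: all-zero windows floor `|x|` at 1e-12 inside LD and
  report 0 for ENTROPY/MNF/MDF (with a warning); zero-variance features score
  0 under MI, are excluded from mRMR candidacy, and contribute 0 importance.
* The default extraction runs the 33 600 windows of the full geometry through
  a compiled single-pass kernel plus one FFT per window; a full dataset
  extracts in well under a minute.
* RFE's elimination step defaults to 1. For the 296-column n-best sweeps in
  the package's own analysis scripts the step is 5, trading a negligible
  ranking difference for a five-fold cut in base-model fits; fractional steps
  (share of remaining features) are supported.
* Problem sizes in the shipped analyses: the end-to-end study runs the full
  default geometry (4200 trials, 296 features) over 10 seeds; planted-signal
  recovery uses 1000 x 30 tabular datasets over 20 seeds; trace oracles run
  on instances of at most 10 features where brute force is exact.

## Limitations

The package deliberately performs no filtering, rectification or sliding
windows (one trial = one window, raw signal shape), no time-frequency
features, and no dataset downloading. The BE base model follows the classic
OLS-on-coded-labels tutorial procedure; it treats the class coding as
numeric, which is a known simplification of that procedure, not a
recommendation. COV on near-zero-mean signals remains intrinsically fragile;
its instability is documented rather than silently repaired.
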