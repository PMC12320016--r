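---
title: "Characterizing brain states with time-series feature sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing brain states with time-series feature sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statefeats)
```

## The problem

Transitions between brain states — eyes-closed rest (EC), eyes-open rest
(EO), a pre-stimulus baseline (BSL), active visual stimulation (VS) — are
traditionally characterized by oscillatory power in canonical frequency
bands. But band power misses much of what a time series can tell us:
aperiodic (1/f) structure, entropy and complexity, distributional shape,
baseline drifts. `statefeats` implements a pipeline that extracts a rich
41-feature time-domain descriptor set ("TimeFeats") per 1 s epoch and
spatial unit (cortical parcel or electrode), alongside two spectral
benchmark sets, and quantifies the informativeness of each set by how well
a multivariate classifier separates the four states under three
cross-validation regimes.

Because real M/EEG cohorts cannot ship with a package, a first-class
synthetic generator produces multi-subject, four-state epoched signals
with exactly the structure the features measure. Every pipeline stage is
exercised end-to-end against it.

## The feature sets

* **TimeFeats (41)** — the 22 canonical catch22 descriptors (computed on
  the z-scored signal, following that set's convention); the aperiodic
  1/f slope and offset from a peak-excluded log–log fit; mean, median,
  standard deviation, skewness and kurtosis; Hjorth mobility and
  complexity; the rescaled-range Hurst exponent; zero crossings of the
  mean-removed signal; mean curve length (mean absolute first
  difference, raw differences without sampling-rate scaling); and seven
  entropy/complexity measures — sample, approximate, permutation,
  weighted-permutation and spectral entropy, Lempel–Ziv complexity, and
  the Higuchi fractal dimension.
* **FreqBands (6)** — mean periodogram power in delta (1–4 Hz), theta
  (4–8), alpha (8–13), beta (13–30), low gamma (30–45) and high gamma
  (55–100 Hz). Shared integer-Hz edge bins belong to both neighbours;
  the 45–55 Hz gap skips the mains-line region.
* **fullFFT (100)** — power at every integer frequency 1–100 Hz.

Spectra are single-taper Hann periodograms of whole 1 s epochs, one
spectrum per epoch (no averaging: each epoch is one observation). The
normalization is fixed so that the *untapered* non-DC power sum equals
the epoch's population variance — the discrete Parseval identity linking
the standard deviation feature to total spectral power; the test suite
asserts it to 1e-8 relative tolerance.

### Conventions worth stating

* Kurtosis is reported **non-excess** (Gaussian ≈ 3).
* Zero crossings are counted on the mean-removed signal, so the feature
  is orthogonal to the location features; exact zeros count as positive.
* Entropy hyperparameters are the standard defaults: embedding `m = 2`
  and tolerance `r = 0.2 sd` for sample/approximate entropy; order 3,
  delay 1, normalized to [0, 1] for the permutation entropies;
  `k_max = 10` for Higuchi. Lempel–Ziv operates on the median-binarized
  signal, normalized by `N / log2(N)`.
* The Hurst exponent uses classical rescaled-range analysis over dyadic
  windows from 8 to N/2 (the method is recorded here so that it can be
  swapped; detrended fluctuation analysis is a drop-in alternative).
* Degenerate inputs (constant epochs, zero tolerance) produce `NaN`,
  never an error; `NaN`s flow into the imputation stage downstream.

## The peak-excluded aperiodic fit

Separating periodic from aperiodic spectral components is unstable on
1 s segments. The pipeline therefore:

1. averages the spectra of all epochs of one spatial unit;
2. finds oscillatory peaks on that average by iterative Gaussian
   extraction in log10-power space (a robust log–log line is removed,
   the largest residual above `min_peak_height = 0.1` is fitted with a
   Gaussian whose FWHM is constrained to 1–12 Hz, subtracted, and the
   search repeated up to 6 times);
3. masks, in **every** single-epoch spectrum, all bins within
   `center ± bandwidth` of any detected peak (bandwidth = 2 Gaussian
   standard deviations; the exclusion half-width multiplier is
   configurable, 1× bandwidth by default);
4. fits ordinary least squares of log10 power on log10 frequency over
   the retained 1–100 Hz bins of each epoch, yielding per-epoch slope
   and offset (offset defined at log10 f = 0).

Peak detection is implemented natively (a deliberately simplified
iterative Gaussian scheme) so the pipeline carries no binary dependency;
the contract is the (center, height, bandwidth) tuple. The detection
settings above are declared defaults, not estimates of any particular
study's settings. On synthetic 1/f signals with an injected alpha
oscillation, the masked fit recovers exponents 0.5–2 within ±0.15 while
the unmasked fit is biased away by substantially more — this recovery
property, not numerical parity with any external spectral
parameterization tool, is the design goal.

## Classification

Feature tables hold one row per epoch and one column per
feature × spatial-unit pair (feature-major order). Three partition
schemes relate cross-validation folds to subjects:

* **within** — one classifier per subject, k-fold (default 5) over
  contiguous epoch blocks;
* **between** — leave-one-subject-out (or a grouped k-fold that never
  splits a subject, for large cohorts);
* **across** — every subject contributes ~90% of its epochs to training
  and the remainder to testing, rotated over 10 folds; a single-split
  85/15 mode with uniformly placed contiguous holdouts is available for
  cheaper analyses.

Fold contiguity is enforced *within each subject's state block*: the
generator lays epochs out in contiguous state blocks, and cutting folds
as contiguous runs inside each block keeps every training fold exposed
to all four states while preserving the temporal-adjacency rationale
(adjacent filtered epochs can leak into each other). A literal
contiguous split over a subject's full epoch sequence would make most
folds single-state and the within-subject problem ill-posed; this is a
deliberate design choice.

Per fold, preprocessing is fitted on training rows only and frozen:
all-NaN columns are dropped; remaining NaNs are imputed with training
column means; columns are centered on the training median and scaled by
the training IQR (an IQR of 0 is replaced by 1); values are squeezed
through `tanh` into (−1, 1) to curb outliers; finally PCA retains the
smallest number of components reaching 90% cumulative explained
variance. For feature-set runs under the across scheme the PCA is
fitted per feature across its spatial-unit columns (each feature keeps
at least one component); within/between use a single global PCA. A
perturbation test asserts that modifying test rows can never change any
fitted parameter.

The classifier is a soft-margin SVM (C = 10, Gaussian kernel with
`gamma = 1 / (n_columns × mean column variance)`, which reduces to the
common "scale" heuristic on standardized data); multiclass problems are
handled one-vs-one with majority voting, delegated to libsvm via
`e1071::svm` (including its internal tie handling). Accuracy is always
**balanced accuracy** — the unweighted mean of per-class recall — so
label imbalance cannot inflate scores.

## Feature clustering

Redundancy among the 41 features is quantified by `1 − |r|`, the
absolute-Pearson correlation distance computed on each feature's values
concatenated over all epochs, spatial units and subjects, followed by
complete-linkage agglomeration (`stats::hclust`; tie-breaking follows
that implementation). On the default synthetic cohort the location
features (mean, median) merge almost immediately — both track the slow
baseline drift — while the standard deviation sits on a distant branch
with the dispersion-sensitive descriptors, reproducing the qualitative
location-vs-spread cluster structure the feature space is expected to
show.

## The synthetic generator

Each state is an additive model: a 1/f^χ power-law background (white
noise shaped in the frequency domain, unit variance), narrow-band
sinusoids with random phase and optional rectangular burst envelopes
covering a fraction of the epoch at a uniformly placed onset, a constant
per-epoch baseline offset drawn from a slow random walk across each
state block (so mean/median carry state information between blocks), and
i.i.d. Gaussian noise. Defaults: 1 s epochs at 256 Hz, 5 subjects,
10 epochs per state, 4 spatial units, 20% multiplicative between-subject
parameter jitter.

The default state presets encode only *orderings*, not magnitudes, since
real-data effect sizes are not published quantities: alpha amplitude
1.0 (EC) vs 0.35 (EO); 65 Hz gamma amplitude 0.45 (VS) vs 0.1 (BSL);
aperiodic exponents 1.6/1.4/1.5/1.2 for EC/EO/BSL/VS (flatter under
stimulation, consistent with increased cortical excitability); drift
amplitudes 0.5/0.2/0.3/0.3; noise sd 0.3 everywhere. These were chosen
once as values a practitioner would call realistic for source-level
M/EEG and are not tuned further.

What the generator deliberately does **not** model: cross-unit coupling
and source leakage (units are independent), non-sinusoidal waveform
shape, head geometry, artifacts. Passing tests therefore demonstrate
that the pipeline measures what it claims on signals with known
structure — not that any particular accuracy level transfers to real
recordings, where between-subject variability is richer than a
multiplicative parameter jitter.

## Numerical choices and degenerate inputs

* All randomness flows through named seed streams derived from a single
  master seed; identical configurations reproduce bit-identical cohorts,
  tables and classification results.
* Periodogram resolution is 1 Hz at the default epoch length; band
  edges are inclusive.
* The robust aperiodic line for peak detection refits on the bins lying
  closest to the initial OLS line (lower-envelope refit), which
  discounts oscillatory mass without iterative reweighting.
* Zero-power bins are dropped (with a warning) before log-log fitting;
  fewer than 3 usable bins yield an all-NaN fit that the imputation
  stage absorbs.
* Single-class training folds are skipped with a warning rather than
  fitted.
* Constant columns survive robust scaling via the IQR → 1 guard and
  come out exactly zero after centering.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full pipeline at the
default cohort size (5 subjects × 40 epochs × 4 units ≈ 200
observations × 164 TimeFeats columns), 50 epochs per exponent for the
aperiodic recovery study, and 200 label permutations for the
chance-level null. These sizes were chosen so that every stochastic
check has comfortable margins while the whole suite stays quick to run
on a laptop.

## Known limitations

* The catch22 descriptors follow the published definitions but are an
  independent implementation; exact numerical parity with the reference
  C implementation is not a contract (histogram-bin placement and
  fluctuation-analysis split points differ in the last decimals).
* The aperiodic estimator fits the `fixed` (knee-free) model only.
* Within-subject fold counts below the per-state epoch count are
  required (each fold needs at least one test epoch per state).
* The between-subjects scheme is the hardest generalization test and is
  sensitive to the amount of between-subject jitter; with the default
  20% jitter and only 5 subjects its accuracy varies noticeably across
  cohort seeds, while the within ≥ between ordering is stable.
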