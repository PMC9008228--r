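---
title: "Multi-centroid hyperdimensional seizure detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-centroid hyperdimensional seizure detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hdseizure)
```

## The classification model

Hyperdimensional (HD) computing represents every object as a very long
binary vector (here D = 10,000 bits) and manipulates these hypervectors
with three operations: **binding** (element-wise XOR, which associates
two vectors and preserves Hamming distances exactly), **bundling**
(per-bit majority vote over a set, which yields a vector similar to all
its inputs), and **similarity search** (normalised Hamming distance).
Two independently drawn hypervectors sit at distance ~0.5, so random
codebook entries are effectively orthogonal.

An EEG window enters this space in three steps:

1. **Features.** Each 8-s window (stepped every 1 s) of each channel is
   summarised by M = 46 features (see below).
2. **Discretisation.** Each feature is linearly mapped onto L = 20
   levels between its 1st and 99th training-split percentile (values
   outside clip to the end levels; constant features are widened by an
   epsilon so the map is defined). Because all features share one level
   scale, a single value codebook serves all of them.
3. **Encoding.** The level of feature m on channel n selects
   `HDV_Val[l]`, bound (XOR) to the pair's identity `HDV_ChFeat[n, m]`;
   the N x M bound vectors are bundled into one window hypervector.
   Channels are weighted equally. The value codebook is built so that
   level i+1 equals level i except inside the i-th disjoint block of
   `d = floor(D / (L-1))` bits, which is re-randomised; expected distance
   between levels therefore grows linearly with their separation, so
   numerically close feature values stay similar in HD space. (A
   within-block shuffle variant is available via `scheme = "shuffle"`.)

**2-class baseline.** All training windows of a class are bundled into a
single class prototype; inference picks the nearer prototype.

**Multi-centroid training** is single-pass and order-dependent by
design. The first window of a label opens that label's first sub-class.
For each later window, all sub-class prototypes are searched: if the
globally nearest prototype carries the window's label, the window joins
the nearest sub-class *of its own label* (the same vector in that case)
and the prototype — the majority-binarised accumulator — is refreshed;
if the nearest prototype has the wrong label, a new sub-class of the
correct label is created from the window. Nothing constrains the number
of sub-classes; the data decides, which is the method's point: the
number of distinct seizure and background regimes per patient is not
knowable in advance.

Ties are handled deterministically throughout: bundling ties copy a
fixed random tiebreak vector drawn once per model from the model seed;
equal prediction distances resolve to the lowest sub-class index.

## Sub-class reduction

Unconstrained creation can leave sub-classes that hold few windows.
Two procedures prune a trained model, both iterating in steps of 10% of
the *initial* sub-class count (at least 1 per step), ranked by training
population, least-populated first, both labels pooled:

* **Removal** deletes the selected sub-classes (never the last one of a
  label).
* **Clustering** merges each selected sub-class into its nearest
  same-label sub-class by summing accumulators and counts — exactly
  equivalent to bundling all constituent windows directly, so no
  training data is discarded.

After each step the smoothed F1DEgmean on the training windows is
re-evaluated; the procedure returns the last model within 3% (relative)
of the pre-reduction value. The 3% tolerance is interpreted as a
relative drop ("3% of F1DEgmean"); an absolute mode is available
(`relative = FALSE`). Gating uses the training set only; test data is
only ever reported.

## Features

The 46 features per channel and window:

* **37 entropies** (the grid lives in `default_entropy_grid()` and is
  data, not code): sample entropy with embedding m in {2, 3} on
  coarse-grained series at scales {2, 3, 4} (tolerance r = 0.2 sd, the
  standard multiscale-entropy construction; coarse-graining also keeps
  the O(n^2) kernel affordable at fs = 256); permutation entropy of
  orders 3-7 with delays {1, 2, 3}, normalised; Shannon histogram
  entropy with 8/16/32/64 bins; Renyi and Tsallis entropies with
  q in {0.5, 2, 3} and {16, 32} bins. Constant windows return each
  family's analytic floor (0), never NaN.
* **8 frequency-domain features**: relative power in the low-frequency
  [0-0.5], delta [0.5-4], theta [4-8], alpha [8-12], beta [12-30] and
  gamma [30-45] Hz bands (denominator: total power over [0, 45] Hz),
  plus log10 total power and peak frequency. The count of eight is a
  deliberate completion: six named bands alone would leave the
  frequency-domain set at six, and total power and spectral peak are the
  two most standard additions; both are flagged in `feature_config()`
  and can be disabled.
* **Mean absolute amplitude** (sign-invariant).

Power spectra come from a Welch estimator (1-s Hann segments, 50%
overlap), recorded in the config for reproducibility; any consistent
PSD estimator would do. An all-zero window cannot be normalised and
falls back to uniform relative band powers with a flag.

## Evaluation protocol

Each per-seizure file is windowed (8 s / 1 s) and a window is labeled
ictal iff at least half of it overlaps a seizure interval (the boundary
rule is a package choice; annotations never state it). Datasets follow
three balancing regimes — F1, F5, F10: interictal duration equal to,
5x or 10x the ictal duration — drawn as contiguous random segments
outside every `[onset - 60 s, offset + 900 s]` zone, because pre- and
post-ictal EEG carries ictal-like patterns of medically uncertain label.
Validation is leave-one-seizure-out: one file per fold is held out, the
rest train the model; subject performance is the average over folds.

Metrics are computed at two levels: **duration** (per sample) and
**episode** (per seizure event), each as TPR, PPV and F1, combined as
`F1DEgmean = sqrt(F1D * F1E)`. The episode rule is any-overlap: a truth
episode touched by at least one predicted seizure sample is detected;
a predicted episode overlapping no truth episode is one false alarm;
several predicted episodes on one truth episode count once, and one
long predicted episode spanning two truth episodes detects both without
penalty (configurable tolerance margins exist but default to 0; the
cited evaluation conventions do not pin these corner cases down, so the
package states its own). Zero-denominator rates return 0 with a flag so
subject averages stay defined.

Predicted label sequences are smoothed with a centred 5-s moving
majority vote (ties to interictal; edges truncate; a causal mode exists
for on-line use), never across file boundaries; TP/FP/FN counts are
pooled over files before rates are formed. Paired per-subject
comparisons use the two-sided Wilcoxon signed-rank test (exact
distribution for n <= 25 without ties or zeros, normal approximation
otherwise; all-zero differences return p = 1 with a flag).

## The synthetic generator

`generate_synthetic_recording()` emulates the properties of long-term
scalp EEG that this method feeds on, and nothing more:

* interictal background alternating between several **brain-state
  sub-types** (distinct oscillation frequency, amplitude and 1/f-noise
  level per sub-type, epoch lengths 10-40 s);
* several **seizure sub-types** per subject, on a frequency ladder with
  2 Hz spacing, laddered amplitudes and alternating spike-train /
  sinusoidal morphology so sub-types are mutually separable; each
  seizure chirps (frequency falls ~30%, amplitude grows ~60% over the
  event) with small per-event jitter — one seizure spans a trajectory in
  feature space, as real discharges do;
* brief high-amplitude **artifacts** (blink/movement-like, Poisson) and
  seizure-like rhythmic **bursts** of a few seconds drawn from recurring
  per-subject burst types — the non-epileptic activity that drives false
  alarms and forces the interictal class to fragment;
* per-channel gain, phase and independent noise over a shared rhythm,
  a crude stand-in for spatial coherence.

Everything is sample-exact and reproducible from one seed. What it does
**not** model: true EEG spectra and non-stationarity, electrode
artifacts with realistic topography, inter-channel propagation, or any
physiology. Passing benchmarks on this generator therefore demonstrates
that the algorithms behave as designed under controlled heterogeneity
and imbalance — not clinical performance. Real-data claims require the
EDF path (`read_edf()` + CHB-MIT-style side-car annotations) on real
recordings.

The benchmark cohort (`benchmark_cohort_args()`, 20 subjects with 2-3
seizure sub-types each) was calibrated once — sub-type signatures were
tuned until fully-ictal windows of different sub-types form feature
clusters separated by at least 3x their within-cluster spread — and then
frozen. Its problem sizes are deliberately modest so a full cohort
experiment runs on one CPU in minutes: 4 channels instead of the
18-channel montage, 30-min records, 4 seizures of 12-20 s per subject.
The channel count scales compute linearly but carries no extra
discriminative information in the generator (channels share the rhythm),
so results transfer qualitatively to the full montage.

## Numerical and design choices

* D = 10,000 and L = 20 by default; both configurable. L is a
  resolution/robustness trade-off: enough levels that discretisation
  noise stays below feature noise, few enough that adjacent levels stay
  distinguishable (d = 526 bits apart at D = 10,000).
* Normalisation bounds are 1st/99th percentiles of the training split
  only — robust to outliers and leak-free.
* Bundling parity: with the default 18 x 46 layout the bundle size (828)
  is even; ties are resolved by the model tiebreak vector, making
  encoding bit-reproducible given the model seed.
* Prototypes compared during training are the binarised accumulators,
  keeping Hamming distance well-defined at every step.
* Reduction ranks both labels in one pooled list; per-label ranking is a
  config switch away. A floor of one sub-class per label is enforced.
* Bits are stored as unpacked 0/1 integers at the R level (BLAS-friendly
  for batch distance computations via the inner-product identity);
  the C++ training kernel packs them into 64-bit words and uses
  popcounts. The contract is positional equality, not storage layout.

## Known limitations

* Desk-scale training sets (hundreds of windows per subject) spawn only
  a handful of sub-classes, nearly all of which guard a distinct seizure
  sub-type or a recurring false-alarm source. Deep (>= 50%) sub-class
  reduction presupposes a long tail of redundant sub-classes, which
  emerges only with hours of heterogeneous recording per subject; on the
  packaged cohort the reduction procedures therefore stop early rather
  than reach such depths, and held-out performance can shift more than
  the train-side tolerance suggests when a marginal sub-class goes.
* Single-pass training is order-dependent: windows preceding the first
  seizure of the first file can never open interictal sub-classes
  (no wrong-label prototype exists yet). This mirrors the on-line
  setting but makes early data less informative for sub-class structure.
* The Wilcoxon comparison treats subjects as exchangeable; with 20
  synthetic subjects of two sub-type regimes that is an approximation.
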