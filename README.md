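# hdseizure

Multi-centroid hyperdimensional (HD) computing for epileptic seizure
detection from multichannel EEG.

## The problem

Detecting seizures from scalp EEG with a model light enough for wearable,
real-time use is hard because both seizure and background ("interictal")
EEG are highly heterogeneous: one patient can express several distinct
seizure morphologies, and the background wanders through brain states and
is riddled with seizure-like artifacts. A classic HD classifier bundles
all training windows of a class into a single prototype hypervector, so
rare patterns are out-voted by common ones and the minority class suffers
— especially under the realistic class imbalance of continuous
monitoring.

This package implements a **multi-centroid** HD classifier that creates
sub-class prototypes on the fly during a single training pass, plus the
evaluation protocol needed to study it honestly: episode- and
duration-level metrics, leave-one-seizure-out cross-validation, and
balanced / 5x / 10x-unbalanced dataset regimes (F1/F5/F10), together with
a sub-typed synthetic EEG generator so the whole pipeline is testable
without patient data.

## The model

Every 8-s window (stepped by 1 s) of N-channel EEG is summarised by
M = 46 per-channel features (37 entropies; 6 relative band powers over
the low-frequency, delta, theta, alpha, beta and gamma bands, plus total
log-power and peak frequency; mean absolute amplitude). Features are
normalised on the training split and discretised into L = 20 levels.

With two fixed random codebooks — item memory `HDV_ChFeat[n, m]` per
(channel, feature) pair and level memory `HDV_Val[l]` whose neighbouring
levels stay similar — a window becomes a single D = 10,000-bit
hypervector:

    HDV_window = majority_{n,m} ( HDV_Val[level(n,m)] XOR HDV_ChFeat[n,m] )

Training is single-pass. The first window of a label opens its first
sub-class. Each later window is compared with all sub-class prototypes
(normalised Hamming distance): if the nearest prototype has the correct
label, the window is added to the nearest same-label sub-class; if it has
the wrong label, a **new sub-class** of the correct label is created from
that window. Inference returns the label of the nearest sub-class
prototype. Two post-hoc procedures shrink the model under a 3% train
F1DEgmean tolerance: iterative *removal* or *clustering* (merging) of the
least-populated 10% of sub-classes per step.

Performance is scored both per sample ("duration") and per seizure event
("episode"), each as TPR/PPV/F1, combined as
`F1DEgmean = sqrt(F1D * F1E)`; predicted label sequences are smoothed by
a 5-s moving majority vote before the headline figures.

## Worked example

```r
library(hdseizure)

cfg   <- do.call(synth_config, c(benchmark_cohort_args(),
                 list(n_seizure_subtypes = 2, n_background_subtypes = 3,
                      seed = 42)))
rec   <- generate_synthetic_recording(cfg)
files <- build_balanced_files(rec, balancing_config(factor = 10, seed = 1))
res   <- run_crossvalidation(files, memories_seed = 42,
                             models = c("2class", "multicentroid"))
res$summary[, c("model", "n_subclasses_seiz", "n_subclasses_nonseiz",
                "sm_gmean")]
```

```
          model n_subclasses_seiz n_subclasses_nonseiz  sm_gmean
1        2class                 1                  1.0 0.3711151
2 multicentroid                 4                  3.5 0.6840716
```

One synthetic subject with two seizure sub-types, 10x-unbalanced, four
leave-one-seizure-out folds: the classic 2-class model averages a
smoothed test F1DEgmean of 0.37 — it misses held-out seizure sub-types
and false-alarms on seizure-like bursts — while the multi-centroid model
discovers 4 seizure and ~3.5 interictal sub-classes per fold and reaches
0.68.

Real EDF recordings (e.g. CHB-MIT) enter the same pipeline through
`read_edf(path, channels = chbmit_montage())` with a plain-text
`<file>.seizures.txt` side-car (one `onset<TAB>offset` pair per line,
seconds); `inst/cli/hdseizure` exposes `synth`, `extract`, `train`,
`reduce`, `evaluate` and `crossval` subcommands over the same functions.

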