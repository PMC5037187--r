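---
title: "Methods: automatic resting-state network labeling"
author: "rsnlabel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic resting-state network labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnlabel)
```

## Scope and model

`rsnlabel` labels per-subject independent-component (IC) *t*-statistic
maps from resting-state fMRI as one of five canonical networks:
auditory, visual, default-mode, sensorimotor, executive control. The
package assumes preprocessing and spatial ICA happened upstream (an
optional delegation hook, `cmd_decompose()`, hands spatial ICA to an
established external FastICA implementation); its own contribution is
the feature reduction, the three classifiers, the evaluation protocol,
and a synthetic data generator that makes all of it testable without
patient data.

All volumes must share one grid; the loader verifies shape and voxel
size and never resamples. The reference grid is 53 × 63 × 46 voxels at
3 mm (153,594 voxels). Non-finite voxels are zeroed at load so inner
products and correlations stay finite; the in-brain mask defaults to the
nonzero voxels of each map, and a shared explicit mask can override it.
Maps are classified **unthresholded**; display thresholds exist only in
the report renderer.

## Feature space

The feature-based classifiers reduce a map to R × R × R block means.
Each axis of length L is partitioned in voxel-index space into R
intervals [floor(aL/R), floor((a+1)L/R)), a = 0…R−1. This covers every
voxel exactly once, is integer-exact and deterministic, and behaves
sensibly when R does not divide L (or even exceeds it — surplus cells
are empty and yield 0). Only in-mask voxels enter a cell mean; a cell
with no in-mask voxel reports 0 rather than diluting means with
out-of-brain zeros. Features are ordered lexicographically in (i, j, k)
with k fastest, so the vector layout is reproducible across machines.

R ranges over 5…20 in tuning (125–8000 features). Resting data smoothed
at 10 mm FWHM carries little high-spatial-frequency information, which
is why a coarse grid suffices.

For the naïve Bayes classifier the block means are Z-transformed
*within each map* (mean 0, sample SD 1; a constant vector maps to all
zeros) and discretized into 11 bins at cut points −1.2, −0.9, −0.6,
−0.3, 0, 0.3, 0.6, 0.9, 1.2, 1.5. The printed intervals share their
endpoints, so a boundary convention is needed: bins are left-open,
right-closed, the lowest extends to −∞ and the highest is open above
1.5 (so −1.2 falls in bin 1, 0.15 in bin 6, 1.6 in bin 11). Binning is
monotone and total on finite inputs.

**Order of transforms.** The Z-transform could equally be applied at
full resolution before resizing; the wording of the source method
permits both. The package standardizes *after* resizing, i.e. exactly
the quantities the classifier consumes, which makes the binned encoding
invariant to any positive affine rescaling of the input map. The
perceptron consumes raw block means by default
(`perceptron_encoding = "zscore"` switches to standardized input).

## Classifiers

**Template correlation.** Pearson correlation at full resolution over
the intersection of component and template masks; the component inherits
the label of the best-correlating template and the full descending
ranking is returned. A template whose overlap has zero variance has
undefined correlation: it scores −Inf and ranks last; if every template
is undefined the classification errors out rather than guessing. Ties
keep template list order. No reference templates ship with the package
(the published set is not redistributable); users supply a NIfTI + TSV
directory, and `make_archetypes()` fabricates a synthetic set.

**One-vs-all perceptron.** One linear unit per network with a bias
slot. Training uses the classic stochastic rule Δw = η (t − o) x with
t = +1 for the unit's own class and −1 otherwise, o = sign(w·x).
Hyperparameters are not dictated by the source method, so the package
fixes reproducible defaults: learning rate 0.1, 50 epochs,
zero-initialized weights, bias included, per-epoch shuffling driven by
an explicit seed. Prediction is the maximal dot product; exact ties
resolve in the fixed label order (auditory < visual < default-mode <
sensorimotor < executive-control). On linearly separable data the
update rule converges to zero training error — a property the tests
exercise empirically.

**Discretized naïve Bayes.** Priors and per-feature conditional
probability tables are estimated by frequency counting over the bin
codes. Pure counting (α = 0) reproduces the literal rule but a single
unseen (class, feature, bin) combination annihilates a whole posterior,
so the default adds Laplace smoothing α = 1:
P(c) = (n_c + α)/(N + αL), P(v | c, f) = (n_{c,f,v} + α)/(n_c + 11α).
Scoring runs in log space; the label is the argmax with the same fixed
tie order, and the normalized posterior accompanies the label as a
*heuristic* confidence — several similar large posteriors flag a map
spanning learned networks.

`backproject_weights()` renders what a model learned: perceptron
weights painted uniformly over each cell's voxels; for naïve Bayes the
modal bin per cell, shifted by the bin-range center (6) so the image
reads like a signed weight map.

## Evaluation protocol

Cross-validation is at the **subject** level: each LOOCV fold trains on
all components of all other subjects and predicts every component of
the held-out subject, mimicking the clinical scenario of labeling a new
patient. Feature extraction is purely per-component (the Z-transform is
within-map), so the feature matrix can be computed once and subset per
fold without leakage; the fold plan itself is exposed to the tests,
which assert structurally that no held-out subject ever contributes to
its own training fold.

R is selected on a seeded tuning split of half the subjects (rounding
up: 15 of 30, 12 of 23), by LOOCV within the tuning set for each R in
the grid; ties go to the smallest R. Whether the tuning subjects should
then be excluded from the final LOOCV is ambiguous in the source
protocol; the default keeps the full dataset and
`cmd_evaluate(exclude_tuning = TRUE)` provides the other reading.

Per-viewer ground truth is evaluated separately and the resulting
accuracies averaged (`average_over_viewers()`); confusion matrices are
carried per viewer, never summed, because viewers may label different
component subsets. Metrics derive one-vs-rest from the confusion
matrix; zero-denominator cells are reported as `NA`, not 0. Significance
against chance labeling uses the exact upper-tail binomial probability
P(X ≥ correct), X ~ Binomial(n, 1/5), accumulated in log space — totals
here are a few hundred at most, so no approximation is warranted. The
binomial *n* is the component count (the protocol's natural unit of
prediction).

## Synthetic data generator

`make_dataset()` emulates the structure the method assumes, not real
anatomy or hemodynamics:

- **Archetypes** — per network, one or two sum-of-Gaussian-blob maps
  (visual, default-mode, sensorimotor carry two variants, as these
  networks typically split into several ICs), smoothed at the
  configured FWHM and normalized to unit peak. Blob centers are fixed
  fractions of the grid approximating canonical topographies; the
  auditory/sensorimotor and visual/default-mode pairs are deliberately
  the spatially closest, reproducing the confusion structure observed
  with real maps.
- **Subjects** — each of the (default 8) components per subject samples
  an archetype with every network covered, displaces blob centers by
  Gaussian jitter (default SD 6 mm, emulating residual inter-subject
  variability after MNI registration), and adds smoothed white noise.
  Maps are on a pseudo-*t* scale: the smoothed noise field is
  standardized to unit SD and scaled by `noise_sd`, the blob field to a
  peak of `peak_t` (default 8). `noise_sd = 1` is therefore the nominal
  *t*-map regime, and the parameter is a clean separability dial:
  accuracy is provably 1.0 in the fully noiseless limit
  (`noise_sd = 0`, `jitter_mm = 0`) and degrades monotonically as noise
  rises.
- **Viewers** — viewer 1 reports the generating network exactly;
  viewer 2 relabels each component to a random other network with
  probability `viewer_disagreement` (default 0.1), emulating imperfect
  inter-rater agreement.

Everything is a pure function of `generator_config()` including its
single seed; bundles round-trip exactly through the NIfTI + TSV loader.

What passing on synthetic data does **not** show: robustness to real
anatomical variability, artifact ICs, atypical network topology after
pathology, or registration failure. The generator contains no noise-only
components (real ICA output does); classification assumes pre-selected
signal ICs.

## Numerical and design choices

- NaN/Inf voxels → 0 at load; correlations and dot products stay finite.
- Zero-variance inputs: Z-transform of a constant vector returns zeros;
  zero-variance template overlaps rank last at −Inf.
- Tie-breaks are total and deterministic everywhere: fixed label order,
  then lowest template/component index, smallest R in tuning.
- All stochastic steps (tuning split, perceptron shuffling, generator)
  consume explicit seeds; per-subject and per-viewer streams derive
  from the master seed with 32-bit-safe arithmetic, and the package
  never clobbers the caller's RNG state.
- Models serialize to a single JSON document (config echoed); reloaded
  models reproduce predictions to numerical precision (≈1 ulp from
  decimal round-trip).
- Baseline decision-tree/SVM classifiers are thin hooks over rpart and
  e1071 behind the same interface, excluded from core guarantees.

## Problem sizes in the shipped checks

The test suite and the acceptance script exercise the reference scale —
20 subjects × 8 ICs on the 53 × 63 × 46 grid — for the parameter-recovery
checks, with R tuned over the full 5…20 grid on a held-out tuning split.
Because single-dataset LOOCV accuracy has Monte-Carlo spread, recovery
is assessed as the mean over three fixed generator seeds; the noise
monotonicity check uses 8-subject datasets at noise SD 0.25 / 1 / 4
averaged over five seeds. Unit tests run on a reduced 20 × 24 × 18 grid
that preserves the anisotropy of the reference grid.

## Known limitations

- Five networks only; language, memory, fronto-parietal and cerebellar
  networks are out of scope.
- No signal-vs-noise IC triage: inputs are assumed to be signal
  components.
- The correlation classifier is only as good as the supplied template
  set; it has no trained model and no resize parameter.
- Naïve Bayes accuracy is sensitive to training-set size (its
  conditional tables need tens of examples per class) and to the many
  uninformative background features whose bin membership is near the
  0 cut point; the perceptron is markedly more robust at small n on
  the synthetic data.
- Confidence outputs (posteriors, softmaxed perceptron scores) are
  heuristic indicators, not calibrated probabilities.
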