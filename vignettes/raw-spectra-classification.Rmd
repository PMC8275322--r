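---
title: "Phenotype classification from raw SWATH-MS spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype classification from raw SWATH-MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

SWATH-MS (data-independent acquisition) fragments *all* precursors in wide
m/z windows systematically, so a single run carries one MS1 survey series
and one MS2 fragment series per isolation window. Standard analysis
quantifies a curated set of peptides from these data, discarding most of
the recorded signal. `rawms` implements the complementary question: treat
each scan series as an *image* over retention time × m/z, encode the images
with a generic feature extractor, and ask how well a downstream classifier
separates two phenotypes from those features alone.

```{r setup}
library(rawms)
```

## Rasterization model

Each scan series is binned onto a G×G grid. Along m/z the axis is fixed at
0–2000 Th for every spectrum type: MS2 fragments span that range, and MS1
precursors (acquired over 400–1249 Th) fall in the interior, so the columns
outside the acquisition range are structurally zero — black padding that
gives MS1 and MS2 images identical geometry. Along RT, each series' own
span is mapped linearly onto the grid (`per_run_minmax`), scaling every run
to a uniform duration; a `fixed_duration` policy is available when runs
share a known gradient.

Bins are half-open `[lo, hi)` tiles with the top edge closed, so coverage
is total and non-overlapping. A cell's value is the **arithmetic mean of
the recorded points assigned to it** — not a mean over implicit zeros.
Averaging over recorded points only keeps the padding exactly black and
makes a cell's value independent of how many empty scans surround it;
cells receiving no points are 0. Intensities are kept on their raw scale
internally; dynamic-range compression (`log1p_then_linear`) is offered at
export/encoding time, with `linear_max` the default since raw intensities
are the least processed representation.

Grid sizes of 512 and 2048 are the two standard choices: powers of two,
and close enough to typical encoder input sizes that the bilinear resize is
mild. Orientation is fixed — rows are RT ascending downward, columns m/z
ascending rightward — so exported images are comparable across tools.

Degenerate inputs: an empty scan series is an error (a run without scans is
not a spectrum), while a series whose scans all share one RT collapses onto
row 0, since there is no time axis to spread over.

## Encoding

`prepare_image()` fixes the image-preparation chain: intensity transform,
per-image max normalization to [0, 1] (an all-zero grid stays zero),
bilinear resize to the encoder's S×S input, channel triplication to RGB.
Per-image (rather than cohort-level) normalization is used because each
image is encoded independently; no cross-sample statistics leak into the
encoding stage. The bilinear convention is pinned to half-pixel centers
(align-corners-false) so results are bit-stable and testable against an
independent per-pixel implementation.

Pretrained networks differ in their expected pixel range, so
`encoder_spec()` records `unit_interval` vs `symmetric_unit` per encoder;
adapters for external models must document their choice.

External encoders are optional plugins (`register_encoder_backend()` +
`load_external_encoder()`); no weights ship with the package. The built-in
`reference_encoder()` stands in for them wherever a deterministic,
offline encoder is needed: it mean-pools the prepared image into P×P
blocks and applies a fixed Gaussian random projection to D dimensions,
drawn once from a seed. It is a linear map of the pooled image — cheap,
reproducible, and sensitive to any block-level intensity difference, which
is exactly the granularity at which the synthetic cohorts plant signal. It
does not model the nonlinear, hierarchical features of a convolutional
network, so absolute AUCs obtained with it say nothing about any specific
pretrained model; defaults are S = 64, P = 16, D = 256, giving a 256-dim
projection of a 256-block pooled image.

## Feature assembly and constant-feature removal

Per sample, `ms1_only` uses the MS1 encoding (length D); `ms1_and_ms2`
concatenates MS1 and all K window encodings in a canonical order — MS1
first, then windows ascending by lower bound — for length D×(1+K). A
missing window is an error, never silently zero-filled: fabricating a black
spectrum would be indistinguishable from real absence of signal.

Features with zero standard deviation across all samples are removed.
"Zero" is exact equality, not an epsilon: encoder outputs are deterministic
floats, and the constant features of interest (e.g. those tracing always-
black padding) are bit-identical. The default scope is the whole cohort;
dataset-level removal technically looks at test rows, which is benign for
exactly-constant columns but is still exposed as a choice — `train_only`
gives the strictly leakage-free variant.

## Evaluation protocol

For one feature matrix the protocol is: stratified 70/30 split (per-class
test counts `round(n_class × 0.3)`, seeded within-class shuffles);
per-feature min–max scaling **fit on training rows only** and reapplied to
test rows (test values are not clipped; a train-constant column maps to 0
everywhere); hyperparameter grid search by 2× repeated stratified 6-fold
cross-validation selecting on the mean of the 12 fold AUCs, ties broken
toward the first listed grid point; refit on the full training set; metric
suite on the held-out test set.

The grids: logistic regression C ∈ {0.1, 1, 10, 100}; SVC the same C
crossed with linear/poly/rbf kernels; random forest and gradient boosted
trees 100 or 500 trees, other settings at library defaults. `C` is inverse
regularization strength; for the ridge-penalized logistic regression this
maps to a glmnet penalty λ = 1/(nC).

AUC is computed rank-based (Mann–Whitney with half-credit ties) on a
*continuous score*: the decision margin for logistic regression and SVC,
the class-1 probability for the tree ensembles. Brier score and log loss
need calibrated probabilities, so the SVC uses Platt-style internal
calibration; its decision values are orientation-checked against the
training labels because the sign convention depends on class order.
Youden's J is maximized over all ROC thresholds; the thresholded metrics
(accuracy, F1, recall, precision, specificity) use probability 0.5.
Precision and F1 are defined as 0 when no positive predictions exist.

Every source of randomness receives a seed derived deterministically from
one master seed and a stage label (`derive_seed()`), so a full sweep is
reproducible from a single integer, and changing one stage never perturbs
another. Splits are sample-level; when technical replicates of one subject
are present the caller should split by subject before building the matrix,
as replicate leakage inflates test scores.

## Benchmarking statistics

`run_sweep()` crosses resolution × encoder × mode × classifier, recording
per-configuration failures without aborting. `summarize_by_encoder()`
reports median/mean/sample-sd of AUC per encoder, pooling rows over the
other factors; a single-row group reports sd 0 with its n. Contrasts
between variants use a one-sided paired t-test with pairs matched on all
remaining configuration keys (mode contrasts pair on resolution × encoder ×
classifier; resolution contrasts on encoder × mode × classifier), and
rank agreement between variants uses Spearman correlation with average
ranks for ties. Zero-variance differences and constant sequences are
reported as degenerate errors rather than NaN.

## The synthetic cohort generator

The generator emulates the *structure* of a SWATH acquisition, not any
instrument's noise floor. Each run has `n_scans` scans per series over an
`rt_span`-second gradient (defaults 32 and 600 s). Peaks have Gaussian
elution profiles (widths 5–15 s), precursors uniform over 400–1249 Th,
log-normal apex intensities around 10⁴, and 5 fragments each over 0–2000
Th. The isolation windows tile 400–1249 Th contiguously (K = 10 by
default; a full-scale 100-window scheme is a configuration away, at 10×
the cost), and every fragment is routed to exactly the window containing
its precursor, so routing is unambiguous by construction — overlapping
schemes can be *declared* for real data, but the generator never emits
ambiguity. Intensity noise is multiplicative log-normal (σ = 0.3) on peak
points plus uniform-m/z, exponential-intensity background (20 points per
scan, mean 200 ≈ 2% of a typical apex): a minimal heavy-ish-tailed model.

Class signal: of 20 peaks, 5 are discriminative, amplified `fold_change`-
fold in class-1 samples — in both MS levels, or in the fragments only
(`signal_location = "ms2_only"`), which leaves MS1 class-invariant and lets
one measure the information gained by including MS2 features. The default
study conditions are 30 samples per class and fold-change 4, a strong but
not absurd effect (~2 log2 units on 25% of the discriminative-peak mass).

What the generator does **not** model — retention-time drift between runs,
isotope envelopes, charge states, chromatographic tailing, batch effects —
bounds what passing tests show: they validate the pipeline's mechanics and
statistical honesty (signal in ⇒ signal out; no signal in ⇒ chance-level
out), not performance on instrument data.

## Problem sizes used in the shipped tests

The test suite and acceptance script run cohorts of 60 runs with K = 10
windows at grid size 512 (sweep tests use 20 runs, K = 4, grid 128), which
exercises every code path at desk scale; the full-scale geometry (100
windows, 2048² grids, 2048-dim encoders, ~900 samples) is the same code
with larger configuration values. Oracle-equivalence tests (rasterization,
bilinear resize, CV loop, AUC) are exact or at 10⁻¹² tolerance; stochastic
end-to-end properties (signal recovery, null calibration, MS2 gain) are
asserted over seeds 1–5.

## Known limitations

- No retention-time alignment across runs; binning absorbs small shifts
  only.
- The min–max scaler is sensitive to single extreme training values.
- Dataset-level constant-feature removal is the default for fidelity to
  common practice, despite its (benign) use of test rows.
- The reference encoder is a linear descriptor; encoder quality comparisons
  among pretrained networks are out of scope — the package provides the
  harness, not the networks.
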