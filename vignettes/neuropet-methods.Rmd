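---
title: "Methods: synthetic FDG-PET cohorts and volumetric classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic FDG-PET cohorts and volumetric classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropet)
```

## The problem

Distinguishing Alzheimer's disease (AD), mild cognitive impairment (MCI),
dementia with Lewy bodies (DLB) and cognitively normal (CN) ageing from
18F-FDG-PET brain scans is a canonical multi-class neuroimaging task. Two
modelling families compete: a compact 3D convolutional network trained from
scratch on the volumes, and 2D ImageNet-style backbones used as frozen
feature extractors over a mosaic re-encoding of the volume ("transfer
learning"). `neuropet` implements both pipelines end to end — cohort
simulation, preprocessing, training, evaluation, occlusion explainability
and out-of-distribution robustness — so the comparison can be exercised and
tested entirely on synthetic data.

Real multi-site PET cohorts of this kind are access-restricted. The package
therefore ships a first-class generator whose defaults mirror the reference
cohort's structure: 757 cases (200 AD, 200 MCI, 157 DLB, 200 CN, the CN
split 156/44 across two acquisition sites) plus 8 external frontotemporal
lobar degeneration (FTLD) scans, raw grids of 95 x 79 x 79 voxels in a common
template space, and per-class age/sex demographics drawn from the reference cohort's
reported means and standard deviations (truncated to [40, 100]; used only
for manifest realism).

## The generative model

Each scan is

    smooth( baseline x prod_r (1 - delta_r mask_r) x site + noise )

* `baseline` — a smooth ellipsoidal "brain" on a zero background (sigmoid
  shell times a radial falloff, peak 1.0).
* `mask_r` — ellipsoidal proxy regions at fixed template coordinates
  (posterior cingulate, occipital, frontal, temporal, parietal, left
  striatum, pons/thalamus). These are reproducible geometric stand-ins, not
  anatomy; the atlas lives in a versioned YAML file and scales with the grid.
* `delta_r` — fractional intensity reductions per class: AD reduces the
  posterior cingulate (default 0.40); DLB the posterior cingulate (0.30)
  plus occipital cortex (0.35); FTLD frontal and temporal lobes (0.35 each);
  CN nothing. MCI is `lambda = 0.5` times the AD profile, encoding an
  intermediate position on the CN-to-AD axis. The paper-described regional
  patterns fix which regions carry signal; the numeric deltas are the
  package's choice of a "strong effect" operating point, picked so the
  binary task is clearly learnable at desk scale, and are swept towards
  zero by `scale_effects()` when chance-level behaviour must be verified.
  The effect-size sweep is run with the site factor disabled: DLB comes
  exclusively from one site, and the residual noise-scale trace the site
  factor leaves after per-scan standardisation is itself (realistically)
  class-informative, which would mask the chance floor the sweep is meant
  to demonstrate.
* `site` — one multiplicative intensity factor per acquisition source
  (`N(1, 0.05)`), mimicking scanner/protocol differences; per-scan
  standardisation must (and does) cancel it.
* `noise` — i.i.d. Gaussian voxel noise (sd 0.05 against a baseline of 1),
  then isotropic Gaussian smoothing (FWHM 2 voxels) for spatial correlation.

Reproducibility: a single master seed; each subject's noise stream is seeded
by a stable string hash of its id, so a subject's voxels do not depend on
who else is generated or in which order.

What the generator does *not* emulate: PET physics (attenuation, partial
volume, scatter), anatomical variability, registration error, or realistic
covariance between regions. Tests passing on this phantom demonstrate that
the pipeline's machinery is correct and that its statistics behave as
designed — not that the models would reach any particular accuracy on real
scans.

## Preprocessing

Matching the reference pipeline: the first 10 and last 9 axial slices are
discarded (95 x 79 x 79 to 95 x 79 x 60); each scan is standardised
*feature-wise within the scan* — each in-plane position (x, y) is a feature,
each axial slice a sample; features with standard deviation below `1e-8`
(dead background) are set to 0 — then min-max rescaled to [0, 1] per scan.
For 2D backbones the 60 slices are tiled row-major into a 6 x 10 mosaic
(570 x 790 pixels) and replicated across RGB channels. The mosaic transform
is exactly invertible (`mosaic_to_volume()`), which the tests exploit as a
codec round-trip.

Two readings of "feature-wise" were possible (dataset-level statistics vs
per-scan); the per-scan reading is implemented because the description ties
the statistics to "each scan", and because it makes external cases
processable without any training-set statistics leaking in. Whether [0,1]
rescaling is per scan or global is likewise not fully specified; per scan is
used, consistent with the standardisation scope.

## Models and training

The 3D model is four blocks of (3D convolution, ReLU, 2x2x2 max pooling),
then flatten, a dense feature layer (1024 units at full scale) with ReLU
and dropout, and a softmax. Four kernel-depth variants are supported
exactly: first layer 3x3x1 with the rest 3x3x3; all 3x3x3 (the default);
first 3x3x1 with the rest 3x3x6; all 3x3x6. Filter widths (32/64/128/256)
and pooling are the package's choice — the source architecture description
fixes the block count and feature width but not the filter counts, and its
printed trainable-parameter total cannot be reconstructed from the printed
description, so parameter-count parity is explicitly not a target. "Same"
padding is used on all three axes so the depth-6 kernels are well defined at
the volume boundary.

Transfer learning is a contract: a frozen backbone maps a 570 x 790 x 3
mosaic to a fixed-length feature vector; a trainable head (dense, ReLU,
dropout, softmax) consumes it. Because ImageNet weights are out of scope, a
deterministic stand-in backbone (random frozen conv features over a
block-pooled mosaic) implements the contract for testing; its point is
frozenness, determinism and input sensitivity, not pretrained knowledge.

Training minimises categorical cross-entropy with Adadelta (rho 0.95) in
mini-batches of 6, and supports early stopping on the validation loss
(minimum improvement 0.0001, patience 10, best-weights restoration — the
restoration choice makes the reported validation accuracy correspond to the
stopping criterion). The engine is written in R with Rcpp kernels for
im2col/col2im, pooling and smoothing; gradients are verified against
central finite differences in the test suite. Weights use He-uniform
initialisation: with Glorot scaling the ReLU stack's activations shrink by
roughly half per block, and at small widths the head gradient underflows
into a long plateau.

### Full-scale vs desk-scale protocol

The package defaults carry the full-scale protocol (learning rate 0.01,
dropout 0.5, 50 epochs, early stopping; 100 epochs for the fixed-epoch
arm). The test suite and the reports run a *desk-scale* protocol chosen
once: volumes 32 x 28 x 24 (trim 2+2 to 20 slices, 4 x 5 mosaic), class
counts about one fifth of the full cohort, width multiplier 0.125
(4/8/16/32 filters, 128 features), Adadelta learning rate 0.3, dropout 0,
up to 24 epochs (binary) or 32 epochs (multi-class). The rationale: with
roughly one hundred training cases there are only a few hundred optimiser
updates, which never leaves Adadelta's conservative warm-up at the
full-scale learning rate; and dropout 0.5 on a 128-unit feature layer
injects more gradient noise than the small problem's signal. These are
properties of the scaled problem, not retunings of the full protocol, which
remains the default.

## Evaluation

* Stratified splits by (class, site) — the main 89/11 train/test split and
  the 90/10 variant used for the held-out ROC analysis are both supported;
  strata smaller than 2 fall back to training with a warning.
* Repeated stratified k-fold cross-validation (k = 2..10, 10 reshuffled
  rounds by default), retraining from scratch per fold; 95% confidence
  intervals are Student-t over all fold-by-round values (the CI method is
  the package's choice; the source does not state one).
* NMI between true and predicted labels: mutual information normalised by
  the arithmetic mean of the marginal entropies (the variant is the
  package's documented choice). Exhaustively cross-checked against a
  brute-force double-sum oracle.
* One-vs-rest ROC per class via pROC with trapezoidal AUC and unweighted
  macro averaging; verified against a Mann-Whitney pair-counting oracle.
* 2D feature embeddings: unsupervised nonmetric MDS (`MASS::isoMDS`,
  classical-MDS initialisation) of Euclidean feature distances. The
  reference analysis used UMAP; no UMAP implementation exists in this
  package's dependency universe, and nonmetric MDS provides the same role —
  an unsupervised nonlinear 2D projection preserving neighbourhood
  structure — deterministically. Cluster-separation and cohesion behaviour
  is what the analyses consume, and both are covered by tests.

## Occlusion sensitivity

A 6 x 5 pixel window is zeroed out of one axial slice at a time on a
stride-2 grid (1710 positions on a full 95 x 79 slice); the response is the
cross-entropy `-log p(true class)` with the probability clipped at `1e-12`.
Zero is the natural fill value because it is the background level after
[0, 1] rescaling. Maps are averaged per class, projected to voxel space by
coverage-weighted accumulation (each position's response is added to every
voxel its window covers, then normalised by coverage), and tiled into a
7 x 7 mosaic of 49 axial slices blended over the cohort-mean "average
brain"; the 49-tile grid takes 0-based axial slices 5..53. `region_recovery_score()` quantifies localisation on synthetic
ground truth: the fraction of response mass in the top 5% most-responsive
voxels that falls inside the planted mask.

Two occlusion options exist beyond the base protocol, both exercised by the
desk-scale recovery experiment. First, `fill_value` may be a reference
volume instead of a scalar: zero-filling an *already hypometabolic* region
adds disease evidence rather than removing it (the planted lesion is dark;
making it darker pushes the classifier towards the disease class, and the
response never rises there), whereas filling from the average brain erases
the subject-specific evidence — the textbook occlusion semantics for
deficit-type signals. Second, `depth` occludes several consecutive slices:
a well-trained classifier's softmax is nearly saturated, and removing a
single slice's worth of a region that spans four slices leaves enough
evidence that the response stays flat. The desk recovery protocol therefore
runs the 4-way model with a 3 x 3 window, depth 3, stride 2 and
average-brain fill; the package default remains the single-slice 6 x 5
window with stride 2 and zero fill.

## Robustness

External FTLD cases are preprocessed identically (per-scan statistics, no
leakage), classified under the closed 4-class vocabulary, and embedded
jointly with the training features. The qualitative notion "grouped, not
scattered" is operationalised as the cohesion statistic: mean intra-external
distance over mean external-to-training distance (below 1 = grouped;
scale-invariant). Whether a majority-CN or majority-AD assignment is "more
correct" cannot be adjudicated on synthetic data; the tests instead verify
the mechanism — an FTLD profile constructed near the AD profile must
attract AD labels.

## Numerical and design choices

* Probability clipping at `1e-12` before logs; standard-deviation guard
  `1e-8` with zero output for dead features; constant volumes rescale to 0.
* Argmax ties break to the lowest class index, deterministically.
* Adadelta epsilon `1e-6`.
* Max pooling uses floor mode (trailing odd planes dropped), so every input
  dimension must survive four halvings.
* The per-subject RNG-stream design makes cohorts invariant to generation
  order; all stochastic stages (splits, folds, shuffling, dropout) are
  seeded.
* `kfold_cv` interprets "10 rounds of k-fold CV" as 10 independent
  reshuffled k-fold runs per k; the alternative reading (one shuffle,
  10 folds) is a special case.
* Wall-clock training time is reported per round but excluded from written
  reports, which must be byte-identical across reruns.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` train on the desk-scale cohort
(152 cases, 32 x 28 x 20 voxels after trimming) with 3 replicate seeds for
the stochastic claims, 2-3 occlusion subjects per class-average map, and the
structural checks at full 95 x 79 x 60 geometry where no training is
involved. These sizes are the package's reporting conditions; the full-size
conditions remain available through the default configurations.

## Known limitations

* The phantom's regions are geometric proxies; real hypometabolism patterns
  are diffuse, bilateral and correlated with atrophy.
* The stand-in backbone tests the frozen-feature contract, not the value of
  ImageNet pretraining.
* Accuracies measured on the phantom say nothing quantitative about
  clinical data.
* Nonmetric MDS embeddings preserve neighbourhoods but, unlike UMAP, are
  fitted per dataset with no out-of-sample transform; joint embeddings are
  therefore refitted on each train+external concatenation.
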