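---
title: "Exemplar patch features for MRI slice classification: methods and design"
author: "exemplarMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exemplar patch features for MRI slice classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exemplarMRI)
```

## The problem and the model

Multiple sclerosis produces focal hyperintense lesions on brain MRI.
exemplarMRI implements a slice-level classification pipeline that avoids
training a deep classifier end to end on small clinical datasets. Instead
it treats a convolutional network (or a deterministic stand-in) purely as
a *feature extractor*, applies it both to the whole slice and to small
non-overlapping tiles ("exemplars"), and hands the concatenated features
to classical machinery: mutual-information feature selection and a
random-subspace k-nearest-neighbour ensemble.

The stages are:

1. **Brain-area crop.** Otsu threshold on the channel-mean grayscale,
   binary closing (3×3 box), largest 8-connected component, bounding box.
   A uniform image falls back to the full frame with a warning.
2. **Canonicalization.** Anisotropic anti-aliased bilinear resize of the
   crop to 224×224, grayscale replicated to 3 channels, intensities in
   [0,1].
3. **Exemplar decomposition.** The 224×224 canvas tiles exactly into an
   8×8 grid of 28×28 patches (64 exemplars).
4. **Feature extraction.** A backbone maps any image or patch to
   *d* = 1000 features. The whole-image block plus 64 patch blocks merge
   into a 65,000-dimensional vector (whole first, then patches row-major —
   the concatenation order is a declared convention; nothing downstream
   depends on it beyond the feature-name map).
5. **Feature selection.** Greedy mRMR ranking (MID criterion, difference
   form) followed by a cross-validated search over prefix sizes.
6. **Classification.** 30 k-NN learners on random 86-dimensional feature
   subspaces, majority vote, stratified 10-fold cross-validation,
   per-class one-vs-rest metrics.

## Backbones

`extractFeatures()` is the single contract: any spatial input is resized
to the backbone's input size and mapped to `outputDim` finite floats.

**Mock backbone.** Resize, channel-mean grayscale, z-normalize the
flattened pixels, multiply by a seed-fixed Gaussian matrix. It is linear
on the z-normalized image, deterministic, and invariant to affine
intensity rescaling; a constant image maps to the zero vector. Its
internal resolution is 28×28: patches pass through at native resolution,
and the projection matrix stays small (a 1000×224² matrix would hold 50
million entries for no testing benefit). Random projections approximately
preserve pairwise geometry, which is all the downstream k-NN uses.

**Fine-tuned small CNN.** When a trainable backbone is wanted without
pretrained weights, `fineTuneBackbone()` trains a compact network: two
3×3 convolution + ReLU + 2×2 mean-pool blocks whose filters are seeded at
He-scaled random values and then *frozen*, a 4×4 adaptive average pooling
(256 trunk features), a trained fully connected feature layer of width
*d*, and a trained softmax head (Adam, cross-entropy, full batch). Only
the fully connected layers learn — a random-feature convolutional
network. The coarse pooling matters: lesions occur anywhere in the brain,
and with a handful of training slices a head on raw local activations
memorizes the training split and generalizes at chance, while pooled
channel evidence is translation-tolerant. Data are split stratified 70:30
into training and validation; per-epoch accuracies are kept in
`trainingHistory()`. The feature vector is the linear output of the
feature layer (the conv-feature standardization is folded into its
weights, so extraction needs no training-set statistics at run time).

A `pretrainedBackbone()` entry point exists as a documented stub: this
package ships neither network weights nor a deep-learning runtime, and
the constructor says so and points at the two working backbones.

## Mutual information and mRMR

MI is the plug-in histogram estimate in bits: equal-width discretization
into B = 10 bins over `[min, max]` (the maximum lands in the top bin;
constant features collapse to one bin), then
\(I = \sum p(a,b)\log_2 \frac{p(a,b)}{p(a)p(b)}\), computed as
\(H(a)+H(b)-H(a,b)\) and clamped at 0 against rounding. Equal-width
binning is invariant under affine transforms, so standardizing features
before binning would change nothing and is skipped. The estimator is
exact on its discretized inputs — tests compare it against a direct
joint-table oracle — but at n ≈ 60 samples and 10 bins it is a noisy
estimate of the underlying continuous MI; that noise is intrinsic to the
method at desk scale.

The ranking is greedy **MID**: step one takes the most relevant feature;
each later step maximizes relevance minus mean redundancy against the
selected set. The difference form is the standard default and avoids the
quotient form's division by near-zero redundancy. Ties break to the
smallest feature index, with scores within 1e-9 of the maximum counted as
tied so that floating-point summation order cannot flip a pick.

**Subset-size search.** The iterative stage evaluates prefix sizes of the
fixed ranking with stratified 10-fold CV of a 1-NN classifier (Euclidean,
features z-normalized with training-fold statistics) and keeps the size
with minimal error, ties to the smallest. The default grid is
{1,…,9, 10, 20, …, 1000}: on modest sample counts the error curve
typically rises monotonically after a minimum *below* ten features, so a
grid with floor 10 would truncate the search at no cost saving. Prefix
search over a fixed ranking is one reading of "iteratively add or remove
features"; general add/remove search is deliberately out of scope because
it is neither deterministic nor cheaply testable. Selection runs once on
the full feature matrix — the same order of operations as the pipeline it
reproduces — which is optimistically biased relative to nested per-fold
selection; the error curve, not a single headline number, is the honest
output.

## Subspace k-NN and evaluation

Every learner draws `min(86, n_features)` feature indices without
replacement from a learner-specific stream derived from the ensemble
seed. Base learners are 1-NN (the conventional subspace-KNN preset; k is
configurable). Distances are Euclidean on z-normalized features with
statistics learned from training data only. Tie rules are fixed
everywhere for bit-reproducibility: equal distances favour the smaller
training index, tied k-NN votes fall back to the nearest neighbour's
class, tied ensemble votes favour the earliest class in the fixed class
order.

Cross-validation refits the ensemble per fold (fold-specific learner
streams) and accumulates a single confusion matrix. Per-class metrics are
one-vs-rest — accuracy, precision, recall, F1 as percentages to two
decimals — because that is the only definition under which per-class
accuracies can differ. Zero-denominator cases yield 0 with a
`degenerate` flag rather than NaN.

## Synthetic data: what it emulates and what it does not

`generateBrainImage()` draws an off-centre bright ellipse (intensity
about 0.5, slight radial shading) on a near-black background; the
sagittal view is more elongated than the axial. MS slices add 3–6
hyperintense Gaussian blobs (+0.5 on the [0,1] scale, sd between 1/60
and 1/30 of the image side) placed inside the ellipse; all images get
additive Gaussian noise (sd 0.02) and are clipped to [0,1]. These
defaults describe an *easily separable* problem on purpose: they are the
regime in which the pipeline's recovery can be asserted, and parameters
are exposed for harder settings. Geometry, lesions and noise come from
separate seeded streams, so a zero-effect, zero-noise configuration
yields bit-identical images across classes — the generator's own null.
`generateDataset()` assigns disjoint index ranges to the classes so every
image has its own anatomy, as distinct patients would; without that, each
MS image has a healthy anatomical twin and nearest-neighbour classifiers
anti-learn.

What passing tests on these images do **not** show: robustness to real
MRI characteristics — bias fields, partial-volume effects, acquisition
variation, anatomical variability, lesions that are not blob-shaped, or
class effects subtler than focal hyperintensity. Results on the synthetic
fixtures are evidence that the machinery works, not that the method
attains any particular accuracy on clinical data.

The tabular generator (`generateTabular()`) plants `nInformative`
features whose class means differ by `classSeparation` within-class
standard deviations among standard-normal noise features, returning the
informative indices as ground truth for selection-recovery tests.

## Numerical choices and degenerate inputs

* Interpolation: anti-aliased bilinear for all resizing; canonical pixels
  are clamped to [0,1] after interpolation overshoot.
* Intensity scaling: decoded integer images arrive scaled by their bit
  depth; in-memory float arrays outside [0,1] are min-max scaled,
  integer-valued arrays divided by 255 or 65535.
* A uniform image cannot be cropped and falls back to the full frame with
  a warning, not an error.
* Constant features discretize to a single bin (MI 0); zero-variance
  features get unit scale in z-normalization.
* A subspace dimension above the feature count is clamped with a warning.
* All derived seeds stay below 2^31 via multiplicative hashing; every
  stage's seed is recorded in the run report.

## Problem sizes

Package defaults follow the published configuration (224 canvas, 28-pixel
patches, d = 1000, 30 learners, subspace 86, 10 folds). End-to-end
recovery runs use 60 images per class: at that size the 10-fold accuracy
estimate has roughly 2% binomial standard error, so a recovery threshold
is a statement about the method rather than about estimator noise. The
mRMR ranking is truncated to 200 steps and the size grid capped at 200 —
the error curve is far past its minimum by then — and module tests use
small backbone dimensions, which the merged-length contract
(r·c + 1)·d makes equivalent to full scale structurally.

## Known limitations

* Feature selection is not nested within the outer CV (see above). A
  concrete consequence: permutation nulls must be run at the
  classification stage on a fixed feature subset — rerunning full-matrix
  selection against permuted labels reports the selection bias itself
  (a few points above chance at desk scale), not classifier leakage.
* The brain-area crop is a bounding box, not skull stripping or
  segmentation; it is a stated stand-in for an unspecified preprocessing
  step.
* The mock backbone's z-normalization discards patch mean intensity, the
  single most lesion-sensitive statistic; it is a geometry-preserving
  test double, not a tuned representation.
* No volumetric (NIfTI/DICOM) input; 2-D slices only.
* Whether patch features should come from a fine-tuned or stock backbone
  is configurable (`backboneKind`); the pipeline defaults to the mock
  backbone so that the zero-download path is the default path.
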