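---
title: "Recognising activities from textile pressure-sleeve images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising activities from textile pressure-sleeve images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pressureHAR)
```

## The problem

A pressure-sensing sleeve records, at every instant, a 20 x 10 grid of 12-bit
readings (0--4095): a low-resolution "pressure image" of where the forearm is
touching itself, furniture or other objects. Because most daily activities
leave a characteristic contact signature on the arm, these images support
human activity recognition (HAR). `pressureHAR` implements the complete data
path from raw frames to cross-validated classifier scores:

1. a **synthetic-data generator** that emulates a multi-subject recording
   campaign, so every stage is testable without any recorded dataset;
2. **preprocessing**: bilinear upsampling, Gaussian smoothing, anthropometric
   size normalization and exposure-image alignment;
3. a **100-feature static descriptor** per image (statistical, geometric,
   symmetry);
4. an **evaluation harness** (six classical classifiers, stratified 10-fold
   and leave-one-subject-out schemes, macro metrics, ablation grid);
5. a compact three-block **convolutional network** on raw frames.

## The synthetic generator: what it emulates

The unit sample is one *averaged* pressure image per
(subject, round, activity): `nSubjects * nRounds * length(activities)`
frames per campaign, e.g. 14 x 10 x 18 = 2520. Each activity is an
archetype of one to three anisotropic Gaussian contact blobs on the grid
(`defaultActivityArchetypes()`); smooth unimodal patches are what a knitted
pressure matrix records when a forearm rests against a surface.

Three nuisance effects are injected:

* **Body size.** Each subject's forearm length `L_FA` (truncated normal,
  mean 25.5 cm, sd 1.8 cm on [23, 28] cm) and biceps circumference `L_BC`
  (mean 29.0 cm, sd 4.7 cm on [21, 38] cm) define row/column size factors
  `s_row = L_FA / mean(L_FA)` and `s_col = L_BC / mean(L_BC)` (attenuated by
  `sizeEffect < 1`). Blob centres *and* spreads scale by these factors about
  the grid origin, so larger subjects produce proportionally larger contact
  patches at proportionally shifted positions --- exactly the geometry that a
  corner-aligned bilinear resize can undo. The size factors are a
  deterministic function of the sampled anthropometrics so that the
  anthropometric normalization below can be *proven* (on synthetic data) to
  remove the effect. The shipped archetypes are placed so that patterns
  stay within the sensor area across the whole anthropometric range
  (size factors up to ~1.1 by row, ~1.31 by column); contact that slides
  off the sensor edge is physically plausible but not invertible by any
  rescaling, and is deliberately excluded from what the generator emulates.
* **Re-wearing offsets.** The sleeve is taken off and put back on between
  rounds. One rigid integer pixel shift per (subject, round), rounded from
  Gaussian draws (`roundOffsetSd`, default 1 px), is applied to all frames
  of the round.
* **Sensor noise.** Additive Gaussian noise (`noiseSd`, default 25 sensor
  units) with a quiescent floor: readings below `zeroFloor` (default 50)
  report 0, mimicking a fabric sensor that rests at zero with occasional
  crosstalk speckle; values are clipped to [0, 4095] and rounded (12-bit
  ADC).

What the generator does **not** emulate: the 50 Hz time series (only
per-activity averages), biomechanical posture variation, hysteresis and
drift of resistive textiles, and between-subject differences in *how* an
activity is performed. Passing tests therefore demonstrate the pipeline's
internal correctness and its ability to remove the modelled nuisance
effects, not state-of-the-art accuracy on real recordings.

## Preprocessing

Each 20 x 10 frame is upsampled 3x by bilinear interpolation and smoothed
with a normalized 5 x 5 Gaussian, giving the 60 x 30 *smoothed image*. Two
conventions are deliberate:

* the resampler uses the **corner-aligned** sample-position convention
  (output corners coincide with input corners), which reproduces constants
  exactly and makes unit scaling the identity;
* the smoother uses **reflective borders** and `sigma = 1` px
  (conventional for a 5-tap kernel; configurable), so constants are
  preserved and edges are not darkened.

Size normalization computes per-subject ratios
`alpha = mean(L_FA) / L_FA(i)` (rows) and `beta = mean(L_BC) / L_BC(i)`
(columns) and rescales the smoothed image to
`(round(60 * alpha), round(30 * beta))`: images of large subjects shrink
towards the cohort mean, small subjects grow. Rows are tied to forearm
length and columns to biceps circumference because the grid's long side
runs along the arm and its short side around it.

Alignment then removes the re-wearing offset. All scaled frames of a round
are embedded centrally on an 84 x 42 zero canvas and summed into an
*exposure image*; its pressure-weighted centre of mass estimates where the
sleeve sat during that round. The per-round offset is the difference
between the mean centre over all rounds and the round's own centre, applied
to every frame of the round as one rigid shift. Fractional offsets are
applied by bilinear resampling rather than rounding (centres of mass are
fractional); content shifted past the canvas is cropped. Rounds whose
exposure image is identically zero get a zero offset rather than an error.
Scaling precedes shifting, and the shift is estimated *after* scaling, so
that one rigid translation per round aligns all of its frames.

Both images are kept per sample --- normalization can discard information,
so the sample is the pair (smoothed 60 x 30, normalized 84 x 42) and the
image count doubles rather than overwrites.

## The 100-feature static set

All features are computed per image; a sample contributes 200 values
(`smoothed.Feat1 ... normalized.Feat100`). Conventions that the literature
leaves open were fixed as follows:

* **Coordinates**: origin at the upper-left pixel centre, x along the short
  side (columns), y along the long side (rows), 0-based; angles in radians
  from the positive x axis.
* **Activity threshold**: wherever "area" means a pixel count (centroid
  support, bounding rectangle, Feat21, symmetry-side areas), a pixel is
  active iff its value is at least 2 sensor units. The threshold is kept on
  the raw ADC scale after smoothing and scaling.
* **Coverage** (Feat29) counts strictly positive pixels; a threshold at
  "non-negative" values would be vacuous on non-negative data.
* **Contours** (Feat37--40) are 8-connected regions of the image binarized
  at its own mean value; per contour the area (pixel count), pressure
  (pixel sum) and intensity (pressure/area) are computed. The *masked
  image* keeps only the contour with maximal pressure (ties broken by
  first appearance in row-major order) and feeds Feat41--52 and
  Feat77--100.
* **Symmetry splits** assign a pixel to the left/upper side iff its
  coordinate is strictly below the split coordinate (centre of mass or
  centroid), making every split an exact partition of the pressure mass.
  Side ratios are guarded: 0/0 is 1, and ratios are capped at 1e6, so
  feature vectors are always finite.
* **Degenerate images**: an all-zero image has centroid and centre of mass
  at the image centre, zero bounding box, zero contours and zero
  statistical features; every image yields exactly 100 finite values.
* **Entropy** (Feat8) is the Shannon entropy (natural log) of the
  pressure-mass distribution `p_i = v_i / sum(v)`.

The 38-feature baseline (`baselineFeatureNames()`) used by the ablation's
"without the new feature set" arm is a synthetic stand-in assembled from
this package's own statistical and basic geometric features; compact
38-feature spatial sets exist in the literature but are not enumerated
anywhere reproducible, so the harness accepts any named subset.

## Evaluation harness

Features are min--max normalized **per training split** (constant training
features map to 0; test values are clipped to [0, 1]). Fitting the scaler
globally would leak test information into training; the conservative
per-split choice is the default and documented here because published
descriptions are usually ambiguous on this point.

The six classifiers are pinned in `classifierConfig()`: polynomial-kernel
SVM (`e1071`), 5-nearest-neighbour (`class`), l2-penalized multinomial
logistic regression (`nnet::multinom`, weight decay 1e-4, up to 8000
iterations), random forest (balanced class weights, Gini, `log2(p)`
features, fixed seed 40), decision tree (`rpart`, fixed seed 40) and
Gaussian naive Bayes (`e1071`; zero-variance training columns are dropped
because a Gaussian class-conditional is undefined at zero variance).
Hyperparameters not pinned take the R implementations' defaults.

Schemes: stratified seeded 10-fold (per-class round-robin after a shuffle;
stratification is the natural reading when every round contributes one
instance of every class) and leave-one-subject-out (one fold per subject,
measuring generalization to unseen people). Accuracy, macro precision and
macro recall are *averaged over folds*; macro F1 is the harmonic
combination `2PR/(P+R)` of the averaged P and R, so the F1 identity holds
exactly on every emitted result. Confusion matrices are *pooled* over
folds for reporting. Both views are exposed (`perFoldMetrics`,
`confusionMatrix`).

`runAblation()` crosses {with/without size-and-shift normalization} x
{100-feature set / 38-feature baseline} under both schemes. "Without
normalization" uses only the smoothed-image features; "with" uses both
images' features, since the normalized image is what the method adds.

## The convolutional network

Three blocks of 3 x 3 convolution (stride 1, padding 1; 64/128/256
channels), batch normalization, ReLU and 2 x 2 max pooling (stride 2,
spatial paddings (0,1), (1,1), none) map a raw 20 x 10 x 1 frame through
10 x 6 and 6 x 4 to a 3 x 2 x 256 feature map (1536 values), followed by
one fully connected layer of class scores. Training uses softmax
cross-entropy and Adam (learning rate 1e-4, 30 epochs, batch size 40).
The layers, backpropagation and optimizer are implemented natively on
BLAS-backed matrix products; analytic gradients are verified against
finite differences in the test suite.

Choices where the architecture description is silent: inputs are divided
by 4095 to [0, 1] (standard for bounded sensor data; configurable);
max-pool padding uses `-Inf` semantics so padding never wins the max
(equivalent to zero padding on non-negative post-ReLU activations, but
correct in general); the loss is cross-entropy over the class scores; no
early stopping, weight decay or augmentation; cross-validated evaluation
re-initializes the network from scratch in every fold; the CNN consumes
the per-activity averaged frames, not the underlying time series. Batch
normalization uses batch statistics during training and exponentially
averaged running statistics (momentum 0.1) at prediction time.

## Numerical choices and degenerate inputs

* Corner-aligned bilinear resampling everywhere (upsampling, scaling,
  fractional shifts); unit ratios are exact identities (deviation < 1e-9).
* Interpolation can produce values like `-1e-17` on non-negative inputs;
  normalized images are clamped at 0.
* The coverage-quantile cumulative comparison uses a 1e-12 slack so exact
  fractions (e.g. uniform images) do not fall on the wrong side of a
  floating-point boundary.
* Empty datasets preprocess to empty sample sets; all-zero rounds align
  with zero offsets and a warning; single-round datasets get offset (0,0).
* Fold assignment, generator draws, network initialization and minibatch
  shuffles all flow from explicit integer seeds; identical seeds reproduce
  results bit-for-bit on one machine.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen so the whole
suite completes comfortably on a single CPU: structural checks run one
full-size 14 x 10 x 18 campaign (2520 samples) through preprocessing;
property suites use small images and 100 seeded random masks; the
size-normalization recovery and the classifier floors/ceilings use
6 subjects x 3 rounds x 18 activities (324 samples), five seeds for the
recovery analysis; the CNN demonstrations train the full 30-epoch schedule
on one to two hundred samples. `scripts/acceptance.R` recomputes the same
quantities end-to-end at the same reduced scale.

## A worked example

```{r example, eval = FALSE}
cfg <- syntheticConfig(nSubjects = 6, nRounds = 3, seed = 1)
ds  <- generateDataset(cfg)
ss  <- preprocessDataset(ds$frames, ds$anthropometrics)
se  <- extractFeatures(ss)
runKFold(se, k = 10, seed = 1)
runLOSO(se)
```

## Known limitations

* Synthetic blobs are far cleaner than real textile-pressure images; real
  accuracies will be lower and the normalization gain smaller.
* Edge-truncated contact (patterns sliding off the sensor) is not
  invertible by rescaling and is excluded from the generator; on real data
  the normalization can only attenuate, not remove, such size effects.
* The 38-feature baseline is a documented stand-in, not a reproduction of
  any published feature list.
* The native CNN is single-threaded R; it is sized for the 20 x 10 inputs
  it targets, not for larger imagery.
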