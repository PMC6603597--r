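---
title: "Online gesture spotting with a recognition-verification mechanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online gesture spotting with a recognition-verification mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable sign-language recognition fuses two sensor families worn on the
forearm: an 8-channel surface electromyography (sEMG) array, which picks up
the superimposed electrical activity of the forearm muscles, and a 6-channel
inertial unit (3-axis accelerometer + 3-axis gyroscope) capturing arm
motion. Both are sampled at 100 Hz, giving a continuous 14-channel stream.

Offline classification of pre-cut gesture samples is a solved problem at
high accuracy; the hard part is *online* recognition from a continuous
stream. The stream contains effective regions (genuine gestures), blank
regions between them, and -- crucially -- non-gesture interference: walking,
arm swings, grasping. Interference is not noise; it is real movement with
gesture-scale signal energy, so energy-based segmentation cannot tell it
from a gesture.

`slrmech` implements two complete mechanisms for this problem:

* the **recognition-verification mechanism**: a sliding window pulls
  128-point snippets (random step of 8-20 samples); each window is
  preprocessed, classified by a 1D convolutional network, and then
  *verified* -- a Siamese encoder maps the window to a 64-dimensional
  vector, and the result is accepted only if the Euclidean distance to the
  predicted class's reference vector (the "difference") is strictly below
  that class's threshold. Accepted results skip the next few window steps.
* the traditional **segmentation-recognition baseline**: windowed-energy
  voting rules locate segment boundaries, handcrafted features (RMS,
  zero crossings, AR coefficients, STFT / PSD / wavelet energies) are
  extracted, and an RBF-kernel SVM classifies each segment. No
  verification stage exists, so every segment classification is final.

A five-way misrecognition taxonomy scores either mechanism against ground
truth: *insert* (blank recognized as gesture), *misalignment* (window
straddling a region edge), *repeat* (region correctly recognized twice),
*substitute* (wrong class), *delete* (region missed), plus *correct*.

## Preprocessing

A raw 14 x 128 window becomes the 14 x 64 network input:

* **Inertial channels** are smoothed by piecewise quadratic fits
  (`y = A n^2 + B n + C` over 16-point units, least squares). Adjacent
  units share a 2-point overlap whose two fits are averaged, removing the
  jump a disjoint piecewise fit would create; the reconstruction is then
  kept at every other point. The unit length (16) matches the transform
  frequency of arm motion at 100 Hz; the overlap width is our choice (the
  mechanism only requires *some* overlap) and is exposed in
  `smoother_config()`.
* **sEMG channels** are denoised and compressed: Fourier components below
  15 Hz (the noise band of this sensor class) are removed, samples under
  an amplitude floor (3 x the channel's median absolute deviation by
  default) are zeroed, and a 4-level periodized db5 discrete wavelet
  decomposition is applied. The deepest approximation band (8
  coefficients) is scaled back to signal amplitude and linearly
  interpolated onto 64 points; a coefficient-concatenation variant
  (`extend = "concat"`) keeps the detail bands instead. The interpolation
  reading of "extending" the transformed data is a design choice; both
  variants produce the contract length of 64.
* Finally each channel is z-normalized with statistics frozen on the
  training split -- sEMG and inertial channels otherwise live on scales
  orders of magnitude apart. Training and online recognition run the
  identical code path (`preprocess_window()`).

The db5 filter bank is periodized and orthonormal, so the decomposition
preserves energy exactly; the analysis step is validated in the test suite
against an independently computed reference decomposition.

## The classification model

`build_architecture()` constructs 1D VGG-style networks: blocks of
kernel-3, stride-1, padding-1 convolutions (each followed by batch
normalization and a Leaky ReLU with slope 0.01), 2x max-pooling after every
block, adaptive average pooling to 2 points per channel, and a single fully
connected layer onto the class scores. Five named layouts A-E are built in;
structure D -- blocks of 64 / 128 / 256,256 / 512,512 channels -- is the
default operating point and yields a 1024-dimensional flattened feature.
Blocks nearer the output never have fewer convolution layers than earlier
blocks; the builder enforces this.

Training uses softmax cross-entropy with Adam, batches of 128, initial
learning rate 1e-4 scaled by 0.1 every 10 epochs, and normal-distribution
weight initialization (sd 0.02, our choice of scale). All randomness runs
under the caller's seed; two runs with the same configuration are
bit-identical.

Convolutions are lowered to BLAS matrix products through an im2col gather
written in C++ (RcppArmadillo); everything else -- batch-norm statistics,
pooling masks, Adam -- is plain R on matrices.

## The verification model

The Siamese encoder shares the classifier's convolutional trunk (structure
D + adaptive pooling, 1024 features) and adds a 1024 -> 64 fully connected
head. Both branches are literally the same parameter set. Training pairs
are drawn at 5x the dataset size, half same-class and half cross-class,
with a 90/10 train/test split of the pairs.

Two pairwise losses are provided on the encoding distance `D`:

* the classical **contrastive loss**
  `(1-Y) D^2/2 + Y max(0, m - D)^2/2`, whose gradient is exactly zero for
  cross-class pairs beyond the margin -- the sparsity that slows its
  convergence; and
* the **sigmoid modification loss**: `p = sigmoid(D - m)` is read as the
  probability that the pair is cross-class (`p = 0.5` exactly at the
  boundary point `D = m`), trained with binary cross-entropy against the
  pair label. The published form of this loss names the label in its
  signature without placing it in the formula; the cross-entropy reading
  reproduces every stated property (0-1 range, 0.5 at the boundary,
  nonzero gradient everywhere) and is what `train_verifier()` uses by
  default.

The margin `m` has no published value; the default (10) sits between the
typical same-class and cross-class encoding distances the loss itself
produces and is a plain configuration field, not a constant.

Convergence is monitored on held-out pairs through L1 (95% quantile of
cross-class distances) and L2 (5% quantile of same-class distances);
training stops early when both change by less than 1% over three
consecutive epochs -- our concrete reading of "stable". Initializing the
trunk from the trained classifier ("transfer") reaches any given loss level
at least as fast as normal initialization and is the default.

## Reference vectors and thresholds

Each class keeps a standard reference vector: the mean encoding of its
training samples. The class threshold is `2.5 x Sd(I)` where `Sd` is the
ascending sequence of within-class differences and `I = floor(0.8 N)`
(1-based, at least 1 -- an order statistic needs an integer index). On the
original sensor scale these thresholds were operationally clamped into
[14, 18], and the package ships the published 86-class threshold table
(`load_reference_thresholds()`); 78 of its 86 values (90.70%) already lie
in that range.

The clamp range is a property of that sensor scale, not of the rule. On
synthetic data the encodings are tighter and the same rule lands at smaller
absolute values, so the packaged experiments build reference sets with the
clamp disabled (`threshold_config(clamp_low = 0, clamp_high = Inf)`) --
exactly as the baseline's energy threshold (582 on the original scale) is
recalibrated rather than copied. `threshold_config()` defaults remain
14/18 for fidelity.

## What the synthetic generator emulates -- and what it does not

No public corpus of fused sEMG/inertial sign-language recordings exists, so
`slrmech` generates its own study data. The generator emulates:

* per-class sEMG amplitude envelopes (multi-Gaussian bumps) modulating
  band-limited carrier noise -- sEMG is stochastic; only its envelope
  carries class information;
* smooth per-class inertial trajectories plus white jitter;
* sample lengths uniform in 164-207 points at 100 Hz, with the central
  128 points used as the core;
* an empty class (near-silent channels);
* repetition-to-repetition execution variation: per-sample amplitude
  scaling (+-20%) and timing shift (+-5% of the sample). Without this,
  same-class encodings collapse to near-zero distances and the
  quantile-based threshold rule degenerates;
* continuous streams with 0.5-5 s blank gaps and optional non-gesture
  interference bursts drawn from a disjoint pool of movement shapes with
  gesture-scale amplitude, injected only into blank regions and never
  annotated.

It does **not** emulate electrode shift, muscle fatigue, crosstalk between
channels, subject-to-subject variation, or the heavy class imbalance of
real vocabularies. Passing tests on this data shows the mechanisms are
implemented correctly and behave in the published directions (verification
removes inserts; the baseline cannot reject interference); it does not
certify real-sensor accuracy figures.

Default test-scale conditions: 10 classes (the full 86 are supported),
500 training / 100 test samples per class for the packaged training
experiments, noise standard deviation 0.1 on the unit envelope scale --
documented bound for nearest-centroid separability is 0.3.

## Numerical and design choices

* Coordinates are 0-based half-open `[start, end)` everywhere: regions,
  window spans, segments, events.
* The energy segmenter's voting rules are applied literally: the boundary
  is the first sample of the firing group's first window, even if that
  window itself is below threshold.
* `calibrate_energy_threshold()` uses the *median* blank-region energy
  times a headroom factor (default 10): interference bursts are genuine
  movements that live in blank regions, and an extreme quantile would let
  them drag the threshold above gesture energy.
* Evaluation overlap thresholds (0.25 / 0.6 of the window) quantify the
  insert / misalignment / aligned boundary; the underlying "adjacent zone"
  has no published width, so both are configuration, and baseline
  segments (variable length) use the shorter of segment and region as the
  denominator.
* Skip-ahead after acceptance defaults to 5 steps ("several"); rejected
  windows are still emitted with `accepted = FALSE` for diagnostics, and
  empty-class predictions are suppressed entirely.
* Problem sizes in the test suite: the shared small pipeline uses 5
  classes x 40 samples and a 3-block network; the packaged training
  experiment uses 10 classes x 600 samples with structure D, trained for
  6 epochs (the accuracy contract allows up to 20) and 2 verifier epochs
  from transfer initialization. These sizes are the package's chosen
  experiment scale.

## Known limitations

* The verification stage can only reject what the classifier proposes; a
  stream with no empty-class training data would force every blank window
  into a gesture class and lean entirely on thresholds.
* Gating monotonicity (every event accepted with verification is accepted
  without it) holds exactly only when skip-ahead is disabled, since
  acceptance changes which later windows are evaluated.
* The published threshold clamp [14, 18] and energy threshold 582 are
  sensor-scale constants; any new sensor (or the synthetic scale) needs
  the packaged calibration paths, not the constants.
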