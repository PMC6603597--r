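# slrmech

Online sign-language (gesture) recognition from fused wearable sensors:
8-channel surface electromyography (sEMG) plus a 6-channel inertial unit
(3-axis accelerometer, 3-axis gyroscope), sampled at 100 Hz as a continuous
14-channel stream.

The package is for researchers in biomedical signal processing and
gesture/sign-language recognition who need a complete, reproducible
implementation of the **recognition–verification mechanism** for continuous
streams — and of the traditional **segmentation–recognition** baseline to
compare it against.

## The mechanisms

**Recognition–verification.** A 128-point sliding window (random step, 8–20
samples) pulls data continuously; there is no segmentation. Each window is
preprocessed to a 14×64 input (piecewise quadratic smoothing + 2×
down-sampling for inertial channels; sub-15 Hz denoising, amplitude
flooring and a 4-level db5 discrete wavelet transform for sEMG channels),
classified by a 1D VGG-style convolutional network (structure D:
64 / 128 / 256,256 / 512,512 channel blocks, batch norm, Leaky ReLU
λ = 0.01, adaptive average pooling to 2, one fully connected layer), and
then *verified*: a Siamese encoder (the classifier's trunk + a 1024→64
head) maps the window to a 64-dim vector **v**, and the prediction *c* is
accepted iff the difference

&nbsp;&nbsp;&nbsp;&nbsp;d = ‖v − r_c‖₂ < V_Th(c)

where r_c is class *c*'s reference vector (mean training encoding) and

&nbsp;&nbsp;&nbsp;&nbsp;V_Th(c) = 2.5 · S_d(⌊0.8 N⌋)

is 2.5 times the 80% quantile of the ascending within-class difference
sequence S_d (operationally clamped to [14, 18] on the original sensor
scale). Accepted results skip the next few window steps. The verifier is
trained on sample pairs (5× the dataset, half same-class) with the
**sigmoid modification loss**: p = σ(D − m) is the probability the pair is
cross-class (boundary point m, p = 0.5 at D = m), scored with binary
cross-entropy — unlike the contrastive loss it has no zero-gradient region.

**Segmentation–recognition baseline.** sEMG is high-passed at 5 Hz; the
mean energy E = (1/16) Σ_c Σ_j R_c²(j) of non-overlapping 16-sample windows
is compared with a threshold; a segment starts when 4 of 6 consecutive
windows are above it and ends when 5 of 7 fall below. Each segment yields
handcrafted features (sEMG: RMS, zero crossings, AR(4), STFT; inertial:
RMS, AR(4), Welch PSD bands, wavelet sub-band energies) classified by an
RBF-SVM (C = 256, γ = 0.0175).

Runs on continuous streams are scored by a five-way misrecognition
taxonomy: **insert**, **misalignment**, **repeat**, **substitute**,
**delete**, plus **correct**.

Because no public corpus of this sensor combination exists, the package
includes a first-class synthetic generator: per-class envelope-modulated
sEMG and smooth inertial trajectories, an empty class, per-repetition
amplitude/timing variation, annotated streams with 0.5–5 s blank gaps and
non-gesture interference (arm swings, grasps) injected into blanks only.

## Worked example

```r
library(slrmech)

cfg <- generator_config(n_classes = 5, samples_per_class = 40,
                        noise_sd = 0.1, interference_rate = 4)
ds  <- build_offline_dataset(cfg, seed = 3)
pp  <- preprocess_dataset(ds)

arch <- architecture_spec(list(8, 16, c(32, 32)))   # small 3-block network
clf  <- train_classifier(pp, arch, train_config(batch_size = 32, lr = 1e-3,
                                                epochs = 10, seed = 7))
ver  <- train_verifier(pp, cfg = verifier_config(batch_size = 64, lr = 1e-3,
                                                 epochs = 6, margin = 10,
                                                 seed = 5),
                       classifier_model = clf, arch = arch)
refs <- build_reference_set(ver, pp, threshold_config(clamp_low = 0,
                                                      clamp_high = Inf))

st <- compose_stream(ds$templates, schedule = rep(1:4, each = 3), cfg,
                     seed = 21)
sw <- sliding_window_config(seed = 9)
with_ver <- run_online(st$stream, clf, ver, refs, sw)
no_ver   <- run_online(st$stream, clf, ver, disable_verification(refs), sw)
print(score_run(with_ver, st$regions))
print(score_run(no_ver,   st$regions))
```

Output:

```
taxonomy_counts: insert=0 misalignment=0 repeat=0 substitute=0 delete=0 correct=12
taxonomy_counts: insert=4 misalignment=9 repeat=1 substitute=12 delete=0 correct=10
```

All 12 scheduled gestures are recognized correctly with verification; with
verification disabled (thresholds +∞) the same classifier on the same
stream produces 4 inserts (interference bursts accepted as gestures), 9
misalignments, 12 substitutes and a repeat. That difference — the
verification stage filtering the classifier's mistakes on continuous data —
is the mechanism's point.

The published per-class threshold table for the original 86-category
vocabulary ships with the package:

```r
s <- threshold_summary(load_reference_thresholds()$threshold, 14, 18)
str(s)
#> List of 2
#>  $ count_in_range: int 78
#>  $ fraction      : num 0.907
```

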