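---
title: "Attention placement in a spectrogram CNN for heart sounds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention placement in a spectrogram CNN for heart sounds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Auscultation records the heart's mechanical activity as a phonocardiogram
(PCG). The two fundamental sounds, S1 and S2, mark the onset of ventricular
systole and diastole; pathological recordings add murmurs — band-limited
acoustic energy, typically between S1 and S2 — and other anomalies.
`pcgcbam` implements a binary (normal/abnormal) PCG classifier: fixed-window
segmentation, log-power spectrogram images, and a small CNN whose
convolutional blocks can be augmented with the Convolutional Block Attention
Module (CBAM) in any of $2^6$ placements, of which twelve canonical ones are
studied.

## Pipeline stages and their parameters

### Segmentation

Recordings (mono, 2 kHz nominal) are cut into non-overlapping windows of
`window_seconds` (default 5 s, i.e. exactly 10,000 samples), covering a
prefix of the recording; the trailing remainder is discarded and recordings
shorter than one window are skipped into a log rather than raising errors,
so corpus statistics remain auditable. A 5-s window reliably contains at
least one full cardiac cycle (2–3 s at rest) and therefore at least one
systolic interval in which a murmur can appear.

Amplitudes are normalized by the PCM full-scale value of the source bit
depth (32768 for 16-bit), *not* per-file maxima: per-file normalization
would erase relative loudness, which is a diagnostic cue. Inputs at other
sampling rates are polyphase-resampled to the configured rate with a logged
warning.

### Spectrograms

The STFT uses a 256-sample Hann window (128 ms at 2 kHz), 64-sample hop and
512-point zero-padded FFT. These values resolve the 10–400 Hz band where
S1/S2 and murmur energy is concentrated (frequency resolution ≈ 3.9 Hz)
while yielding 153 frames per 5-s window (time resolution 32 ms). Magnitude
is mapped by $\log_{10}(|X|^2 + \varepsilon)$ with $\varepsilon = 10^{-10}$;
the matrix is flipped so row 1 is the highest frequency, bilinearly resized
to `height × width` (504 × 864 by default, read as an image's width × height
of 864 × 504), and min–max normalized per image to $[0,1]$, which removes
recording-gain differences. Degenerate all-constant inputs map to an
all-zero image — the $\varepsilon$ floor guarantees finiteness, never NaN.
The model consumes the matrix directly; 8-bit PNG export
(quantization error ≤ 1/255) exists for inspection and caching.

### The synthetic generator

No clinical data ships with the package; a seeded generator emulates the
statistical structure the pipeline assumes:

* cardiac cycles at a uniform heart rate in `bpm_range` (default 60–100
  bpm), with a Gaussian-enveloped S1 tone burst (default 60 Hz, ~40 ms) at
  each cycle start and an S2 burst (default 110 Hz) at 55 % of the cycle —
  systole shorter than diastole, conventional physiology;
* for the abnormal class, flat-spectrum noise band-passed to
  `murmur_band_hz` (default 150–400 Hz, 4th-order Butterworth, zero-phase)
  and shaped by a half-sine envelope across each S1→S2 interval; its level
  is set by `murmur_snr_db` relative to the clean S1/S2 RMS — the
  *separability knob*: as it grows, band-power alone decides the class;
* a white noise floor (default −30 dB) and per-burst amplitude jitter
  (10 %).

Recording $i$ uses sub-seed `seed + i`, so corpora are extensible without
rewriting history, and identical configurations are bitwise reproducible.
The generator mimics the time–frequency *footprint* of a systolic murmur,
nothing more: no murmur taxonomy, respiration, or sensor transfer
functions, and its classes are far cleaner than clinical data. Green
end-to-end tests therefore demonstrate that the pipeline can learn a
separable spectro-temporal class structure — not clinical-grade accuracy.

### CBAM

Channel attention: $M_c = \sigma(W_1\,\mathrm{ReLU}(W_0\,\mathrm{avg}) +
W_1\,\mathrm{ReLU}(W_0\,\mathrm{max}))$ over global spatial average/max
pools, with the MLP shared between branches, no biases, and reduction ratio
$r$ (default 16, standard CBAM practice; the hidden width is clamped to
$\geq 1$ for layers narrower than $r$, e.g. $C=32 \Rightarrow$ hidden 2).
Spatial attention: channel-wise mean and max maps stacked and convolved
with one $k\times k$ kernel (default $k = 7$, odd so "same" padding
centres it) plus a single bias, then a sigmoid. The refined map is
$M_s \otimes (M_c \otimes F)$, computed from the channel-refined map, so
CBAM is an elementwise contraction: both factors lie strictly in $(0,1)$.

CBAM is attached after a conv block's ReLU and before the stage's pooling;
the placement is configurable. Ties in the max-pooling branches resolve to
the first index (deterministic).

### Backbone and the twelve placements

Three stages of two 3×3/stride-1/"same" conv blocks with 32/32, 64/64,
128/128 filters; one 2×2 max pool per stage (after the second block)
followed by dropout 0.2; then FC(500)/ReLU/dropout 0.3 and a softmax with
categorical cross-entropy (chosen over a sigmoid for numerical stability
with this loss and for multiclass headroom). A 6-bit mask over blocks
(1-1, 1-2, 2-1, 2-2, 3-1, 3-2) selects CBAM positions; `model_from_id()`
returns the twelve canonical masks (1 = none … 7 = {1-1, 1-2, 2-1} … 12 =
all), pinned cell-for-cell in the tests.

The default input is a downscaled spectrogram (126 × 216; any size
surviving three 2×2 poolings is valid). Full 504 × 864 inputs are
supported by configuration but make the flatten→FC(500) layer very large;
at desk scale we run 24 × 36 inputs (see below). Max pooling uses floor
semantics (an odd trailing row/column is dropped).

### Training harness

Adam (lr $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size 10.
After each epoch the validation loss drives (a) plateau decay — multiply
the lr by 0.5 after 5 epochs without improvement, floored at $10^{-7}$ —
and (b) early stopping after 15 epochs without improvement, with
best-epoch weights restored. "Improvement" is a strict decrease by more
than $10^{-9}$; the initial best is $+\infty$, so the first finite epoch
counts as an improvement. These semantics are implemented as a pure
stepper (`simulate_schedule()`) so they are testable with scripted loss
sequences, and the training loop consumes the same stepper. `max_epochs`
defaults to 100 (early stopping normally fires first). A non-finite loss
aborts with a diagnostic rather than training on.

Cross-validation folds are stratified by class and, by default, grouped by
source recording: overlapping windows of one recording never straddle the
train/validation boundary, which would leak. A `split_by = "segment"` mode
(segment-level stratification) exists for protocols that split at the
spectrogram level. No class weighting or oversampling is applied by
default, matching the plain protocol the ablation assumes; both are
deliberate non-features rather than omissions.

### Evaluation and separability

Abnormal is the positive class: accuracy $(TP+TN)/N$, precision
$TP/(TP+FP)$, sensitivity/recall $TP/(TP+FN)$, $F1 = 2PR/(P+R)$. Zero
denominators yield `NaN` plus an explicit flag — never a silent 0. The
decision rule is argmax with ties to normal (conservative for screening).
AUC is the Mann–Whitney statistic on the abnormal-class softmax score
(ties count ½), equivalent to exhaustive pair counting and cross-checked
against an independent ROC library in the tests.

Features for separability are the flattened activations after the third
stage's pooling, in inference mode. The exact ($O(n^2)$) t-SNE uses
perplexity 30 (auto-reduced to $\lfloor (n-1)/3 \rfloor$ when the fold is
small), 1000 iterations, early exaggeration ×4 for 100 iterations,
momentum 0.5→0.8 at iteration 250, learning rate 200, and a fixed seed; it
requires $n \ge 3\,\times$ perplexity. The three reported statistics are
computed in the 2-D embedding: per-class mean distance to the class
centroid (a mean-pairwise-distance variant is available by flag) and the
Euclidean distance between the two class centroids. All three are
translation invariant and scale equivariantly — properties the tests pin.

## Desk-scale study conditions

`desk_scale_conditions()` freezes the configuration used by the end-to-end
ablation in the tests and in `scripts/acceptance.R`: the corpus class
balance scaled down 100-fold (26 normal / 7 abnormal recordings), 10–30 s
durations (≈120 five-second spectrograms), murmur SNR +15 dB, 24 × 36
spectrogram images, a 5-fold grouped stratified split with one fold
evaluated, and 15 training epochs. The sizes were chosen by flop
arithmetic so that three full models (1, 7 and 12) train sequentially on a
single CPU in minutes while leaving the learning problem non-trivial: the
24-row frequency axis still separates the murmur band (150–400 Hz) from
the S1/S2 band (< 120 Hz), and at this SNR the classes are separable in
principle by band power, so a model that fails to reach high validation
accuracy is failing at learning, not at an impossible task. With seven
abnormal recordings a 10-fold grouped split is impossible; 5 folds is the
largest grouped stratified choice, and full 10-fold CV remains available
via `make_folds()`/`crossvalidate`-style loops at larger scales.

## Numerical choices and degenerate inputs

* Convolutions use "same" zero padding everywhere, pinned for shape
  determinism.
* Weight init: He for conv layers, Glorot-style for the FC and CBAM
  parameters; all seeded.
* Max-pool and attention argmax ties break to the first index.
* All-zero inputs: spectrogram → all-zero image; zero-parameter CBAM →
  attention 0.5 everywhere; zero-weight network → zero features.
* WAV I/O is 16-bit PCM; quantized samples round-trip bitwise.
* t-SNE distances, not raw-feature distances, feed the separability
  statistics (the embedding is what the statistics describe).

## Known limitations

* The synthetic corpus is far easier than clinical PCG; results on it
  bound nothing about real-world accuracy.
* The backbone is intentionally small; no pretrained baselines (VGG16,
  ResNet50) are included.
* Exact t-SNE is $O(n^2)$ per iteration — fine for hundreds of points, not
  for tens of thousands (subsample first).
* Training is single-threaded CPU; at full 504 × 864 resolution the FC
  layer dominates memory and the flatten width is large — use downscaled
  inputs unless you have a specific reason not to.
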