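# pcgcbam

Binary classification of heart sounds (phonocardiograms, PCG) with a compact
convolutional neural network whose convolutional blocks can be augmented by
the **Convolutional Block Attention Module (CBAM)** at any subset of six
positions. The package is built around a placement question: *where* in a
small CNN does channel + spatial attention help a spectrogram-based heart
sound classifier, and where does it hurt?

It is aimed at researchers in biomedical signal processing who want a fully
reproducible, dependency-light pipeline: every stage — synthetic data,
segmentation, spectrograms, the network, training, evaluation, t-SNE
separability — runs offline on one CPU.

## The method

1. **Segmentation.** Each mono 2 kHz recording is cut into fixed,
   non-overlapping 5-second windows; recordings shorter than one window and
   incomplete trailing windows are excluded (logged, not errors).
2. **Spectrograms.** Each window becomes a grayscale log-power STFT image
   (Hann window 256, hop 64, 512-point FFT), bilinearly resized to a fixed
   height × width (504 × 864 by default) and min–max normalized to [0, 1].
3. **Backbone CNN.** Three stages of two 3×3 conv blocks (32/32, 64/64,
   128/128 filters, ReLU, "same" padding), 2×2 max pooling + dropout 0.2
   per stage, then FC(500) + ReLU + dropout 0.3 and a softmax over
   {normal, abnormal}.
4. **CBAM.** For a feature map `F` (H×W×C), channel attention computes
   `Mc = σ(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared bottleneck MLP
   (reduction ratio r = 16), and spatial attention computes
   `Ms = σ(conv7×7([mean_C(F'); max_C(F')]))` on the channel-refined map
   `F' = Mc ⊗ F`; the refined output is `F'' = Ms ⊗ F'`. A 6-bit mask
   selects which conv blocks get a CBAM, giving 12 canonical placement
   models (model 1 = none, model 7 = blocks 1-1/1-2/2-1, model 12 = all).
5. **Training.** Adam (lr 0.001), batch size 10, categorical cross-entropy,
   `ReduceLROnPlateau`-style decay (factor 0.5, patience 5, floor 1e-7) and
   early stopping (patience 15) on validation loss, best-epoch weights
   restored. Splits are stratified and, by default, grouped by recording so
   no recording leaks across folds.
6. **Evaluation.** Confusion-matrix metrics with abnormal as the positive
   class (accuracy, precision, sensitivity/recall, F1), Mann–Whitney AUC,
   and t-SNE class-separability statistics (per-class mean distance to the
   class centroid and the distance between the two class centroids).

The CNN, its backprop, Adam, CBAM and exact t-SNE are implemented in the
package (convolution/pooling kernels in C++ via Rcpp/RcppArmadillo); the
correctness of every piece is pinned by scalar-loop oracles and
finite-difference gradient checks in the test suite.

A seeded synthetic PCG generator stands in for clinical data: periodic
Gaussian-enveloped S1/S2 tone bursts (S2 at 55 % of the cardiac cycle), an
optional band-limited systolic "murmur" for the abnormal class with a
configurable SNR, and a white noise floor.

## Worked example

```r
library(pcgcbam)

cond <- desk_scale_conditions(seed = 42)
ds <- synthetic_spectrogram_dataset(cond$synth_cfg, cond$spec_cfg)
length(ds$x)        # 119 spectrograms from 33 recordings
sum(ds$y)           # 23 abnormal

out <- run_ablation(ds, model_ids = c(1, 7, 12),
                    train_cfg = cond$train_cfg, k = cond$k)
print(out$report[, c("model", "accuracy", "auc", "f1",
                     "inter_class_center_distance")], row.names = FALSE)
```

```
 model accuracy auc f1 inter_class_center_distance
     1        1   1  1                    96.48952
     7        1   1  1                    72.12578
    12        1   1  1                   120.53784
```

Read: at a +15 dB murmur SNR the synthetic classes are cleanly separable,
and all three placements — no CBAM, early/mid CBAM, all-CBAM — solve the
desk-scale task perfectly within 15 epochs; the inter-class centroid
distances confirm well-separated feature clusters in every case. What the
run demonstrates is the apparatus: three models trained under *identical*
folds, seeds and hyperparameters with only the CBAM mask varying, each row
carrying the full metric and separability panel. Ranking the placements
the way the full-scale study does requires the real, noisy corpus — on
clean synthetic data the ablation is a pipeline check, not a scientific
result.

Individual stages are exposed too (`generate_dataset()`,
`segment_recording()`, `compute_spectrogram()`, `channel_attention()`,
`apply_cbam()`, `train()`, `roc_auc()`, `tsne_embed()`,
`class_distances()`, …), and `inst/cli/pcgcbam` offers a thin command-line
front end (`synth`, `segment`, `spectrogram`, `build`, `train`, `evaluate`,
`ablation`, `holdout`, `separability`).

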