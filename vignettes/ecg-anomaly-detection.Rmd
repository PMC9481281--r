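---
title: "One-class ECG anomaly detection with an adversarial autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class ECG anomaly detection with an adversarial autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgaae)
```

## The problem

Clinical ECG streams are dominated by normal sinus beats; the abnormal beats
a monitor must flag (atrial premature, bundle branch block, ventricular
premature, and rarer types) are scarce, heterogeneous, and expensive to
label. Supervised beat classifiers therefore struggle: they need examples of
every abnormality they should recognise. `ecgaae` takes the one-class
(outlier-detection) route instead: learn what a *normal* beat looks like
from normal beats only, and flag anything the model cannot explain.

## The detector

Three parts cooperate:

1. **Autoencoder.** An encoder compresses a normalized 250-sample beat
   `x` into an 8-dimensional latent code `z = enc(x)`; a decoder maps the
   code back to a beat `x' = dec(z)`. Both are built from temporal
   convolutional network (TCN) residual blocks. Trained on normal beats
   only, the autoencoder learns to reconstruct normal morphology;
   abnormal morphologies, never seen in training, reconstruct poorly.
2. **Discriminator.** A TCN classifier `D(x)` is trained to tell real beats
   from reconstructions, while the autoencoder is additionally rewarded for
   fooling it (a two-player minimax game). The adversarial pressure pushes
   reconstructions toward the manifold of realistic normal beats instead of
   blurry averages.
3. **Outlier detector.** Each beat receives a reconstruction score
   `R(x) = mean((x - x')^2)` and a discrimination score `D(x)`, combined as

   `a(x) = (1 - lambda) * R(x) + lambda / D(x)`,

   with `D` floored at 1e-7. The threshold is fitted on the training set's
   own scores as `T = mean + 1 * sd` (sample standard deviation), and a test
   beat is called abnormal iff `a(x) > T` (strictly; ties are normal).
   `lambda = 0` is the default operating point, making the detector a pure
   reconstruction-error test; the discriminator then acts only as a training
   regulariser. We read the mixing rule's discriminator term as the
   *reciprocal* `lambda * (1 / D(x))`: the discriminator assigns low
   probability to unrealistic beats, so small `D` must raise, not lower,
   the anomaly evidence.

## Architecture

All three subnetworks share the TCN vocabulary: a residual block is two
dilated causal convolutions (kernel size 9, both sharing one dilation),
each followed by weight normalization, ReLU and dropout, with an identity
skip (or a kernel-1 projection when channel counts change) and a final ReLU.
Causality means output `t` sees only inputs at times `<= t`, implemented by
left zero padding of `(k-1)*d` samples. Dilations 1, 2, 4 across the three
blocks give a receptive field of `1 + sum(2*(k-1)*d) = 113` samples
(`receptive_field(9, c(1, 2, 4))`), about 0.3 s at 360 Hz — enough to span
a QRS complex and its neighbourhood from any position in the beat.

Layer layout (time x channels):

* encoder: 250x1 → TCN 250x32 → pool 50x32 → TCN 50x16 → pool 10x16 →
  TCN 10x8 → pool 2x8 → flatten 16 → dense 8 (ReLU)
* decoder: 8 → dense 16 (ReLU) → reshape 2x8 → [upsample x5 → TCN] x 3
  (channels 8, 16, 32) → causal conv k9 → 250x1, tanh
* discriminator: the encoder stack, then dense 8 (ReLU) → dense 1 (sigmoid)

Two layout choices deserve a note, both resolved in favour of dimensional
consistency:

* Nearest-neighbour upsampling repeats time steps and cannot change channel
  counts, so each decoder TCN block performs the channel change (8→8, 8→16,
  16→32) and the upsampling layers touch only the time axis. Every time
  length above is preserved, as is the 250x1 output contract; only the
  channel count *between* the second upsample and second decoder block
  (50x8 rather than 50x16) differs from a literal reading of the design
  table.
* The decoder's final activation is `tanh`, not ReLU: inputs are normalized
  to [-1, 1], and a ReLU output could never reconstruct the negative half
  of the range. `model_spec(output_activation = "relu")` restores the
  literal variant.

"Normalization" inside the residual block is weight normalization on the
convolution kernels (`W = g * V / ||V||` per output channel): deterministic,
batch-size independent, and standard for TCNs. Dropout defaults to 0.05 and
is active only during training; every inference map is deterministic.

The forward and backward passes are implemented in the package itself on
top of BLAS matrix products (an im2col formulation with memoized shift
indices). Gradients of every layer were verified against central finite
differences during development, and the convolution is tested against a
literal triple-loop oracle in the suite.

## Training

Adam with learning rates 1e-3 (autoencoder) and 2e-4 (discriminator),
moments (0.5, 0.999), batch size 64. Per batch, the discriminator first
descends `-log D(x) - log(1 - D(x'))` with the reconstruction `x'` treated
as a constant (real beats and reconstructions run as one stacked batch);
then the encoder and decoder descend `MSE + gamma * (-log D(x'))`, the
non-saturating generator form, with the freshly updated discriminator run
dropout-free as a fixed critic. `gamma` (default 0.05) keeps reconstruction
dominant; `gamma = 0` disables the discriminator entirely and yields the
plain-autoencoder ablation. The training contract refuses input carrying
any non-`N` label.

History rows record the *end-of-epoch* losses on the full training set with
dropout off (adversarial terms on the first 512 beats, to keep the
accounting pass cheap), so the reconstruction entry is exactly recomputable
from the returned weights. Early stopping watches that reconstruction loss
with patience 10 by default.

## The synthetic generator

No public beat-level generator accompanies the datasets this method is
usually evaluated on, so the package ships a parametric surrogate: each
beat is a sum of Gaussian waves (P, Q, R, S, T) on the 250-sample, 360 Hz
grid, with the R peak anchored at position 101. Class caricatures:

* `N` — P-R interval ~0.16 s, QRS ~0.08 s, upright T;
* `A` — P wave advanced 40 ms at half amplitude;
* `L` — broad QRS with a second merged R lobe (notch), discordant T;
* `R` — deep S plus a late R' deflection;
* `V` — no P wave, double-width QRS, inverted T.

Per-beat jitter (5% amplitudes, 4% widths, 2 ms wave centers) plus white
noise (sd 0.03) and, for records, single-tone baseline wander (0.1 a.u. at
0.3 Hz) emulate measurement conditions; one integer seed drives all
randomness. Records place beats at fixed RR intervals at any sampling rate,
so the 560 Hz → 360 Hz resampling path is exercised end to end.

What the surrogate does *not* emulate: rhythm-level arrhythmia (irregular
RR, atrial fibrillation), multi-lead geometry, electrode artefacts,
inter-patient morphology drift, or clinically validated waveshapes. Tests
passing on this generator demonstrate that the pipeline and model behave as
specified — not that the detector reaches any particular performance on
hospital data.

## Preprocessing numerics

* **Resampling** is windowed-sinc interpolation (Kaiser window, beta 12,
  half-width 40 input samples, cutoff at 90% of the narrower Nyquist band,
  weights renormalized to unit DC gain) over an odd-reflection padding that
  continues the signal through each endpoint with matching value and slope.
  A 5 Hz sine resampled 560 → 360 Hz stays within ~1e-5 of the analytic
  curve. R-peak annotations are rescaled and re-snapped to the local
  absolute maximum within 3 samples so the segmentation anchor survives.
* **Denoising** is a periodized multilevel DWT (Daubechies-6) implemented
  in the package: detail coefficients are soft-thresholded with the
  universal threshold `sigma * sqrt(2 log n)` (`sigma` = robust MAD
  estimate from the finest level), and the deepest approximation band is
  zeroed to remove baseline wander and DC. The default depth is 8 levels:
  at 360 Hz the level-8 approximation covers 0–0.70 Hz, so typical baseline
  tones (~0.3 Hz) fall safely inside the zeroed band. A 9-level split was
  considered and rejected: its 0.35 Hz band edge sits on top of ordinary
  baseline frequencies, and a 0.3 Hz tone then leaks into the surviving
  level-9 details, defeating the removal. Both depth and filter are
  arguments.
* **Segmentation** takes samples `(r-100)..(r+149)` around each annotated
  peak (1-based; 100 before, the peak, 149 after — 250 samples). Peaks too
  close to a record edge are skipped and counted, never padded.
* **Normalization** is per-beat min-max to [-1, 1]; a constant beat maps to
  zeros rather than erroring so one flat lead cannot abort a batch. The
  per-beat (rather than per-record) choice matches a model whose input unit
  is the single beat.

## The scaled study

The packaged experiment (`run_experiment()`, also `scripts/acceptance.R`)
runs the one-class protocol at desk scale: 2,000 normal synthetic training
beats and a 500 normal + 500 abnormal test set — one fifth of the
full-scale 10,000 / 5,000 + 5,000 split the workflow is designed around —
with 8 training epochs at batch 64. These sizes are the package's own
choice of problem scale; the acceptance suite requires the resulting
detector to reach AUC ≥ 0.90 with mean R(abnormal) > mean R(normal) across
three seeds — a qualitative separation requirement rather than a fixed
headline number, since absolute metrics depend on the data source.

## Known limitations

* Scores are per-beat; the multi-beat clinical decision rule (flag only
  runs of consecutive abnormal calls) is out of scope.
* The threshold assumes the training scores are roughly unimodal;
  mean + 1 sd puts ~16% of a Gaussian above it, so the operating point
  trades recall for precision and can be conservative on heavy-tailed
  score distributions.
* `lambda > 0` is exposed but untuned; the discriminator's probability
  scale is not calibrated.
* Training is CPU-bound; the default scale trains in minutes, but
  full-scale runs (10,000 beats, 100 epochs) are better scheduled than
  interactive.
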