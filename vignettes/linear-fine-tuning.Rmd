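---
title: "Linear fine-tuning for undersampled MRI reconstruction: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear fine-tuning for undersampled MRI reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lftmri)
```

## The problem

Accelerated MRI acquires only a fraction of the phase-encode rows of
k-space; the zero-filled (ZF) inverse FFT of such data is aliased, and a
convolutional network can be trained to map ZF images to artifact-free
reconstructions. These networks generalize poorly across imaging domains:
a model trained on one contrast, slice orientation, or anatomy degrades on
another. Full fine-tuning (FT) — re-training every weight on a small
target-domain set — risks catastrophic forgetting of the pre-trained
knowledge and overfitting when target data are scarce.

## The model

A convolution layer applies $N$ filters to an $M$-channel input $U$; filter
$n$ holds kernels $W_{(n,m)}$ and a bias $b_n$. Its feature map decomposes
into per-kernel *basic features* summed into per-filter *advanced features*:

$$V_a^{(n)} = \sum_{m=1}^{M} \left( U_{(m)} \circledast W_{(n,m)} \right) + b_n .$$

Linear fine-tuning (LFT) assumes that for related imaging domains the
advanced features of the target domain are *different linear combinations
of the same basic features*. It therefore attaches one scaling factor
$\Phi_{S_W}(n,m)$ and one shifting factor $\Phi_{S_b}(n,m)$ to every kernel:

$$V_a^{(n)} = \sum_{m=1}^{M} \left( U_{(m)} \circledast
  \bigl(\Phi_{S_W}(n,m) \cdot W_{(n,m)}\bigr) \right) + b_n +
  \sum_{m=1}^{M} \Phi_{S_b}(n,m),$$

initialized at the identity ($\Phi_{S_W} \equiv 1$, $\Phi_{S_b} \equiv 0$) so
the adapted model starts exactly at the pre-trained model. In the transfer
phase only the factors train; $W$ and $b$ stay frozen, which removes
forgetting by construction and shrinks the trainable-parameter count from
$\sum_n N(Mk^2+1)$ to $\sum 2NM$. Because the scaling acts uniformly on a
kernel, the factors *fold* into the weights
($W' = \Phi_{S_W} W$, $b' = b + \sum_m \Phi_{S_b}$), so a trained model
deploys as a plain network with zero overhead — `fold_ss()` /
`fold_network()` implement this and the test suite asserts the equivalence
to $10^{-5}$ (in practice it holds to double precision).

Row fine-tuning (RFT) is the intermediate granularity: one scale per kernel
*row* ($\sum NM(k_h{+}1)$ parameters). The source only defines the row
scales for RFT; we include a per-kernel shift by default so RFT strictly
interpolates between LFT and FT, and `include_shift = FALSE` disables it.

Two representation choices deserve note. First, the per-kernel bias of the
decomposition is stored in aggregate as one bias per filter (the
conventional layer shape); `advanced_features()` distributes it equally
across kernels so the decomposition still sums exactly to the filter
output. Second, "convolution" is the deep-learning convention:
cross-correlation, stride 1, zero "same" padding, odd kernels only
(even-sized kernels are rejected rather than padded asymmetrically).

## Forward model

`to_kspace()` is the centered orthonormal 2D DFT (DC at
`(floor(h/2)+1, floor(w/2)+1)`, energy-preserving), axis 1 is the
phase-encode direction. Masks select exactly `round(rate * height)` rows: a
contiguous center band of `round(center_fraction * height)` rows is always
acquired, and the remainder are drawn without replacement with probability
proportional to a Gaussian centered on DC. The Gaussian width and the
center-band size are not standardized; the defaults
(`sigma_fraction = 1/6`, `center_fraction = 0.08`) follow common
variable-density practice and are configurable — they are documented
defaults, not inferred values. When the Gaussian weights of the remaining
rows underflow to zero the sampler falls back to uniform selection.
Images are normalized to $[0,1]$ before the forward model; k-space stays
complex throughout, and the network input is the complex ZF image as two
real channels.

## The reconstruction generator

The generator is a compact residual U-net built only from basic units:
stride-1 convolution banks, leaky-ReLU ($\alpha = 0.2$), 2×2 average-pool
downsampling, nearest-neighbor upsampling, skip concatenations, and a
global residual skip. We use pooling rather than a strided convolution for
downsampling so that *every* learnable layer is a plain stride-1 bank the
factor blocks can wrap uniformly; the final convolution is
zero-initialized, making the untrained network the identity map (its output
is the ZF input). Two U-nets can be chained (`chain_length = 2`) to mimic a
refinement cascade. A discriminator/adversarial term is deliberately out of
the default path: the transfer strategies are architecture-agnostic and the
comparisons only require a common generator.

## Training protocol

All strategies share one protocol: Adam (constant learning rate), loss on
the reconstruction magnitude, validation PSNR after every epoch, early
stopping once the validation PSNR has not *strictly* improved within
`patience = 15` epochs (ties do not reset the window), and the
highest-validation-PSNR checkpoint returned. Datasets split
train:validation:test = 16:5:4 by largest-remainder rounding after a seeded
shuffle; training-set-size sweeps subset the training split only.

Defaults and why:

* **Learning rate** — 1e-4 for pre-training (and for DT/LFT/RFT); 1e-5 for
  FT. The transfer-phase rate is lowered for FT because all weights move;
  the factor-based strategies train orders of magnitude fewer parameters
  and keep the pre-training rate. These transfer rates are package
  defaults, configurable per run.
* **Loss** — squared error (L2) on magnitude by default. Model selection
  and evaluation are PSNR-based, and PSNR is a monotone transform of MSE,
  so the default objective matches the selection criterion; L1 is available
  via `strategy_config(loss = "l1")`.
* **Masks** — one mask per sampling rate, fixed across a run, so every
  model in a comparison cell sees the identical measurement operator.
* **Determinism** — every source of randomness (initialization, shuffling,
  mask and phantom sampling) derives from explicit seeds; two runs with the
  same configuration are bitwise identical on CPU, and the trainer restores
  the caller's RNG state.

Epoch 0 (the untrained/identity state) is recorded as
`initial_val_psnr` rather than as a history row; the best checkpoint is
chosen among trained epochs, which keeps the stopping rule's epoch
arithmetic simple and matches the convention that pre-training "saves the
network with the highest PSNR".

## What the phantom generator emulates — and what it does not

Real MR data cannot ship with the package, so the study conditions are
emulated with ellipse-composite phantoms: a geometry *template* (sagittal
brain, axial brain, knee-like layered stripes), a *contrast map* from five
tissue labels to intensities, independent per-structure geometry jitter
(default 0.1 of the field of view — subject-level anatomical variability,
not a rigid whole-slice perturbation), 1–3 random lesion ellipses, and a
smooth multiplicative bias field (amplitude 0.08) that breaks piecewise
constancy. The three preset domain shifts mirror the transfer scenarios:

* **contrast** — identical geometry, T1-like vs T2-like maps. The T2-like
  map inverts the ordering of the two matter classes and brightens
  fluid/lesions while fat stays bright, a deliberately *moderate* shift, as
  between real T1- and T2-weighted images of the same anatomy.
* **direction** — sagittal vs axial brain templates (partial geometric
  overlap).
* **anatomy** — brain vs knee templates (the largest structural distance).

Label-map Dice between matched slices orders the shifts
contrast (= 1) > direction > anatomy, emulating the small-to-large
distribution deviations of the three scenarios.

What passing tests on these phantoms shows: the freezing contracts, the
fold equivalence, the identity initialization, the forward model, and the
qualitative transfer ordering (pre-trained knowledge helps; LFT adapts
without forgetting; training from scratch is data-limited). What they do
not show: performance on real MR magnitude statistics, noise, coil
profiles, or pathology — the phantoms have none of these, and absolute
PSNR/SSIM values here do not transfer to real data.

## Study conditions at desk scale

The packaged experiments run on one CPU in minutes, with sizes chosen once
for that purpose: 64×64 slices (any multiple of $2^{\text{depth}}$ works;
256×256 is configuration-reachable), a depth-2, 8-channel generator
(≈15k weights; LFT trains 1.3k factors), 80 source slices vs 32 target
slices (the source domain must dwarf the target training set — the premise
of transfer learning), 20 target training images in the headline cell,
sampling rate 0.3, an epoch budget of 60 with patience 15 (at these sizes
the validation PSNR typically still improves when the budget ends, so the
budget — applied identically to every strategy — is the effective stopping
rule), and seeds 0–2 for the replicated ordering check. An early calibration with near-rigid,
four-structure phantoms made 20 target images effectively "ample" (direct
training matched transfer), i.e. it failed to reproduce the data-limited
regime the comparison is about; the richer templates and per-structure
jitter above were adopted for that reason and then frozen.

## Numerical choices

* Double precision throughout; the documented tolerances (1e-6 for
  identity insertion, 1e-5 for fold equivalence) are float32-style bounds
  and hold with orders of magnitude to spare.
* Magnitude gradients use $\sqrt{y_1^2+y_2^2+10^{-16}}$ to avoid the
  singularity at zero.
* PSNR of an exact reconstruction is reported as an `Inf` sentinel and
  excluded (with a count) from mean ± sd aggregation, which uses the
  sample (n−1) standard deviation.
* SSIM follows the standard 11×11 Gaussian window (σ = 1.5,
  k₁ = 0.01, k₂ = 0.03), Gaussian-weighted moments, valid-region mean; it
  matches scikit-image's implementation to ~1e-10 on the packaged check.
* WPSNR: the precise weighting of the published variant is not available,
  so the default weight map is a documented, non-authoritative
  contrast-sensitivity-style high-frequency attenuation
  ($w = 1/(1 + \text{hf}/\overline{\text{hf}})$, normalized to mean 1);
  uniform weights reproduce PSNR exactly and user maps are supported.
* Checkpoints and banks serialize to JSON containers mirroring an
  HDF5-style group layout (`weights`, `bias`, `ss/scale`, `ss/shift`,
  `layout = "NMHW"`).

## Known limitations

Single-coil, Cartesian 1D masks only; no k-space noise model; no
adversarial or perceptual losses in the default path; the generator is a
stand-in, far smaller than production reconstruction GANs; phantom realism
as discussed above. The feature-map extraction (`extract_feature_maps()`)
and the forgetting diagnostic (`compare_forgetting()`) are inspection
tools around the training protocol, not quantities with external reference
values.
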