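---
title: "Adversarial synthesis of thyroid strain elastograms: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial synthesis of thyroid strain elastograms: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tsegan)
```

## The problem

Strain elastography (SE) overlays a B-mode ultrasound image with a color map
of tissue stiffness: green for elastic tissue, blue for stiff (sclerotic)
tissue, with occasional red/yellow artifact spots. Clinicians grade thyroid
nodules on the 1–5 Rago scale from the blue/green composition inside the
nodule — a uniformly green nodule scores 1 (likely benign), a uniformly blue
one scores 5 (likely malignant). Acquiring SE requires a manual compression
protocol that is hard to standardize. This package implements a conditional
generative adversarial network that synthesizes the SE color map directly
from the grayscale B-mode image, so the stiffness reading can be
approximated without the compression step.

## Model

The translator is a three-part generator judged by two conditional PatchGAN
discriminators.

**Local generator.** A 128×128 region of interest (ROI) around the nodule
(half the 256×256 frame) is encoded by deformable-convolution residual
blocks: each convolution tap is displaced by a learned per-position 2-D
offset and sampled bilinearly. Soft tissue deforms anisotropically under
compression, and deformable kernels let the receptive field follow that
deformation instead of staying on a rigid grid. The first layer uses a 7×7
kernel (coarse nodule extent), later layers 3×3 (contour detail). Offset
predictors are zero-initialized, so every deformable convolution starts as
an exact plain convolution and learns its deformation from there. The
bottleneck is nine residual blocks; the decoder upsamples with transposed
convolutions refined by SPADE residual blocks (below). The pre-output
decoder features are exposed for fusion with the global branch.

**Global generator.** The full 256×256 frame passes a convolutional encoder
whose first stage carries a spatial attention module (channel-wise mean and
max maps → 7×7 convolution → sigmoid mask) that re-weights the nodule
region. At the bottleneck, the local branch's decoder features are
projected 1×1, average-pooled onto the ROI's footprint at bottleneck
resolution, embedded at the ROI's window position, and summed element-wise
with the global features — preserving the spatial registration of the two
branches. Nine residual blocks fuse the result before the SPADE decoder.

**SPADE blocks.** Instance-style normalization erases spatially-varying
statistics and produces boundary artifacts in translation tasks. Each SPADE
block therefore standardizes its input per channel (parameter-free) and
re-modulates it as `(1 + γ) ⊙ x̂ + β`, where γ and β are *maps* predicted by
a two-layer convolution from the concatenated skip features and the resized
raw input image. Two SPADE blocks plus a shortcut form one decoder residual
block.

**Content revisor.** The decoder's full-resolution feature map `m` is split
into n = 4 groups: n−1 tanh "content masks" `C_f = tanh(conv_f(m))` carry
the foreground; the input image is the background. A channel-attention head
(3×3 convolution to n channels, global average and max pooling through a
shared fully-connected layer, softmax over the n groups) yields weights
`A_1..A_n` on the simplex, and the output is
`Σ_{i<n} C_i·A_i + x·A_n`. Because the composition is convex and every term
lies in [−1, 1], the output is bounded without a final activation, and the
background term preserves input content exactly when `A_n → 1`.

**Discriminators.** Two 70×70-receptive-field PatchGANs with identical
architecture and independent parameters judge (B-mode, elastogram) channel
concatenations — one at the 256 global scale, one at the 128 ROI scale.
They return raw logits (the sigmoid lives inside the numerically stable
loss) and their four stage-wise feature maps.

## Objective

All image losses are computed in CIELAB coordinates, affinely mapped to
[−1, 1] (L: [0,100], a and b: [−128,127]). Elastogram colors occupy a much
more concentrated region of Lab space than of RGB space (the package's
`channel_entropy()` diagnostic restates this on phantoms), so distances
there align better with perceived color error. Grayscale B-mode images
embed with zero chroma (a = b = 0).

* **Adversarial:** binary cross-entropy on patch logits; non-saturating
  generator form; discriminator loss is the mean of its real and fake
  terms, so all-zero logits give ln 2.
* **Feature matching:** `Σ_i ‖D^{(i)}(x,y) − D^{(i)}(x,G(x))‖₁ / N_i` over
  the discriminator stages, real features treated as constants.
* **Color:** both images are blurred with a normalized Gaussian kernel
  (k = 21, σ = 3 at 256² — large enough to suppress texture while keeping
  the color layout; reflect padding, kernel indices centered) and compared
  with the *sum* of squared plus absolute differences over all elements.
* **Total:** `Σ_k L_GAN + α Σ_k L_FM + β L_color` with α = 10, β = 0.001.
  The color term is applied to the global output; the ROI branch receives
  its pixel-level signal through the ROI discriminator's feature matching.

Training uses Adam (β₁ = 0.5, β₂ = 0.999) with two time-scale updates:
generator 2·10⁻⁴, discriminators 1·10⁻⁴; Xavier initialization; paired
augmentation (flips, translations within ±20 px, including a diagonal
equal-shift variant, rotations within ±15°, each applied with probability
0.5 with one shared draw for the image pair and mask) followed by resize
and random crop. Each iteration computes all losses from one generator
forward pass, then steps the discriminators on the detached fake and the
generator on the full objective — the standard conditional-GAN schedule.

## Synthetic phantoms

The package is verified on seeded synthetic phantoms rather than clinical
data. Each phantom pairs:

* a **B-mode proxy**: a smoothed background texture (mean 0.55) under
  multiplicative Rayleigh-like speckle (σ = 2 px smoothing), with an
  elliptical hypoechoic nodule whose luminance drop grows with the
  stiffness score (0.12 + 0.045·s, i.e. 0.165–0.345). Stiffer nodules are
  drawn darker — consistent with the hypoechogenicity of suspicious
  nodules — and this is what makes the stiffness score recoverable from
  the grayscale input at all;
* an **elastogram**: green-dominant background, a central blue core
  covering a designed fraction of the nodule area per score
  (score 1: ≤ 5%, 2: 15–35%, 3: 40–60%, 4: 65–85%, 5: ≥ 95%), sparse
  red/yellow spots outside the nodule, and luminance modulated by the
  smoothed B-mode so the modalities co-register. The core is realized by
  rank-selecting exactly ⌊f·area⌋ innermost pixels (by angularly-wobbled
  elliptical radius), which pins the realized fraction inside the design
  band at any nodule size and keeps the blue centroid within 2 px of the
  nodule centroid.

`blue_green_ratio()` (the fraction of mask pixels whose blue channel
strictly exceeds red and green) is the programmatic stand-in for human
Rago scoring; fixed thresholds aligned with the design bands map it back
to a proxy score. What the phantoms do *not* emulate: acoustic wave
physics, shadowing, anisotropic speckle, probe pressure variation, real
nodule morphology. Passing the phantom suite shows the pipeline is
implemented coherently — not that it meets clinical image quality.

## Desk-scale study conditions

CPU-scale testing uses a fixed profile: 32 training phantoms and 50
held-out phantoms (10 per score) at 64×64 (nodule radii 6–14 px), base
width 8, ROI 32, 200 iterations, seed 42. The batch size is 4 — half the
full-scale batch of 8 — to bound the step cost on one CPU while keeping
gradient averaging close to the reference schedule; all learning rates,
Adam settings and loss weights are exactly the full-scale values. A
variant that rescaled the color weight β by the crop-area ratio (on the
argument that the color loss sums over elements, so β implicitly carries
the 256² crop area) was evaluated and rejected: the inflated color term
overwhelms the adversarial and feature-matching signals at desk scale and
degrades every measured outcome.

Under these conditions the 200-iteration run takes a few minutes on one
CPU; the test suite checks that the median total generator loss falls, the
trained checkpoint beats the untrained initialization on PSNR, stiffness
ordering is recovered on held-out phantoms (Spearman of score against
generated blue/green ratio), and the loss log reproduces bit-identically
under the seed (the determinism check replays the first 40 iterations —
training is strictly sequential, so a bit-identical prefix establishes the
property).

## Numerical choices and edge cases

* Transposed convolutions are exact fractionally-strided convolutions
  (zero-dilation then a 4×4 stride-1 convolution), checked against finite
  differences like every other operation.
* Batch normalization statistics are computed over the spatial extent of
  each sample (the decoders use SPADE's parameter-free standardization
  instead); ε = 10⁻⁵ guards degenerate variances, so zero-weight residual
  branches are exact identities.
* PSNR of identical 8-bit images is reported at a 100 dB sentinel.
  SSIM ships in two modes: the whole-image-moment form of the printed
  formula (`"global"`) and the community-standard 11×11 Gaussian-window
  average (`"windowed"`, the default). MSE averages over channels as well
  as pixels so `psnr = 10·log10(255²/mse)` closes exactly.
* Metrics are computed on 8-bit sRGB renderings (the clinically displayed
  form), not on Lab tensors.
* Lab conversion uses D65/2° constants; out-of-gamut inversions clip to
  [0, 1] with a reported count. The sRGB round trip on a 6³ grid stays
  below 1/255.
* The channel attention of the content revisor softmaxes globally pooled
  per-channel scalars (pooling + fully-connected structure); the
  alternative reading — a per-pixel softmax across groups — would make the
  masks spatial but is not what the pooling head implies.
* ROI windows are clamped (never padded) at image borders, so crops always
  contain real pixels; an empty mask falls back to the image center with a
  warning.
* `naive_segment()` thresholds at the midpoint of the 2nd and 60th
  intensity percentiles rather than Otsu: with a nodule occupying a few
  percent of the frame the Otsu split degenerates into the background
  distribution. It is a coarse fallback for mask-free inference only.

## Known limitations

* No clinical data ships with the package; all quantitative statements are
  about phantoms.
* The desk profile's 200 iterations demonstrate learning dynamics, not
  convergence; full-scale training (1,500 epochs at 256², batch 8) is a
  GPU-class computation.
* Single-image (H×W×C) processing throughout; batching is a loop, and
  normalization statistics are per-sample by construction.
* The offset fields, attention maps and content masks are exposed in
  `run_generator()` diagnostics but no visualization helpers are provided.
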