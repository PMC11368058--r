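---
title: "Pseudo-healthy synthesis by lesion inpainting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-healthy synthesis by lesion inpainting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudohealthy)
```

## The problem

A pseudo-healthy image is a synthetic lesion-free counterpart of a
pathological scan that (i) looks healthy and (ii) still belongs,
anatomically, to the same subject. Both properties matter: a healthy-looking
image from the wrong anatomy is clinically useless, and an image that
preserves anatomy but still shows the lesion has not been healed. The
package treats the problem as *inpainting*: rather than translating the
whole image into a healthy-looking one (and risking identity loss
everywhere), it localizes the lesion, deletes it together with a small
safety margin, and reconstructs only that region from the surrounding
healthy context. Everything outside the replaced region is preserved
bit-exactly by construction.

## The three stages

**Stage 1 — localization.** A pluggable segmentor produces a binary lesion
mask (1 = pathological). The default is a standard U-Net (encoder-decoder
with skip connections, pixel-wise binary cross-entropy, decision threshold
0.5); manual pixel-level annotations can be loaded instead. The mask is
dilated by a Euclidean disk of 5 mm (`prepareInferenceMask()`), because
pathology (for example peritumoral edema or the rim of an abscess) commonly
extends a little beyond the visible lesion; the dilated mask is what the
later stages replace.

**Stage 2 — coarse filling.** The *vague filler* V receives the masked
image and the mask as two channels — the original's masked pixels are
pre-multiplied away, so the network can never read them — and outputs a
full-resolution slice through a tanh. Its only learnable mechanism is the
gated convolution, `ELU(conv_f(x)) * sigmoid(conv_g(x))`: the learned gate
lets the network treat valid and missing pixels differently under
free-form masks. The body is a straight-line chain of residual dilated
gated-conv blocks at quarter resolution (dilations 1, 2, 4, 8, 4, 2 by
default) with no skip connections, so the fill is driven by context
semantics rather than copied detail. V is trained with the L1 loss alone
and therefore produces a *blurry but anatomically plausible* healthy
outline — exactly what is wanted: contours first, texture later.

**Stage 3 — refinement.** The generator G sharpens the coarse fill. It
exploits the approximate bilateral symmetry of the brain with a fully
symmetric dual-path encoder: the coarse fill and its horizontal flip pass
through the *same* convolution weights. At the deepest feature level the
Attention Calculation Module (ACM) computes, for every patch pair, the
cosine similarity

$$c_{i,j} = \left\langle \frac{b_i}{\|b_i\|}, \frac{b_j}{\|b_j\|} \right\rangle,$$

which is squared and normalized over the context (outside-mask) patches,

$$s_{i,j} = \frac{c_{i,j}^2}{\sum_{i'} c_{i',j}^2},$$

giving the forward-path (PIAS) and flipped-path (FIAS) score matrices.
Rows belonging to inside-mask patches are zeroed — masked content never
serves as context — so each score column is a convex weight vector over
the context patches. The Attention Transfer Module (ATM) fills each hole
patch with the score-weighted combination of context patches,
$b_j = \sum_i s_{i,j} b_i$. The four streams (forward features, re-flipped
flipped-path features, and the two attention-filled maps) are concatenated
channel-wise and decoded by two interpolation + convolution stages.

Finally, *contextual residual aggregation* transplants real high-frequency
texture: the full-resolution residual $R = x - \mathrm{up}(\mathrm{down}(x))$
of the coarse fill is tiled by the same patch grid and the hole's residual
patches are rebuilt with the PIAS scores, $R_j = \sum_i s_{i,j} R_i$
(residuals live in the unflipped frame, hence PIAS). The refined output
inside the mask is the coarse fill plus the decoder's learned correction
plus the aggregated residual, clamped to $[-1, 1]$; outside the mask the
input is passed through unchanged, and the pipeline's final composite
restores the original pathological image outside the dilated mask
bit-exactly.

At the default attention resolution of 256 × 256 with 16 × 16 patches the
patch grid has exactly 256 cells and the affinity matrix is 256 × 256.

## Training objectives

Training uses healthy slices only. Each step masks 30–60 % of the slice's
foreground with a fresh random free-form mask (strokes and disks, clipped
to the foreground), emulating segmentor detections. Intensities are
normalized linearly to $[-1, 1]$; mask value 1 marks the missing region.

* V minimizes the plain L1 loss against the original healthy slice.
* G trains adversarially against a spectral-normalized convolutional
  discriminator with hinge losses,
  $L_D = E[\max(0, 1 - D(h))] + E[\max(0, 1 + D(\hat h))]$ and
  $L_G = -E[D(\hat h)]$, plus a perceptual term
  $L_{perc} = \lambda\, E[\|\phi(h) - \phi(\hat h)\|_1]$ with
  $\lambda = 64$; the generator's total loss is $L_G + L_{perc}$.
  V is frozen during this phase.

All stages use Adam with an initial learning rate of 0.001 halved every 5
epochs, and size-dependent batches (16 up to 256 px, 4 at 512 px).

The feature extractor $\phi$ is pluggable. The default, `"random-fixed"`,
is a frozen, deterministically initialized three-stage conv net whose
first tap is the pre-activation (linear) response — a random linear
projection of local patches, whose L1 distance anchors signed low-level
intensity — with post-ReLU taps at the two deeper stages. Pretrained VGG16
weights can be supplied through the same interface when available; the
package itself has no download step and is fully self-contained.

## Evaluation suite

* **Healthiness** $H = 1 - E[N(f_p(\mathrm{output}))] / E[N(f_p(\mathrm{input}))]$,
  where $N$ counts pixels an evaluation segmentor $f_p$ flags as
  pathological. The denominator uses $f_p$'s prediction on the inputs, not
  the ground-truth masks, so segmentor bias cancels; the ratio is a ratio
  of means, matching the nested expectations.
* **Identity preservation**: masked PSNR and masked SSIM between output
  and input with the lesion mask excluded — PSNR over the mask complement
  on the $[0,1]$ scale (cap 99 dB for exact agreement), and single-scale
  SSIM (11 × 11 Gaussian window, $\sigma = 1.5$, standard stabilizers) on
  images with the masked region zeroed on both sides. Because the pipeline
  composites its output, both metrics attain their caps by construction —
  a hard regression guarantee, not an empirical outcome.
* **Structure healthiness** SH: the mean probability, under a binary
  classifier on Canny edge maps, that outputs synthesized from
  *large-lesion* inputs (lesion strictly above 20 % of the brain area) are
  free of deformations.

Canny is implemented in-package (no installed R package provides it):
Gaussian smoothing ($\sigma = 1$), Sobel gradients, non-maximum
suppression, and hysteresis with thresholds at the 0.10/0.30 quantiles of
the positive suppressed gradient magnitudes — quantile thresholds make the
detector robust to the intensity scale. Hysteresis uses 8-connected
propagation: 4-connected labelling fragments diagonal edge rings.

The SSIM implementation follows the literal masked form of the identity
metric as *single-scale* SSIM; the multi-scale variant named in some
descriptions of the metric is not used — the masked equation form is taken
as authoritative.

## The synthetic phantom study

The package ships a first-class phantom generator so that every stage is
trainable and testable without clinical data. A phantom is a bilaterally
symmetric elliptical "brain" on a $-1$ background with a radial tissue
gradient, two dark ventricle-like shapes near the midline, and mirrored
pairs of internal structures; smooth noise (coarse Gaussian field,
bilinearly upsampled, sd 0.03 by default) is added inside the foreground.
With zero noise a phantom equals its horizontal flip exactly. Lesions are
intensity anomalies on a disk with an optional *mass effect*: a radially
decaying outward displacement with compact support (nothing beyond
`radius + amplitude` moves), emulating the compression of adjacent
structures by edema. Ground truth is the lesion disk.

The phantom study conditions used by the tests and the acceptance script
are fixed: 200 training phantoms and 50 held-out phantoms of 64 × 64 px,
three structure pairs, noise sd 0.03, lesion radii 10–20 % of the image
side, intensity shifts ±0.5–1.0, mass-effect amplitudes 1–3 px. Network
sizes are scaled to CPU training: U-Net depth 3 / width 8 (constructor
defaults stay at the canonical depth 4 / width 32), filler widths 8/16/16
(defaults 32/64/128), generator and discriminator width 8 (default 32),
attention patch 8 at this 64 px scale (default 16 at 256 px — at 64 px a
16 px patch grid would leave no context patches under 30–60 % masks).
Budgets: 200 coarse-filler steps, 500 adversarial refinement steps
(batch 4), ablation arms at equal 500-step budgets (batch 2) over a
shared 150-step coarse filler.

What the phantoms do *not* emulate: MR physics (bias fields, partial
volume, Rician noise), fine-grained cortical texture, true anatomical
variability, and multi-modal contrast. Passing the phantom study shows the
pipeline's mechanics — localization, masked filling, attention transfer,
identity preservation, metric arithmetic — work as specified; it does not
certify clinical-scale image quality, which in the source setting requires
GPU-scale adversarial training on thousands of slices.

## Numerical and design choices

* **Conv-net engine.** No deep-learning framework exists in this R stack,
  so the package includes a compact deterministic CPU engine: im2col +
  BLAS matmul convolutions (the gather/scatter inner loops in C++),
  analytically derived backward passes (verified against finite
  differences in the test suite), max pooling, nearest upsampling, Adam,
  and one-step power-iteration spectral normalization with $\sigma$ held
  constant in the backward pass.
* **Detached attention scores.** ACM scores are treated as constants
  during backpropagation; gradients flow through the ATM value path and
  the direct encoder streams. This keeps the hand-written backward pass
  tractable; the forward semantics are exact.
* **Decoder as correction.** With CRA enabled the decoder's output
  convolution is zero-initialized and its tanh output is *merged with the
  coarse fill* (the blurry image) together with the aggregated residual;
  the untrained generator is therefore the identity-plus-residual merge,
  and training learns a correction. The plain-GAN ablation is a pure
  encoder-decoder with unit-gain output, so the ablation ladder compares
  genuinely different architectures.
* **Residual blur factor.** $R = x - \mathrm{up}(\mathrm{down}(x))$ uses
  factor 2 by default: the coarse filler, which sees the full context,
  already reconstructs all coarser bands, so only the finest band is
  genuinely transplantable; a coarser cutoff injects redundant content
  into the hole. Block-average downsampling and block-centre-aligned
  bilinear upsampling are used so the residual operator is exactly
  flip-symmetric.
* **Patch labelling.** A patch is "inside" if *any* of its pixels is
  masked — conservative, so no lesion pixel ever serves as context.
  Degenerate cases are defined: zero-norm patches get an
  $\epsilon$-guarded norm ($10^{-8}$), an all-zero affinity column falls
  back to uniform weights over context patches, and a mask that covers
  every patch (or none) disables the attention fill for that sample
  rather than erroring inside training.
* **Flip equivariance.** `refine(flip(x), flip(m)) = flip(refine(x, m))`
  holds exactly only when every kernel is left-right symmetric
  (convolution does not otherwise commute with flips); the property test
  therefore runs on a kernel-symmetrized copy of the generator, which
  verifies the dual-path plumbing — shared weights, re-flips, attention
  index relabelling — end to end.
* **Zero-range normalization.** A constant slice normalizes to all $-1$
  (background), matching the skull-stripped darkest-is-background
  convention and avoiding a divide by zero.
* **Mask fraction reference.** The 30–60 % training-mask range is measured
  against the brain foreground, not the whole image: on skull-stripped
  slices image-relative fractions above roughly 40 % are unreachable.
* **Slice extraction.** Every-k extraction starts at index 0; the default
  keep-predicate requires more than 1 % above-background pixels. The
  large-lesion gate is strict: a lesion of exactly 20 % of the brain area
  is excluded.

### What refinement can and cannot add at desk scale

One empirical property of the phantom study deserves a direct statement.
The coarse filler is trained to minimize the masked-region L1 error — the
very quantity one would naturally use to compare the stages — whereas the
refinement stage trains on adversarial and perceptual objectives with no
pixel term. On these phantoms the coarse filler already reconstructs all
*spatially predictable* content (the smooth noise field is correlated
over several pixels, so it can be inpainted from context), leaving an
error that is mostly per-pixel unpredictable. Transplanted residuals then
improve squared-error measures (the transplant correlates about 0.5 with
the missing high-frequency content) but not mean-absolute error, whose
heavy-tailed structure penalizes the many near-zero-error pixels that any
added texture perturbs. Consequently, at desk scale the refined fill
closes most of, but does not cross, the coarse fill's masked-L1 level
(0.191 vs 0.179 under the fixed study conditions), while the ablation
ladder (plain GAN, +CRA, +CRA+FLIP) orders exactly as expected
(0.243 ≥ 0.189 ≥ 0.184 at equal 500-step budgets with stage 2 held
fixed). The refinement stage's contribution is texture
and structure realism, not pixel-metric gains — the same trade-off that
adversarial refinement exhibits at clinical scale, where identity is
protected by compositing rather than by the generator's pixel accuracy.

## Known limitations

* The engine is CPU-bound and double-precision; the canonical 256 × 256 /
  width-32 configuration is provided but training it to visual quality is
  far outside desk-scale budgets.
* Detached attention scores mean the encoder receives no gradient that
  would sharpen patch matching; at desk scale the scores stay relatively
  diffuse, so residual aggregation contributes texture statistics rather
  than exact correspondences.
* The deformation classifier and the evaluation segmentor are phantom
  instances of their architectures; their accuracies do not transfer to
  clinical data.
* Only 2-D axial slices are processed; volumes are handled slice-wise.

## A minimal end-to-end run

```{r, eval = FALSE}
ds <- makePairedDataset(200, phantomSpec(size = 64), seed = 101)
models <- trainPseudoHealthy(ds$healthy,
  list(stepsV = 200, stepsG = 500, batch = 4,
       fillerWidths = c(8, 16, 16), genWidth = 8, discWidth = 8,
       patchSize = 8, seed = 1))
seg <- trainUnet(ds$pathological, ds$mask,
  list(epochs = 8, batch = 4, baseWidth = 8, depth = 3, seed = 1))

hold <- makePairedDataset(50, phantomSpec(size = 64), seed = 202)
res <- synthesizePseudoHealthy(hold$pathological[[1]], seg,
                               models$V, models$G)
maskedPSNR(res$image, hold$pathological[[1]], res$mask) # 99 by construction
```
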