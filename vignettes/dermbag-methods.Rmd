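---
title: "Methods: limited-receptive-field bag-of-local-features models with handcrafted-feature reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: limited-receptive-field bag-of-local-features models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Dermoscopic lesion diagnosis hinges on fine local cues — whether the pigment
boundary cuts off abruptly or fades gradually, and whether the color texture
inside the lesion is even or mottled.  Conventional deep classifiers blend
such cues into features whose receptive fields can cover the whole image, so
their attention maps align poorly with the pixels that actually carried the
evidence.  `dermbag` implements a bag-of-local-features classifier that keeps
the correspondence exact: a backbone $B$ maps an image
$I \in \mathbb{R}^{225 \times 225 \times 3}$ to a feature grid
$X \in \mathbb{R}^{25 \times 25 \times 2048}$ in which each cell depends on
exactly one $33 \times 33$ patch at stride 8, and the image-level logits are
the average of per-patch affine responses.  Classification evidence is
therefore additive over patches by construction, which is what makes the
per-patch heatmaps faithful rather than post hoc.

Two handcrafted targets summarize the clinical cues:

* a **color-texture descriptor** $C \in \mathbb{R}^{354}$: uniform local
  binary pattern histograms (8 neighbors, radius 1, 59 bins) over the six
  channels R, G, B, Y, U, V, concatenated in that order;
* an **edge map** $E \in \mathbb{R}^{225\times225}$: the Sobel gradient
  magnitude of the luma channel.

Two 1x1-convolution *divergers* split $X$ into a CTI-biased and an EI-biased
stream.  During training each stream feeds a decoder that reconstructs its
handcrafted target **non-rigidly**: the decoder head outputs a Gaussian field
$(\mu, \sigma)$ and the reconstruction is a reparameterized sample
$z = \mu + \sigma\epsilon$, $\epsilon \sim \mathcal{N}(0, 1)$.  The targets
guide the streams without pinning them to the handcrafted features.  The
reconstruction loss is

$$ L_{rec} = \log\big(\mathrm{KL}(C \,\|\, z_{CTI}) + 1\big)
           + \log\big(\mathrm{KL}(E \,\|\, \hat{E}) + 1\big), $$

and the total loss is $L = L_S + L_{rec}$ with $L_S$ the softmax
cross-entropy.  Sigmoid spatial *gates* reweight each stream per cell before
concatenation, global average pooling, and the affine classifier
(4096-dimensional input in the full configuration).  At inference the
decoders are dropped.

## Backbone layer plan

The backbone is a no-padding residual bottleneck network.  The stem is a 1x1
convolution followed by a 3x3 convolution; each stage places its only 3x3
convolution (and its spatial stride) in the first block, with every other
convolution 1x1.  Because the main path of a 3x3 block is two pixels smaller
than its stride-only shortcut, the shortcut is cropped top-left to match —
cropping discards rows/columns but never widens a cell's input support, so
the locality invariant is preserved exactly.  The realized full-scale plan:

| stage | blocks | mid | out | stride | spatial conv |
|-------|--------|-----|-----|--------|--------------|
| stem  | —      | —   | 64  | 1      | 1x1 then 3x3 |
| 1     | 3      | 64  | 256 | 2      | 3x3 in block 1 |
| 2     | 4      | 128 | 512 | 2      | 3x3 in block 1 |
| 3     | 6      | 256 | 1024| 2      | 3x3 in block 1 |
| 4     | 3      | 512 | 2048| 1      | 3x3 in block 1 |

Receptive-field folding (`rf <- rf + (k-1) * jump; jump <- jump * s`) gives
side 33 and stride 8; `backbone_rf_arith()` recomputes this for any plan and
`receptive_field_probe()` verifies it empirically from gradient support.
A tiny configuration (57x57 input, 9x9 patches, stride 8, 64 channels,
7x7 grid) uses the same construction so that every downstream module runs on
a CPU in seconds; tests and the synthetic study use it throughout.

The convolutional engine itself (valid convolutions and transposed
convolutions lowered to GEMM via im2col/col2im in C++, batch normalization,
and hand-written backpropagation) is part of the package; its gradients are
verified against central finite differences in the test suite.

## Numerical and design choices

Several pieces of the architecture admit more than one reasonable reading;
the package fixes them as follows.

* **LBP configuration.**  A 59-bin histogram uniquely identifies uniform LBP
  with 8 neighbors: 58 codes with at most two circular transitions plus one
  catch-all bin.  We use the discrete 3x3 ring at radius 1, comparator
  "neighbor >= center", and mirror padding at the borders.  Histograms are
  L1-normalized per channel so the descriptor is image-size invariant.
* **Color space.**  BT.601 coefficients (Y = 0.299R + 0.587G + 0.114B, U and
  V zero-centered), the default of mainstream imaging libraries; the
  transform is exactly invertible, which the tests exploit.
* **Sobel source and scaling.**  The edge map is computed on the BT.601 luma
  with mirror padding (output size = input size) and rescaled by its maximum
  when positive, keeping it commensurate with normalized decoder outputs.
* **Positivity of sigma.**  The mu and sigma branches are structurally
  identical, so positivity must come from parameterization: the sigma branch
  outputs log sigma and is exponentiated.  The branches share no parameters,
  matching the divergers' convention.  The sampling noise is standard normal,
  `eps ~ N(0, 1)`.
* **KL on non-simplex targets.**  A KL loss needs two distributions.  The
  descriptor target is L1-normalized globally (its six blocks each sum to 1,
  so this divides by 6); the edge target gets a 1e-8 floor before
  normalization so all-zero maps remain defined; predictions pass through
  log-softmax over the vector (or flattened map).  KL(target || prediction)
  is summed, then damped by `log(. + 1)` per term.  Results are somewhat
  sensitive to this normalization; it is the one we consider canonical for a
  "KL loss with sum reduction" contract.
* **SAM radius.**  rho defaults to 0.05 (the standard SAM default);
  the ascent step uses the full loss $L$, not only $L_S$.  Running
  batch-normalization statistics are frozen on the perturbed pass so the
  second forward does not double-count batch statistics.  A zero gradient
  norm skips the perturbation.
* **PSAM granularity.**  The general/SAM partition is drawn per parameter
  *element* and resampled every step — PSAM acts like dropout-style noise
  injection, which argues for fine-grained, per-step randomness.  The
  partition is an exact half/half split (sizes differ by at most one element
  for odd counts).
* **Augmentation and crops.**  Training resizes to 256/225 of the input side
  and takes a random input-sized crop plus horizontal/vertical flips;
  inference center-crops.  Since flips and crops move edges, the
  reconstruction targets are recomputed on the augmented image.
* **Model selection.**  Best validation macro F1, the class-imbalance-aware
  headline metric; the best parameters are restored after the last epoch.
* **Heatmaps.**  Per-patch logits include the class bias so that their mean
  over the stride-8 grid equals the image logit exactly (GAP and an affine
  map commute).  Stride-1 coverage pads the image with zeros by 16 pixels
  (4 at tiny scale) and scores all input-size^2 windows; the implementation
  forwards the stride^2 crop offsets of the padded image, which the locality
  invariant makes exactly equivalent to explicit window extraction (a test
  compares both).  The explained class defaults to the predicted one.
  Negative raw scores are kept and handled by the min-max normalization; a
  constant raw map normalizes to zeros with a warning.  An all-nonpositive
  classifier row has undefined mass shares; we fall back to equal alphas
  with a warning.
* **Occlusion analysis.**  Candidate windows are the stride-8 grid; masking
  fills with zeros (consistent with the zero padding elsewhere); ranking
  ties break row-major for reproducibility.  Windows overlap (stride 8 <
  side 33), so k counts windows, not pixels.  Rankings are computed once per
  image from the overall heatmap, not re-ranked during any subsequent
  training; external rankings can be supplied to compare other attribution
  methods.  At tiny scale the sweep saturates quickly: the 7x7 grid offers
  only 49 candidate windows, so masking 20 of them removes roughly half the
  pixels and drives *any* ranking to the chance floor — not least because a
  zero-filled square has exactly the sharp boundary that defines the
  abrupt-edge class, so heavily masked images are predicted as that class
  regardless of where the windows sat.  The discriminative value of the
  heatmap ranking is therefore visible at small k (guided masking costs
  clearly more accuracy than random masking at k = 1..3, i.e. at masked
  fractions comparable to a 20-window sweep on the full 25x25 grid) and the
  tests assert it there; at k = 20 on the tiny grid the two arms tie at the
  floor.

## The synthetic study

The generator emulates the two clinical cues the model is built around.
Each image is a shaded skin-toned background with one random ellipse;
`abrupt` classes use a hard pigment cutoff, `gradual` classes a smoothstep
ramp of relative half-width 0.45; `mottled` classes superimpose two-scale
dark blotches (depth 0.45) inside the lesion; Gaussian pixel noise has
sd 0.02.  The default three classes are (abrupt, uniform),
(gradual, uniform), (gradual, mottled), so the edge cue separates class 1
from the others and the texture cue separates class 3.  The palette and
shape constants are fixed in the source and were chosen so that the cue
separation is verifiable with the package's own extractors (the Sobel
boundary-band statistic and a linear probe on the LBP descriptor) and so a
tiny model reaches well over twice chance accuracy within 20 epochs on a
CPU.  Each image carries its boundary-band mask (|elliptical radius - 1| <
0.12) for heatmap-overlap analyses.

What passing these tests does *not* show: the generator has no hair, rulers,
specular highlights, vignetting, or camera color variation, lesions are
single ellipses, and class cues are far cleaner than in clinical imagery.
Synthetic results validate the mechanics (losses, optimizers, locality,
heatmap fidelity), not clinical performance; full-scale dermoscopy training
requires the public challenge datasets and is out of scope here.

## Problem sizes used by the tests

The test suite trains one shared tiny model on the synthetic study
conditions (3 classes, 100 images per class, 60/20/20 split, 20 epochs,
PSAM, seed fixed) — about six minutes on one CPU — and reuses it for the
alpha-share, heatmap-contract, occlusion, and above-chance criteria.  The
full-scale (225/33/8, 2048-channel) model is built once for the
architectural checks: gradient-support probe, channel and classifier widths,
and decoder geometry; a forward plus one-cell backward pass takes roughly
half a minute.  Monte-Carlo checks use 10,000 draws on 10-dimensional toy
fields; optimizer equivalences run 5 steps on closed-form quadratics.

## Known limitations

* Training at full scale in R is possible but slow; the package targets
  desk-scale scientific use (tiny configuration) and architectural fidelity
  at full scale.  No GPU path, mixed precision, or distributed training.
* The engine supports exactly the layer vocabulary this model needs; it is
  not a general deep-learning framework.
* PNG and TIFF images are supported; JPEG is not decoded.
* Long-tail-specific losses, CAM/Grad-CAM baselines, and global-context
  fusion variants are intentionally out of scope.
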