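---
title: "Model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(slhardnet)
```

This vignette records the model implemented by `slhardnet`, the assumptions
behind it, and the choices made where the design was genuinely open. It
states no empirical number that the test suite or `scripts/acceptance.R`
does not itself compute.

## The segmentation problem

Dermoscopic lesion segmentation is binary dense prediction under three
recurring difficulties: low lesion/skin contrast (fuzzy borders), occlusion
by hair and bubbles, and large variation in lesion size and shape. The
architecture addresses them with, respectively, a boundary-weighted loss, a
low-level attention branch that can suppress thin occluders, and a
multi-dilation cascaded decoder whose receptive-field ladder covers both
small and large lesions.

## Encoder

The encoder is a HarDNet-68: a stem of two 3×3 convolutions (the first at
stride 2) plus 2×2 max pooling, followed by five 8-layer harmonic dense
blocks with pooling after blocks 1, 3 and 4, so blocks 2 and 3 share their
spatial size. Within a block, layer $\ell$ reads layers $\ell - 2^i$ for
every $2^i \mid \ell$ and has width $g\,m^{v_2(\ell)}$ rounded to the
nearest even integer ($m = 1.7$); the odd-indexed layers plus the last are
concatenated and compressed by a 1×1 transition. Per-block growths
$(14, 16, 20, 40, 160)$ and transition widths $(128, 256, 320, 640, 1024)$
give the tap contract: strides 4/8/16/32 with 128/320/640/1024 channels.
All five blocks use eight layers — the depth the architecture description
fixes — even though related harmonic-dense designs shorten the last block;
this costs parameters in block five (its layer inputs include the 1024-wide
block input) but preserves the stated structure.

The encoder is randomly initialized (He) by default. Pretrained weights can
be loaded from a checkpoint through `load_state_dict()`; no pretraining is
asserted or required by any test.

## Decoder, attention and aggregation

The cascaded decoder fuses the reduced taps in two stages, at stride 16 and
stride 8, through five *independently parameterized* FPM instances — the
two stage-one instances read the same upsampled deepest tap but are used
differently, and weight sharing is nowhere implied. Points that the printed
equations leave open, resolved here:

- **Dilated-branch padding.** A 3×3 convolution with dilation $D$ is
  size-preserving only with pad $D$; the factorized $1{\times}D$ /
  $D{\times}1$ convolutions use pad $(D-1)/2$ on their long axis. This is
  the only shape-consistent reading and is asserted by tests for
  $D \in \{1,3,5,7\}$.
- **FPM exit convolution** carries no normalization or activation before
  the residual addition, so that with all internal weights zero the module
  is exactly the identity (a tested invariant).
- **Batch norm + ReLU** follow every 3×3 fusion convolution and the convs
  inside the dilated branches; the 1×1 reducers, attention projections and
  heads are plain convolutions with bias.
- **Upsampling** is bilinear with corner alignment off, everywhere;
  learned deconvolution is deliberately avoided.

The attention module is a *parallel sum* of a spatial gate and a channel
gate — not the sequential composition used by CBAM-style blocks — and its
two channel bottlenecks are separate operators. Both facts are asserted by
tests (sum-composition oracle; a sequential foil must differ).

In the aggregation module, both pixel embeddings $Q$ and $P$ are derived
from the semantic map $O_1$, exactly as the defining equations print it
(even though the surrounding narrative suggests $P$ might come from the
detail branch); this literal reading is implemented and flagged here rather
than "corrected". The printed node-feature shape $16 \times 16 \times 1$ is
read as $K = 16$ anchor nodes of 16 dimensions, obtained by adaptive
average pooling of the gated embedding to a $4\times4$ grid; "center
clipping" becomes a centered crop that is a no-op at the default grid and
activates if a larger `pool_grid` is configured. The graph unit is the
minimal standard one — $\mathrm{ReLU}((I - A)\,F\,W)$ with a learned
adjacency $A$ (zero-initialized, so the unit starts as a channel map) — and
is checked against a dense linear-algebra oracle on 16-pixel toys. The
detail map is aligned to stride 8 once at module entry and shared by the
gate and the mutual embedding; "second channel" of the gate softmax means
index 2 in R's 1-based indexing.

## Losses

The training objective applies the combination $L = IL + BL$ (weighted IoU
plus weighted BCE) to the fused head and to the auxiliary decoder head,
against the same full-resolution ground truth. The weight formula is not
printed in the architecture description; the implementation adopts the
boundary-weighting convention of the salient-object/polyp decoder lineage,

$$ w = 1 + \omega\,\lvert \mathrm{meanpool}_k(G) - G \rvert, \qquad
   k = 31,\ \omega = 5, $$

with reflective padding so constant masks get $w \equiv 1$ everywhere,
including borders. Both $k$ and $\omega$ are configuration parameters. BCE
is computed stably from logits; the IoU loss uses $+1$ smoothing so empty
masks are well-defined. The unweighted IoU/BCE/Dice family and their two
combinations are available (`alt_losses()`) for loss-comparison
experiments. Metrics are averaged per image (the ISIC reporting
convention); pooled-count aggregation is available by flag. When a
reference class is empty, a metric is 1 if the prediction agrees and 0
otherwise — a stated convention, since the usual formulas are 0/0 there.

## Data pipeline

Masks are binarized at gray level 128 on load and resized
nearest-neighbour; images bilinearly. The four augmentation transforms
(vertical flip, horizontal flip, rotation, Gaussian noise) each fire with
probability 0.5; the rotation range (±90°) and noise level (10/255) are not
part of the published recipe and are configurable defaults. Rotation uses
nearest-neighbour sampling for image *and* mask: a mixed
bilinear-image/nearest-mask scheme would let the pair drift apart at the
boundary and cannot satisfy the locked-pair invariant the test suite
enforces (augmenting a sample whose image equals its mask must keep them
equal under the geometric transforms). The k-fold splitter shuffles once
under the given seed and deals round-robin, giving disjoint, covering folds
whose sizes differ by at most one.

## Synthetic generator

`make_synthetic()` emulates the difficulty axes of dermoscopy: lesions are
unions of star-convex blobs with Fourier-perturbed elliptical boundaries,
rendered darker than a warm, mildly graded skin background and composited
through a Gaussian-blurred alpha so the *image* border is fuzzy while the
*mask* stays the exact rendered blob union; hair is drawn as dark quadratic
Bézier strokes over lesion and skin but never enters the mask (hair is an
occluder, not lesion); pixel noise is additive Gaussian; images are
quantized to 8 bits. Lesion centers and radii are constrained so the mask
never touches the canvas border. `make_synthetic_dataset()` alternates
easy (contrast 0.35–0.7) and hard (contrast 0.08–0.25 or up to five hair
strokes) samples, with radii wide enough that mask areas span more than an
order of magnitude.

What the generator does **not** emulate: real pigment network texture,
color variegation inside lesions, bubbles and ruler artifacts, vignetting,
and inter-center color shifts. Passing the learning-sanity tests therefore
demonstrates that the network, losses and optimizer are wired correctly
and can both memorize and generalize on lesion-like structure — not that
the model reaches any particular accuracy on clinical ISIC or PH2 data,
which would require the published full-scale training protocol.

## Training harness and problem sizes

Training uses AdamW (decoupled weight decay, default $10^{-2}$ — the
optimizer's conventional default, as no value is published) with cosine
annealing whose period is the full run and no restarts; "best" weights are
the ones maximizing mean validation Dice, re-loaded at the end. Everything
is seeded: initialization, shuffling, augmentation (per-sample seeds derive
from the config seed, epoch and sample index).

The bundled experiments run at desk scale by design: the capacity check
overfits four 96×96 synthetic lesions with batch 4 at learning rate
$10^{-3}$ and stops as soon as training Dice reaches 0.95 within its
200-step budget; the generalization check trains on 64 samples (batch 8,
same rate) and stops when held-out Dice reaches 0.85 within 15 epochs.
The $10^{-3}$ rate is a harness choice for these short-budget checks; the
default configuration keeps the published $10^{-4}$ for full-length runs.
Validation can be thinned with `eval_every` on long runs.

## Numerical core

All tensors are `(H, W, C, N)` double arrays; convolution is im2col + GEMM
(RcppArmadillo), with batch-norm statistics over space and batch per
channel ($\epsilon = 10^{-5}$, running-stat momentum 0.1, biased variance).
The autodiff tape records nodes in creation order and differentiates in
reverse; gradient correctness of every operator is tested against finite
differences, and the convolution kernels against nested-loop oracles,
including strided, dilated and asymmetric cases. Max-pool ties break toward
the first element in column-major order; bilinear resampling uses
half-pixel centers without corner alignment; adaptive pooling uses
floor/ceil bin edges. In evaluation mode batch norm uses running
statistics, making inference deterministic.

## Known limitations

- CPU-only and double precision: throughput is orders of magnitude below a
  GPU framework, so full-scale (512×512, 200-epoch) training is out of
  desk-scale reach; the package targets correctness, small-scale
  experiments and inference.
- Single-device training only; no multi-class segmentation, test-time
  augmentation or ensembling.
- The eight-layer fifth block concentrates most of the parameter budget;
  loading of external checkpoints is only possible for this exact
  configuration.
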