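---
title: "Segmenting minirhizotron root images with a sub-pixel upsampling head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting minirhizotron root images with a sub-pixel upsampling head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Minirhizotron imaging records soil profiles through buried transparent tubes.
The resulting scans are enormous (up to roughly 10,200 × 14,039 px), and the
objects of interest — roots — are thin, curvilinear, low-contrast structures
embedded in textured soil with bright stone fragments. Two failure modes
dominate automated segmentation: bright soil particles mistaken for roots
(false positives) and washed-out brown roots merging into the background
(false negatives). `rootseg` implements a pixel-wise segmentation network
addressing both, plus the scaffolding to train and evaluate it reproducibly.

## Model and assumptions

The network is an encoder–decoder with atrous spatial pyramid pooling (ASPP)
at output stride 16 and a configurable final upsampling head.

**Encoder.** A stem convolution and three depthwise-separable blocks, each
with stride 2, reduce the input 16× per spatial dimension. The `"lite"`
backbone uses one block per stage so a desk CPU can train it; `"xception"`
adds a second, non-strided separable block per stage. Since the published
workflow trains from scratch in hours, no pretrained weights are used
anywhere. ASPP runs five parallel branches on the stride-16 features — 1 × 1
convolution, three separable 3 × 3 atrous convolutions with dilation rates 6,
12, 18, and global image pooling — concatenated and compressed by 1 × 1
convolution. The published description names only the three atrous branches;
the 1 × 1 and pooling branches are the standard DeepLabv3+ composition and
can be disabled (`aspp_1x1`, `aspp_pool`).

**Decoder.** 4× bilinear upsampling to stride 4, concatenation with
1 × 1-reduced low-level (stride-4) features, then one 3 × 3 fusion
convolution. Low-level reduction to 48 channels and 256 decoder channels are
unstated in the source description and adopted from standard DeepLabv3+
practice.

**Upsampling head.** The last 4× stage is the point of the method:

* `bilinear` — fixed corner-aligned bilinear interpolation. Each output value
  is a convex combination of the four nearest input samples (two linear
  interpolations, first along x then along y), which acts as a low-pass
  filter and blurs exactly the fine-root edges the application cares about.
* `subpixel` — two cascaded learned stages, each a 3 × 3 convolution
  quadrupling the channel count followed by the periodic shuffle
  `out[y, x, c] = in[⌊y/2⌋, ⌊x/2⌋, 4c + 2(y mod 2) + (x mod 2)]`.
  The description fixes `r = 2` per stage while replacing a 4× bilinear
  stage; we resolve this as two cascaded r = 2 stages totalling 4×. The
  classifier (1 × 1) sits after the final upsample, so sub-pixel stages
  operate on features, not logits. The shuffle's channel-major phase order
  follows the originating super-resolution formulation; the alternative
  orders would merely permute the preceding convolution's channels.

**Numerical conventions.** Tensors are H × W × C arrays, 0-based row-major
coordinates, origin top-left. Bilinear resampling is corner-aligned (output
corner samples coincide with input corner samples); this is the reading most
consistent with interpolating on an integer lattice, and it is implemented in
one kernel so the half-pixel-centre alternative could be swapped in.
"Same" padding splits the excess as floor(top)/rest(bottom). Weights are
He-normal initialised, biases zero; there is no batch normalisation — at desk
scale the plain stack trains stably with Adam, and omitting it keeps
per-sample forward/backward exact and deterministic.

## Tiling

Scans are zero-padded bottom/right to the next multiple of the tile size
(original pixel coordinates unchanged), split row-major into fixed-size
tiles — for the full-scan geometry, 10,200 × 14,039 pads to 10,240 × 14,336
(pads 40 and 297) and yields 560 tiles of 512 px — passed through the
network, and stitched back. Stitching averages *scores* (not labels) in
overlapping regions and crops the padding; argmax happens after stitching, so
tile seams cannot create label artifacts. The default stride equals the tile
size (non-overlapping, the published reading); smaller strides are exposed
because the published sub-image counts (16,936 train / 892 validation from 10
scans) are irreconcilable with non-overlapping tiling, which gives 560 tiles
per scan — the overlap/augmentation actually used is unstated, so the
package exposes `stride` rather than guessing.

## Training

Pixel-wise softmax cross-entropy, Adam with learning rate 7e-4, β₁ 0.9,
β₂ 0.999, ε 1e-8, and weight decay 1e-6 folded into the gradient (classic
coupled Adam + L2 — the recipe predates decoupled decay). The learning rate
is constant: only an initial rate is specified and Adam's adaptivity is
credited for convergence. Exactly `epochs` epochs run, with no early
stopping or hidden convergence criteria; the best-validation-F1 parameters
are kept alongside the final ones. Splits are seeded, tile-level, disjoint
and exhaustive; the default validation fraction 0.05 mirrors the published
≈16,936/892 ratio. No data augmentation is applied (none is described).
Cross-entropy is unweighted by default (faithful); per-class weights are
exposed because roots cover well under 15% of pixels. Presets: `"desk"`
(batch 8, 20 epochs) and `"paper"` (batch 24, 80 epochs, GPU-scale).

## The synthetic world

Field minirhizotron datasets with pixel-accurate annotations are rarely
redistributable, so the package generates its own scenes with exact masks:

* **Roots** — smoothed random walks (heading perturbed by bounded Gaussian
  steps of SD 0.14 rad per 1.5 px step) with linear width taper to ~30% of
  the starting width, branching into fine laterals with probability
  `branch_probability` at anchors every ~14 steps. This matches the visual
  character of tapering lateral roots without any biological growth model.
* **Soil** — mean grey 90 with two-frequency Gaussian texture (a coarse
  field bilinearly upsampled plus per-pixel grain, SD 12), tinted brown.
* **Distractors** — bright ellipses (stones/highlights, intensity 200–255,
  expected 8 per megapixel) and low-contrast brown strokes; both are drawn
  into the image only, never the mask, emulating the false-positive and
  false-negative sources respectively.
* **Contrast regimes** — `"high"` renders roots at intensity 170–240 in a
  brown-to-white tint band; `"low"` compresses the band to 105–140, near the
  soil mean.

One integer seed fully determines a scene; datasets vary it as `seed + i`.
Masks are written white-on-black and survive the write/read round trip
bit-exactly. A 100-seed Monte Carlo of the default stroke geometry at
512 × 512 with 5 roots of widths 3–15 px gave root-pixel fractions in
0.037–0.160 (mean 0.094); the frozen test band is [0.02, 0.18].

What a green test does *not* establish: the generator has no root occlusion
by soil films, no moisture gradients, no tube-wall artifacts, no condensation
or scratches, and no temporal correlation — so synthetic scores say the
method and code work, not that field performance is reproduced. The
published distribution shift (validation F1 0.977 vs test dice ≈0.62–0.67 on
unexamined scans) is precisely the kind of effect this world cannot and does
not try to replicate.

## Raster formats

No PNG/BMP codec exists in the target R environment, so images are binary
PNM (P6 RGB, P5 grayscale masks, 0 = background, 255 = root) — lossless,
universally convertible, and bit-exact on round trip. The mask semantics of
the white-on-black annotation convention are preserved.

## Scaling of the test suite

The learning checks train real networks but at reduced size so the suite
fits a CPU test budget: the "easy world" smoke test uses the default
high-contrast appearance on 96 px canvases (root count scaled to keep
coverage near the 512-canvas default) with 40 scenes and 30 epochs, and must
reach validation F1 ≥ 0.90; the head comparison trains paired
bilinear/sub-pixel models on a thin-structure world (fine widths 1–3 px,
64 px canvases) across 3 seeds and requires the median sub-pixel dice not to
fall below the median bilinear dice by more than 0.01. In calibration runs
the sub-pixel head won by a wide margin on every seed (e.g. medians 0.66 vs
0.44), consistent with the published direction. Thresholds are never scaled,
only problem sizes.

## Root length

`estimate_root_length()` skeletonises a mask (Zhang–Suen thinning), prunes
spurs shorter than 5 px that end in a junction (thinning artifacts of
boundary bumps), and sums links: 1 px per orthogonal neighbour pair,
√2 px per diagonal pair, skipping diagonals whose corner pixel is present.
A straight n-pixel run measures n − 1. Digital chain codes with √2 weights
overestimate oblique curves by up to ~8%; against the generator's analytic
centreline length the estimator stays within ±10% for stroke widths ≤ 5 px.
This is deliberately plumbing, not a trait pipeline: diameter/surface/volume
extraction is out of scope (the published comparison itself found average
diameter unreliable, r² = 0.0062 against manual tracing).

## Design choices where the description was open

* **Fitting interface** — one entry point `fit_rootseg()` returning a classed
  object with `print`/`summary`/`plot`/`predict` methods, in the classic R
  modelling idiom; `coef`/`residuals` are not meaningful for a pixel-wise
  CNN and are not provided.
* **Aggregation** — micro (pooled pixel counts) by default, macro available;
  the published evaluation does not state which it used.
* **Degenerate metrics** — zero denominators yield 0 with a `degenerate`
  flag, never NaN, so batch reports cannot fail.
* **Binarisation** — argmax of stitched scores (equivalently a 0.5
  probability threshold for two classes); no morphological post-processing.
* **Physical units** — no pixel-size calibration is published; the package
  works in pixels and leaves mm to the user.

## Known limitations

Pure-R/BLAS training is orders of magnitude slower than a GPU framework; the
paper-scale preset (512 px tiles, batch 24, 80 epochs) is provided and
correct but intended for patient hardware. Only two classes are exercised by
the tests (more are supported in the types). The `"xception"` option is a
deeper separable stack, not a faithful 65-layer Xception.
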