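---
title: "Self-supervised depth and light decomposition for endoscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised depth and light decomposition for endoscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodepth)
```

## The problem and the model

Monocular depth estimation in colonoscopy is hard for a specific physical
reason: the only light source sits on the camera, the tissue is wet and
highly reflective, and the resulting saturated specular highlights move with
the viewpoint. Self-supervised depth methods assume photoconsistency — that
a surface point keeps its colour across views — and speculars are exactly
where this assumption fails.

This package models each frame as

$$I = A \odot S + M$$

where $A$ is the albedo (intrinsic surface colour), $S$ a single-channel
shading field (illumination received and diffusely re-emitted), and $M$ an
additive specular component. The diffuse part $A \odot S$ obeys
photoconsistency far better than $I$ itself; $M$ absorbs the mirror-like
highlights that do not. Shading is stored single-channel because the light
source is effectively monochromatic; a 3-channel variant would only add
unidentifiable degrees of freedom.

Three small networks are trained jointly and self-supervised:

* a **depth network** (U-shaped encoder–decoder, sigmoid disparity output),
* a **pose network** (convolutional regressor from a channel-stacked frame
  pair to an axis-angle + translation 6-vector),
* a **decomposition network** (U-shaped, emitting $A$ through a sigmoid and
  $S$ through a softplus).

Given target and source frames, the target's depth and the pair's relative
pose reproject every target pixel into the source view
($p_s \sim K\,T_{t\to s}\,D_t(p_t)\,K^{-1}p_t$); bilinear sampling
reconstructs the source *diffuse* image in target geometry,
$AS_{s \to t}$, which is compared against the target after specular removal
($I_{t,\mathrm{rem}}$).

## The objective

Every image comparison uses the same per-pixel form
$\alpha\,(1-\mathrm{SSIM})/2 + (1-\alpha)\,\lVert\cdot\rVert_1$ with
$\alpha = 0.85$. The total loss is

$$L = \lambda_d\,(L_d^{(t)} + L_d^{(s)}) + \lambda_a\,\langle L_a\rangle_\mu
    + \lambda_r\,\langle L_r\rangle_\mu + \lambda_{es}\,L_{es}$$

with $\lambda_d = 0.2$, $\lambda_a = 0.2$, $\lambda_r = 1$,
$\lambda_{es} = 0.01$:

* $L_d$ (decomposition): photometric distance between $A \odot S$ and
  $I_\mathrm{rem}$, unmasked, for the target and each source frame.
* $L_a$ (albedo): $\lVert A_t - A_{s\to t}\rVert_1$ — albedo is a surface
  property, so after warping it must agree; any residual difference is
  warping error, not lighting.
* $L_r$ (reprojection): photometric distance between $AS_{s\to t}$ and
  $I_{t,\mathrm{rem}}$, the actual depth/pose supervision.
* $L_{es}$ (edge-aware smoothness):
  $|\partial_x D|e^{-|\partial_x I|} + |\partial_y D|e^{-|\partial_y I|}$
  with forward differences, implemented literally (no mean normalization of
  depth).

$\langle\cdot\rangle_\mu$ is the mean over mask-1 pixels — mask first, then
average, so mask density does not rescale the loss; an empty mask yields 0
with a warning rather than NaN.

**Multi-source aggregation.** With two source frames the reprojection map is
aggregated by the per-pixel *minimum* over sources (each pixel is judged by
the source that sees it best, which also absorbs occlusion), the albedo and
decomposition source terms by the mean. A config flag switches $L_r$ to the
mean.

## Auto-masking

Two binary gates multiply into the masked terms:

* $\mu_1 = [\min_s L_r(I_t, I_{s\to t}) < \min_s L_r(I_t, I_s)]$ keeps a
  pixel only when warping a source explains it strictly better than the raw
  source already does. Pixels that do not move with the scene — burned-in
  UI text, a static camera — fail the strict inequality and are dropped,
  which prevents the classic infinite-depth artefact.
* $\mu_2 = [I_{s\to t} > 0]$ on the channel maximum drops pixels that left
  the source view (zero-padded sampling). This literal rule also masks
  genuinely black source pixels; a `valid_mask = "geometric"` option uses
  the sampler's coordinate-validity instead. The literal rule stays the
  default. With two sources, $\mu_2$ is the union of per-source validity,
  matching the minimum-reprojection aggregation.

Masks are computed from detached values and never receive gradients.

## Specular preprocessing

The specular-free supervision image $I_\mathrm{rem}$ comes from a classical,
fully deterministic pipeline: threshold segmentation (near-saturated
minimum channel, or bright-and-colourless relative to a local median),
disc dilation to catch halos, small-component removal, then harmonic
inpainting (Jacobi relaxation of the Laplace equation with the surrounding
intensities as boundary, tolerance 1e-4, cap 2000 iterations). The discrete
maximum principle guarantees filled values stay within the boundary range.
Thresholds (`t_abs = 0.92`, `t_sat = 0.25`, `t_rel = 1.7`, dilation 2 px,
`min_area` 4 px) were fixed on the synthetic fixtures and are all exposed.
Results are cached on disk keyed by a content hash, so training never
recomputes them.

The trained model is expected to detect and remove speculars *beyond* this
detector: at inference the specular component is recovered as
`binarize(I - AS)` at 50 on the 8-bit scale, with the residual reduced over
channels by its maximum (speculars are near-white, so the max is the most
sensitive reduction; the mean is available). The threshold is interpreted on
[0, 255] because that is the scale on which a threshold of 50 is meaningful
for 8-bit video.

## Training mechanics

There is no deep-learning framework for R in this stack, so the package
carries a compact reverse-mode automatic differentiation engine over dense
`H x W x C` arrays: convolution as im2col + BLAS matmul (input gradients as
transposed convolution), 2x average pooling / nearest upsampling, 3x3
reflection-padded mean filtering for SSIM, and differentiable bilinear grid
sampling. Every op is checked against central finite differences in the
test suite.

Two choices are specific to training *from scratch*. The published pipelines
in this family initialize depth and pose from pretrained weights; no
pretrained weights are shipped here, and cold-started networks expose two
failure modes that warm-started ones never meet:

* **Multi-scale supervision** (`n_scales`, default 4). The bilinear
  sampler's gradient only sees one pixel of context, so at full resolution
  a pose/depth error corresponding to several pixels of flow produces no
  useful gradient and the zero-motion solution is locally stable. The
  photometric terms are therefore evaluated on an image pyramid (each level
  half the previous, intrinsics rescaled accordingly, masks per level);
  coarse levels capture large displacements and hand over to fine levels as
  the estimates improve. `n_scales = 1` restores plain full-resolution
  supervision.
* **A bootstrap phase** (`bootstrap_steps`, default 300). The reprojection
  term warps the diffuse reconstruction `A*S`, but a cold decomposition
  network outputs a nearly uniform `A*S` that carries no texture, so depth
  and pose would receive no signal until the decomposition has converged —
  and receive it from a moving target while it does. For the first
  `bootstrap_steps` optimizer steps, the reprojection term warps the raw
  source frames instead; afterwards the objective is exactly the
  non-Lambertian one. The decomposition and albedo terms are unaffected
  throughout.

Other choices that matter:

* **Disparity to depth**: $1/D = 1/d_{max} + d\,(1/d_{min} - 1/d_{max})$,
  so the sigmoid's (0,1) range maps to $[d_{min}, d_{max}]$ (defaults 0.1
  and 10 scene units).
* **Pose**: axis-angle via the Rodrigues map, with a series branch at small
  angles so gradients stay finite at zero rotation; network output scaled
  by 0.01 so initial motions are small.
* **Optimizer**: Adam, default learning rate 1e-4 over 20 epochs, with a
  100-step linear warm-up, global gradient-norm clipping at 10, and a 1/3
  learning-rate decay after 60% of the planned steps; the toy runs in the
  tests use 3e-3, which on the small synthetic scenes converges within
  their step budget. Warm-up and clipping exist because cold-started joint
  depth/pose training can be tipped into degenerate all-near or all-far
  depth solutions by a few bad early updates; both are standard
  stabilizers. Gradients can be accumulated over `batch_size` triplets per
  step. One global seed fans out to weight initialization and epoch
  shuffling; there is no augmentation, and in particular no horizontal
  flipping, because the principal point is not at the image centre.
* **Coordinates**: 0-based, origin at the centre of the top-left pixel;
  a continuous coordinate $u$ interpolates cells $\lfloor u\rfloor$ and
  $\lfloor u\rfloor + 1$; validity requires the full 2x2 support inside the
  source and positive transformed depth. With the identity pose the sample
  coordinates are integral and the warp is exact, a property the tests rely
  on.
* The shading **adjustment network** used by earlier Lambertian
  decomposition models is intentionally absent: the specular component is
  its replacement. The configuration flag exists but refuses `TRUE`.

Ablation flags reproduce the model family: `use_inpainting` (IM) — when
off, $I_\mathrm{rem} := I$; `use_automask` (AM) — when off, $\mu_1 \equiv 1$.
IM and AM off together is the plain Lambertian-decomposition baseline.

## The synthetic scenes

The renderer is the package's data source for testing and emulates the
features that matter for this method, with full ground truth (albedo,
shading, specular component and its saturated-core mask, metric depth,
poses, intrinsics):

* a tube with periodic radius modulation (haustral folds) or a
  fronto-parallel plane; depth by closed-form ray–cylinder intersection, or
  vectorized marching + bisection when folds are on;
* a light co-located with the camera and inverse-power distance falloff —
  the endoscope configuration, which makes shading view-dependent and moves
  highlights between frames like on real tissue. The falloff exponent is
  configurable: 2 is a point source; values below 2 approximate the
  extended ring illuminator of a real endoscope tip;
* procedural mucosa albedo (seeded smooth waves + sharp vascular streaks)
  with adjustable contrast;
* specular spots as surface-anchored glossy facets: a plateau with a sharp
  logistic rim, normal tilted toward a reference camera position, and a very
  high Phong exponent, so highlights are saturated where the geometry
  aligns and fade/move with small viewpoint changes. The ground-truth spot
  mask is the set of pixels where the specular component alone reaches the
  saturation threshold (0.92);
* an optional static, burned-in text-like overlay at fixed gray, for
  auto-masking tests;
* deterministic given the spec: the same seed yields bitwise-identical
  sequences. 8-bit quantization happens only when writing PNGs.

**What the scenes do not emulate** — and hence what passing tests do not
show about real data: sensor noise and motion blur, deformation, fluids and
debris, sRGB/gamma response, interreflections, and realistic colour
statistics. The scenes are a controlled physics sandbox for the geometry
and light model, not a colonoscopy simulator.

A note on two deliberate test-scene choices. A perfectly straight tube
viewed along its axis under a co-located light is nearly *self-similar*:
moving forward barely changes the image, so the raw-source photometric
baseline in $\mu_1$ is almost zero everywhere and the mask collapses — an
artefact of an unrealistically degenerate scene, which the haustral folds
remove. And the static-overlay mask property is exercised on a textured
plane with lateral/rotational motion, where photoconsistency of the moving
content holds cleanly; on the tube, the view-dependent shading of the
co-located point light dominates the comparison and tests the light model,
not the mask semantics.

## Evaluation

Monocular depth is scale-ambiguous, so predictions are median-scaled
(multiplied by median(gt)/median(pred)) before computing MAE, MedAE, RMSE,
RMSE_log, Abs_Rel, Sq_Rel and the threshold accuracies
$\delta < 1.25^k$; metrics are computed per image and then averaged across
images, never pooled over pixels.

For data without ground truth, the specularity-surrounding metric (SSM)
scores depth smoothness across specular regions: a region counts as smooth
when its mean depth is within $\tau$ (relative, default 0.1) of the mean
depth of its surroundings — the region's bounding box grown by 5 px, minus
all specular pixels. The percentage of smooth regions is reported; images
without regions are excluded from averages rather than scored 0 or 100.
The $\tau$ and margin defaults are this package's own calibration, recorded
in every result object.

## Problem sizes in the tests

The test suite and the acceptance script run entirely on synthetic scenes:
warping oracles at 8 x 8, photoconsistency and the specular pipeline at
128 x 128, auto-masking at 128 x 128, and a toy end-to-end training on a
60-frame 64 x 64 folded-tube sequence with `tiny` networks: 2000 optimizer
steps at learning rate 3e-3 (decayed by 1/3 at 60%), depth bounds
[0.25, 6], a long bootstrap phase (1400 steps) because everything starts
cold, and a trajectory whose lateral sway (0.25 units) dominates its
rocking (0.02 rad) so that depth-dependent parallax, not depth-free
rotational flow, carries the signal. Training from scratch on a short toy
sequence is the honest but hard setting: the published pipelines in this
family start from pretrained depth/pose weights, which are deliberately
not shipped here. The acceptance script reports the measured improvement
in median-scaled Abs_Rel over the untrained network; at this step budget
the main factor limiting it is the accuracy of the jointly-learned pose,
not the depth network (see the limitations below).

## Known limitations

* Training entirely from scratch at toy scale is limited by the pose
  regressor: with only thousands of optimizer steps, per-pair pose
  estimates remain noisy, and depth accuracy tracks pose accuracy. Joint
  self-supervised systems in this family are ordinarily trained for
  hundreds of thousands of steps from pretrained initializations; the toy
  runs here demonstrate the mechanics and the direction of learning, not
  converged accuracy.

* The reprojection premise is violated by the view-dependent diffuse
  shading itself (the light moves with the camera); the decomposition
  absorbs speculars but not this smooth brightness drift. On real video
  with small baselines the effect is modest; on aggressive synthetic
  motions it bounds the achievable masked photometric error.
* The networks are deliberately small; nothing here aims at benchmark
  accuracy on real datasets, and no pretrained weights are distributed.
* Harmonic inpainting produces smooth (feature-free) fills; it is a
  stand-in for learned inpainting and is labelled as such.
* SSM depends on the detector's segmentation; its absolute value is only
  comparable between methods evaluated with the same detector settings.
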