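# endodepth

Self-supervised monocular depth estimation and intrinsic light decomposition
for endoscopy video, in R.

## The problem

3D reconstruction from a monocular endoscope supports navigation, coverage
assessment and polyp measurement, but colonoscopy frames violate the central
assumption of self-supervised depth learning: photoconsistency. The only
light source moves with the camera, the tissue is wet, and saturated
specular highlights appear, move and vanish from frame to frame.

`endodepth` models each frame with a non-Lambertian decomposition

    I = A ⊙ S + M

— albedo `A` (intrinsic surface colour), single-channel shading `S`
(illumination), and an additive specular component `M`. Depth `D` and
relative camera pose `T` are learned jointly with the decomposition, with no
ground truth, from the photometric reprojection objective

    L = λ_d (L_d(AS_t, I_t,rem) + L_d(AS_s, I_s,rem)) + λ_a ⟨L_a⟩_μ
        + λ_r ⟨L_r⟩_μ + λ_es L_es,     λ = (0.2, 0.2, 1, 0.01)

where every image distance is `α(1−SSIM)/2 + (1−α)L1` with `α = 0.85`,
`I_rem` is the frame after classical specular segmentation + harmonic
inpainting, `L_r` compares the warped source reconstruction `AS_{s→t}`
against `I_t,rem`, `L_a` enforces view-independence of albedo, `L_es` is
edge-aware depth smoothness, and `μ = μ1 ⊙ μ2` combines the static-pixel
auto-mask (`min_s L_r(I_t, I_{s→t}) < min_s L_r(I_t, I_s)`) with the
out-of-view mask (`I_{s→t} > 0`). At inference a single frame yields
`A, S, D, AS` and a specular mask `binarize(I − AS)` at 50/255.

The package is self-contained for this stack: it includes a compact
reverse-mode autodiff engine and small U-shaped networks (CPU-trainable), a
deterministic synthetic colon-scene renderer with complete ground truth
(albedo, shading, speculars, depth, poses), the specular preprocessing
pipeline, and depth evaluation metrics with median scaling plus the
specularity-surrounding smoothness score (SSM).

## Worked example

```r
library(endodepth)

# a synthetic colon-like sequence with full ground truth
scene <- scene_spec(resolution = 64L, n_frames = 60L, step = 0.12,
                    wobble = 0.25, rock = 0.02, light_falloff = 0.5,
                    texture_contrast = 2.5, fold_amp = 0.3, seed = 301L)
frames <- render_sequence(scene)
frames[[30]]
#> <endo_rendered #29: 64 x 64, depth [0.61, 5.62], 3.08% specular>

# train the full model (inpainting module + auto-masking) from scratch
cfg <- train_config(seed = 7L, lr = 3e-3, epochs = 40, max_steps = 2000,
                    bootstrap_steps = 1400, d_min = 0.25, d_max = 6)
model <- depth_fit(frames, cfg)
summary(model)
#> Self-supervised depth + light decomposition model
#>   preset: tiny   seed: 7   epochs trained: 35   steps: 2000
#>   inpainting module: TRUE   static auto-mask: TRUE
#>   depth range: [0.25, 6.00] scene units
#>   loss: 0.3973 (first) -> 0.0932 (last)

# decompose a frame and estimate its depth
inf <- predict(model, frames[[30]]$frame)
inf
#> <endo_inference: depth [0.36, 1.55], specular cover 2.15%>

# evaluate against the renderer's ground truth (median scaling resolves
# the monocular scale ambiguity)
gt <- frames[[30]]$gt$D$values
depth_metrics(median_scale(inf$D$values, gt), gt)
#> MAE 0.8767  MedAE 0.8252  RMSE 1.0565  RMSE_log 0.5825  Abs_Rel 0.6570  Sq_Rel 0.8630
#> delta<1.25 0.3535  delta<1.25^2 0.5823  delta<1.25^3 0.6672  (n=4096)

# depth smoothness across detected specular regions, no ground truth needed
regions <- segment_speculars(frames[[12]]$frame)
regions
#> <endo_specular_regions: 3 region(s), 6.37% of pixels>
ssm_metric(infer_frame(frames[[12]]$frame, model)$D$values, regions)
#> <endo_ssm: 100.0% smooth of 3 region(s), tau=0.10 margin=5>
```

The inference output is the full decomposition: `inf$A` (albedo), `inf$S`
(shading), `inf$D` (depth), `inf$AS` (specular-free reconstruction) and
`inf$M_binary` (the binarized specular mask). A short from-scratch toy run
like this recovers the scene's coarse depth ordering; per-frame error
metrics at this scale are noisy between runs and frames — the SSM line
shows what the method is for: depth that stays smooth across the specular
highlights that break plain photometric methods.

A command-line front end wrapping the same functions ships in
`inst/cli/endodepth`:

```sh
Rscript inst/cli/endodepth make-synthetic --out scene/ --resolution 128
Rscript inst/cli/endodepth train --data scene/ --out model.rds
Rscript inst/cli/endodepth infer --ckpt model.rds --in scene/ --out pred/
Rscript inst/cli/endodepth evaluate --pred pred/ --gt scene/ --out metrics.json
```

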