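---
title: "Uncertainty-guided hybrid segmentation: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-guided hybrid segmentation: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphereseg)
```

## The model

`sphereseg` turns any slice-wise 2D segmenter into an uncertainty-aware
hybrid 2D/3D pipeline in three stages.

**Stage 1 — spherical-projection ensemble.** A 2D slice is draped onto a
sphere of radius $R$ tangent at a projection origin and unrolled
equidistantly: an output pixel at radial distance $\rho$ from the origin
samples the source at

$$s(\rho) = R \tan(\rho / R), \qquad \rho(s) = R \arctan(s / R),$$

along the same direction. The local radial scale $ds/d\rho = \sec^2(\rho/R)$
is 1 at the origin and strictly increasing, so the origin's neighborhood is
relatively magnified while the periphery is compressed but retained; the
map is undefined at $\rho \ge \pi R / 2$ (those pixels take the fill
value). Varying the origin over a uniform grid produces an ensemble of
deformed views of the same anatomy. Each view is segmented, the prediction
is pulled back through the inverse map, and per pixel we obtain a set of
probabilities. The mean (over valid pull-backs) is the global probability
$P_{2D}$, binarized at a strict $> 0.5$; the dispersion gives the
uncertainty

$$U = -\sum_{t=1}^{T} f(t)\, \ln f(t),$$

where $f(t)$ are the empirical frequencies of the ensemble's predictions
over 100 uniform bins on $[0,1]$ and $T$ counts the occupied bins. $U = 0$
at unanimity; $k$ equally-filled bins give $\ln k$, bounded by
$\ln 100 \approx 4.605$ nats.

Even a deterministic segmenter produces genuine ensemble variability here:
the deformation resamples the image at different scales per view, and
boundary pixels — where intensity gradients are steep — land in different
bins across views. That is precisely the signal the framework exploits:
entropy concentrates at ambiguous anatomical boundaries.

**Stage 2 — kernel localization.** The uncertainty volume is scanned with
a cubic $d \times d \times d$ window; each in-bounds corner's score is the
exact sum of enclosed voxel uncertainties, computed with a 3D summed-area
table so a dense (stride-1) scan is cheap. Candidates are accepted greedily
in descending score order; a candidate is rejected if its volumetric
overlap with *any* accepted kernel exceeds `max_overlap` (default 0.4 of
$d^3$), and the scan halts when the best remaining score drops below
`stop_fraction` (default 0.1) of the first accepted score. Ties are broken
by lexicographic corner order, making selection fully deterministic.

**Stage 3 — refinement and fusion.** Each selected kernel is cropped from
the 4-channel volume without resampling ($4 \times d \times d \times d$)
and segmented by a local 3D model. Overlapping local predictions are
averaged into a composite map $P_{3D}^{comp}$ with an integer coverage
count $N$ per voxel. The fused probability is

$$P_{fused} = \begin{cases} P_{2D} & N = 0\\
\sigma\!\left(w_{2D} P_{2D} + w_{3D} P_{3D}^{comp} + b\right) & N \ge 1,\end{cases}$$

with $\sigma$ the logistic function and $w_{2D}, w_{3D} \ge 0$. Voxels no
kernel covers keep their 2D probability bit-for-bit — no sigmoid is
applied there. The weights are found by global-best particle swarm
optimization (PSO) maximizing mean Dice over training cases.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| origin interval | 8 (full) / 16 (desk) | px | 8 px on a 256×256 slice gives the full 1024-view ensemble; 16 px on 64×64 test volumes gives 16 views per slice. Entropy and mean are ensemble-size agnostic properties. |
| sphere radius $R$ | 64 | px | places the $\pi R/2 \approx 100.5$ px horizon near a 256×256 slice's half-width: peripheral compression is visible but nondegenerate. |
| interpolation | bilinear, fill 0 | — | MR background is 0 after skull stripping; nearest-neighbor is available and preserves binary value sets. |
| entropy bins | 100 | — | uniform on $[0,1]$, last bin right-closed so 1.0 is counted. |
| kernel edge $d$ | 32 (ET/TC), 64 (WT) | voxels | power-of-two round-down of median tumor extents (~42–53 mm ET/TC, ~83 mm WT) at 1 mm isotropic, where mm ≡ voxels. |
| max overlap | 0.4 | fraction of $d^3$ | large overlaps produce redundant subvolumes; small ones under-cover; 40% balances the two. |
| stop fraction | 0.1 | relative | the stopping level for "remaining uncertainty is negligible" is stated only qualitatively in the source method; a relative rule is scale-free across uncertainty magnitudes. An absolute threshold (`stop_abs`) is available. |
| PSO | pop 20, 50 iter | — | inertia 0.72, cognitive = social = 1.49 (standard constriction-like values), velocity clamp 0.5× box width, search box $[0,5]^2$ (the logistic saturates far beyond). |
| binarization | strict > 0.5 | — | a mean of exactly 0.5 maps to background. |

## Numerical and design choices

- **The deformation law is a documented strategy, not a fidelity claim.**
  The qualitative requirements — invertibility, origin magnification,
  preserved field of view — admit several radial laws; this package fixes
  the gnomonic $s = R\tan(\rho/R)$ with equidistant unrolling because it is
  closed-form invertible and satisfies all three. `projection_params()`
  exposes $R$, interpolation order, fill, and output size.
- **Entropy uses only valid pull-backs.** Back-projection marks pixels
  whose pull-back lands in-domain; pixels with no valid prediction get
  entropy 0 and a flag rather than a silent number. Predictions are
  back-projected *before* averaging and binning — the only geometrically
  consistent frame for combining views.
- **The bias $b$.** Optimizing only $(w_{2D}, w_{3D})$ with non-negative
  weights inside a logistic would bias every fused probability above 0.5;
  the default policy therefore centers the rule, $b = -(w_{2D}+w_{3D})/2$,
  so two 0.5 inputs fuse to 0.5. Alternatively `b_policy = "optimize"`
  adds $b$ as a third PSO dimension, or a fixed numeric can be given.
- **No feathering.** Local predictions are averaged plainly at kernel
  borders; no distance weighting is applied, keeping the composite an
  order-invariant arithmetic mean.
- **Degenerate inputs.** An all-zero uncertainty map selects no kernels
  and the refinement stage is a graceful no-op ($P_{fused} = P_{2D}$).
  A slice whose brain-ROI contains no origin falls back to the full origin
  grid with a warning. Objective evaluations returning NaN inside the PSO
  are treated as $-\infty$ with a warning rather than propagating.
- **HD95 convention.** Surfaces are 6-connectivity boundary voxels; the
  reported value is the maximum of the two directed 95th-percentile
  nearest-surface distances (spacing-aware, mm), the most common
  convention in medical-segmentation tooling. Empty masks give a flagged
  undefined value, never a silent 0. Dice of two empty masks is 1 by
  convention, flagged.
- **Wilcoxon protocol.** Zero differences are excluded; the exact null
  distribution is used for $n \le 25$ untied pairs, the normal
  approximation with continuity correction otherwise. Significance is
  declared at $\alpha / \text{comparisons}$ (0.05/2 = 0.025 for the
  two-baseline design).

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a 4-channel volume with nested ellipsoidal
tumor subregions — enhancing tumor (ET) inside necrotic/non-enhancing core
(NCR/NET) inside peritumoral edema (ED) inside an ellipsoidal brain — from
which the standard composite targets derive: ET, TC = ET ∪ NCR/NET,
WT = TC ∪ ED, nested by construction. Channel means follow a contrast
table whose defaults encode the qualitative contrasts the method relies
on: ET hyperintense on T1ce (0.9 vs ≤ 0.45 for everything else), edema
hyperintense on FLAIR/T2 (0.8/0.75 vs 0.3 for normal brain); values are
conventions on a normalized scale, not claims about scanner intensity
distributions. Additive Gaussian noise (default σ = 0.05, ~1/5 of the
smallest relevant contrast step) and a seed complete the specification.

The phantom gives every pipeline stage a ground truth: exact ellipsoid
voxel counts, noiseless intensities equal to class means, deterministic
regeneration. What it does **not** have: textured heterogeneous cores,
infiltrative (non-ellipsoidal) margins, bias fields, partial-volume
effects, or inter-channel misregistration. Passing tests on phantoms
therefore demonstrates the *mechanics* of the framework — uncertainty
concentrates at boundaries, kernels land on them, fusion helps where the
local model is better — not clinical-grade accuracy on real gliomas, which
requires trained segmentation backbones and real data.

Default grids are desk-scale: 64×64×48 for pipeline tests (the full
256×256×160 BraTS geometry is supported), 32³ for fusion scenarios so a
full PSO budget (20 particles × 50 iterations) runs in seconds, and 16
projection origins per slice for ensemble runs. All tested properties are
size-agnostic.

## Constructed scenarios and what the weight ordering shows

`make_fusion_scenario()` builds cases where one source (2D or 3D) is a
noisy-but-informative transform of the reference and the other is weakly
informative, with the dominance direction known by construction. Running
the PSO on such a case must recover $w_{3D} > w_{2D}$ when the 3D source
carries the signal, and the mirror image otherwise;
`scenario_recovery_rate()` measures this over seeded repetitions. This is
a parameter-recovery *analogue* of the per-target weight orderings
observed on real cohorts (2D-dominant for heterogeneous compact targets,
3D-dominant for large diffuse ones) — it validates that the optimizer and
objective behave as intended, not that those real-data orderings are
reproduced here.

## Known limitations

- The entropy of a test-time ensemble is a surrogate for predictive
  uncertainty; it does not separate epistemic from aleatoric components.
- Kernel size, overlap and stopping thresholds are fixed hyperparameters,
  not adapted to the uncertainty distribution.
- The shipped backends are intensity thresholds and oracles; scientific
  use requires plugging trained 2D/3D segmenters into the
  `SlicePredictor`/`VolumePredictor` contract (any callable mapping a
  4-channel grid to a probability grid; `check_predictor_contract()`
  verifies shape, range and determinism).
- `run_case()` treats mm and voxels as equal; anisotropic inputs load with
  a warning but the kernel search does not rescale.

## A minimal run

```{r, eval = FALSE}
ph <- generate_phantom(phantom_spec(seed = 7, noise_sd = 0.2))
st <- run_uncertainty_stage(ph$volume,
                            mock_threshold_predictor(channel = 3, center = 0.65),
                            interval = 16, roi = ph$roi)
ref <- run_refinement_stage(ph$volume, st$u2d, st$p2d,
                            oracle_volume_predictor(ph$labels$ET),
                            selection_config(d = 32), fusion_weights(0.5, 6))
rbind(`2d_only` = segmentation_metrics(st$mask2d, ph$labels$ET),
      fused     = segmentation_metrics(ref$mask, ph$labels$ET))
```

The README shows this example with the numbers it prints.
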