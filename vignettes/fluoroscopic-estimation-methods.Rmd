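---
title: "Fluoroscopic 3D image estimation from 4D-CBCT motion models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluoroscopic 3D image estimation from 4D-CBCT motion models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During stereotactic body radiotherapy of thoracic tumors, the anatomy moves
with breathing while the treatment machine acquires only a single cone-beam
projection at a time. `fluorovol` estimates a *fluoroscopic 3D image
sequence* — one volumetric image per incoming projection — from two inputs
that are available on the treatment day itself: a respiratory-correlated
4D-CBCT acquired just before delivery, and the stream of single cone-beam
projections. A patient-specific linear motion model is derived from the
4D-CBCT, and each projection is then inverted for the few coefficients of
that model.

The method has two steps.

**Step 1 — motion model.** The raw projections are sorted into `n_bins = 6`
respiratory phase bins using a marker-free breathing trace (the Amsterdam
shroud), and each bin is reconstructed with short-scan FDK, giving a
4D-CBCT set of six phases. Every phase is registered deformably (Demons) to
the peak-exhale reference phase, producing displacement vector fields
(DVFs). Principal component analysis of the flattened DVFs yields the model

$$ D(u) = \bar{D} + \sum_{i=1}^{N} u_i\, v_i , $$

with the mean field $\bar D$, unit-norm eigenvector fields $v_i$ (sorted by
descending eigenvalue) and per-time coefficients $u_i(t)$. By default
$N = 3$ modes are retained; on both the digital phantom and in the
literature the spectrum collapses after 2–3 modes because quasi-periodic
breathing has very few latent degrees of freedom.

**Step 2 — per-projection optimisation.** For each measured projection $x$
the coefficients are found by minimising the ROI-restricted squared
$L_2$-norm

$$ J(u) \;=\; \bigl\| M \odot \bigl(P\, f(D(u), f_0) - \lambda x\bigr) \bigr\|^2 , $$

where $f_0$ is the reference phase, $f(D, f_0)$ its pull-back warp by
$D(u)$, $P$ the cone-beam forward projector at the frame's gantry angle,
$M$ a detector region of interest, and $\lambda$ a per-evaluation
closed-form intensity scale. The minimiser over $\lambda$ is
$\langle Pf, x\rangle_M / \langle x, x\rangle_M$; re-estimating it at every
cost evaluation makes $J$ invariant to the global intensity scale of $x$
(projections and reconstructions live on different scales), and by the
envelope theorem the gradient in $u$ at the optimal $\lambda$ equals the
partial gradient with $\lambda$ held fixed. The text form of the objective
is squared (the unsquared norm is not differentiable at a perfect fit);
minimisation is plain gradient descent with Armijo backtracking
(`c = 1e-4`, shrink 0.5), the first step calibrated from the first gradient
norm, warm-started across frames from the previous frame's solution.

The gradient is analytic end to end: the masked residual is back-projected
with the *exact adjoint* of the ray-driven projector (both directions share
one ray discretisation), multiplied by the exact spatial derivative of the
trilinear interpolant of $f_0$ at the displaced sample positions, and
contracted against each eigenvector field. Because every factor is the
true derivative of the discrete forward computation (not a continuous
approximation), the gradient matches central finite differences to the
finite-difference truncation error; the test suite checks a relative error
below $10^{-3}$ at random coefficient points.

## Conventions

* **Axes**: x = left–right, y = anterior–posterior, z = superior–inferior
  (SI). The isocenter is the world origin; volumes are centred on it by
  default. Gantry angle 0° puts the source on the anterior side; rotation
  is counter-clockwise viewed from superior. Detector coordinates are in
  mm with (0,0) at the principal point; the v axis is parallel to SI.
* **Displacement fields** are stored in the *pull-back* (reference-
  sampling) convention used by `warp_volume()`:
  `out(p) = vol(p + D(p))`. `demons_register()` is therefore called with
  `fixed = phase, moving = reference`, so each stored field deforms the
  reference *into* that phase — the single convention used by the model,
  the estimator and the warping operator alike. Whether one inverts
  phase-to-reference fields or registers reference-to-phase is not
  observable from outside; this package does the latter and records it in
  the DVF provenance.
* **Tumor positions** are obtained by mapping the reference tumor centroid
  through a field. Under pull-back warping the anatomy sitting at the
  reference centroid $c$ appears at the point $p$ solving $p + D(p) = c$;
  `tumor_position()` solves this by fixed-point iteration
  ($p \leftarrow c - D(p)$, a two-iteration contraction for breathing-scale
  fields). Using $c + D(c)$ instead would land on the wrong side of the
  trajectory by twice the displacement and would disagree with the centroid
  of the warped tumor mask — the test suite checks the fixed-point position
  against that independently computed centroid to half a voxel.

## The synthetic study conditions

Patient projections are not distributable, so the package ships a
deformable digital thorax: an elliptical body, two lungs whose inferior
boundary is a diaphragm dome, an optional spine, and a spherical tumor
(10 mm radius) in the right lung. Breathing is an analytic SI-dominant
displacement field `A_SI * s(t) * w(z) * b(p)`: `w(z)` is 1 at the
diaphragm apex, decays as a raised cosine to 0 at the lung apex, and fades
to zero toward the caudal volume edge; `b(p)` tapers the field smoothly to
zero at the body surface; AP and LR components are fixed fractions (0.3,
0.1) of the SI component. The surrogate signal is
`s(t) = ((1 - cos(2*pi*t/T))/2)^k` with `T = 4 s` and `k = 2` (the longer
end-exhale dwell of free breathing), 5 % cycle-to-cycle amplitude jitter,
and a baseline drift of 1 mm/min emulating intra-fraction baseline shifts —
deliberately outside the space a 6-phase model can represent exactly.
`A_SI = 10 mm` at the diaphragm is a typical free-breathing excursion;
none of these values are fitted to any patient.

The default *desk preset* keeps the full chain within minutes on one CPU:
a 64³ volume at 4 mm, a 96² detector at 4 mm pitch, and 330 frames over a
200° arc at 5.5 fps (one minute of breathing, ≈ 55 views per phase bin).
The clinical-scale raster (e.g. 176 × 228 × 256 at 1.1 mm, 512²
projections, 1320 frames over four minutes) is reachable through the same
configuration objects; nothing in the code is specialised to the preset.

What the phantom does **not** emulate: hysteresis (inhale/exhale path
asymmetry), cardiac motion, scatter, beam hardening, detector lag, gantry
flex, and anatomy beyond the five-tissue model. Passing the end-to-end
tests therefore demonstrates the correctness and stability of the
*algorithmic chain* under known ground truth — not clinical accuracy on
patients, whose 4D-CBCT quality (streaks from ~200 views/bin at 512²,
residual sorting errors) and breathing irregularity are harsher than the
desk preset.

## Numerical choices

* **Projector**: ray-driven line integrals with trilinear interpolation at
  a fixed step of half the smallest voxel spacing; samples outside the
  voxel-centre hull contribute zero. The adjoint scatters the identical
  weights, so the dot-product identity holds to rounding — the optimisation
  gradient is exact *by construction*, not by approximation. A fused
  variant evaluates only ROI pixels during optimisation.
* **FDK**: cosine pre-weighting, Parker weighting for the 200° short scan
  (without it, rays in the redundant wedge are double-counted), sampled
  ramp kernel applied by zero-padded FFT along the lateral axis (optional
  Hann apodisation), voxel-driven backprojection with the 1/U² factor.
  Phase-binned subsets are non-uniform in angle; each view carries its
  local angular share as quadrature weight. The pipeline reconstructs the
  phase bins with Hann apodisation by default: at ~55 views per bin the
  Ram-Lak streaks are sharp enough to perturb both registration and the
  per-frame projection fit, and trading resolution for artifact
  suppression measurably stabilises tumor tracking. On a ball phantom the absolute
  reconstructed attenuation comes back within a few percent, though the
  estimator never relies on absolute scale ($\lambda$ absorbs it).
* **Demons**: symmetric (ESM-style) forces — the mean of the fixed and
  warped-moving gradients — with the classical
  $\delta = \mathrm{diff}\,g / (|g|^2 + \mathrm{diff}^2/\kappa^2)$
  normalisation ($\kappa$ = mean spacing), Gaussian smoothing of each
  update (σ = 8 mm ≈ 2 voxels of the default grids) and of the accumulated
  field (σ = 4 mm ≈ 1 voxel), three pyramid levels (4×/2×/1×) with
  50/30/20 iterations. The one-sided Thirion force with sub-voxel smoothing
  oscillates on coarse grids; the symmetric force plus ≈2-voxel update
  smoothing is the standard stable regime, and the smoothing lengths should
  be scaled with voxel size when registering finer data. Demons is
  intensity-driven: inside homogeneous tissue it interpolates rather than
  measures (the aperture problem), so endpoint-error statements are made on
  textured volumes, and on the phantom the model is accurate near the
  high-contrast structures that drive the fit.
* **PCA**: eigen-decomposition of the n × n Gram matrix of the centred
  flattened DVFs (n = 6 samples; equivalent to the SVD), unweighted inner
  product, eigenvalues as sample variances (divisor n − 1). The reference
  phase's zero field *is* included as a training sample, anchoring the
  model at the reference state. Rank-deficient requests are truncated to
  the positive-variance modes. Mode signs are fixed so each eigenvector's
  largest-magnitude SI entry is positive, making outputs reproducible.
* **ROI**: a rectangle covering the projected reference tumor centroid and
  diaphragm apex with a 30 mm margin at isocenter scale, recomputed per
  gantry angle. The margin was chosen on the phantom by inspecting
  tracking stability: concentrating the data term on the high-contrast
  moving structures is *more* accurate than fitting the whole detector,
  because wider regions are dominated by reconstruction streaks and by the
  parts of the mode shapes that registration estimates worst — the same
  rationale the ROI has on patient data.
* **Optimisation stops** at relative cost change < 1e-4, at 50 iterations
  (with a warning), or when the cost falls below 1e-9 of the ROI energy of
  $\lambda x$ (a numerically perfect fit; without this floor a perfect-data
  fit halves the cost forever without ever "changing slowly").
* **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7), fixed here because the evaluation protocol
  pairs the MAE with a 95th percentile without prescribing a definition.

## Evaluation protocol

Tumor localisation error is reported *along SI, in mm at isocenter*: the
estimated 3D centroid is perspective-projected onto the detector, compared
with the ground-truth detector coordinate, and the difference is scaled
down by SAD/SDD. On phantom runs the ground truth comes from the
simulator's per-frame tumor positions (the analogue of a clinical
contour); the diaphragm-apex detection plus diaphragm-to-tumor linear
regression path — the protocol needed when only projections are available —
is implemented and validated on the phantom as well, with SI-only
prediction as the default mode.

The desk-scale end-to-end run (the acceptance configuration) tracks the
tumor with an SI MAE well under one voxel (0.7-1.2 mm at 4 mm voxels over
different seeded breathing realizations, 95th percentile 2-3 mm) and a
correlation of 0.89-0.96 against the true trace — the spread comes from
the cycle-amplitude jitter draw, which shapes how evenly the gantry arc
populates the six phase bins and hence the model quality. The
measured-vs-rendered projection correlation is around 0.97 throughout.
All numbers are printed by `scripts/acceptance.R`, which recomputes them
from scratch on every run. They characterise the pipeline under the
stated synthetic conditions; they are of the same order as, but not
comparable to, errors achievable on real patients.

## Known limitations

* Demons under-recovers motion amplitude in texture-poor regions; the
  fitted coefficients compensate near the ROI structures, but interior
  voxels of the fluoroscopic volumes inherit the model's smoothing bias
  (estimated trajectories come out ~15–20 % shallower than truth at the
  tumor before the projection fit corrects them frame by frame).
* A single projection constrains motion along the current view poorly in
  the source–detector direction; errors are therefore reported along SI,
  where the surrogate and the paper's protocol are meaningful.
* Baseline drift beyond the span of the six training states is only
  partially recoverable by construction; the residual appears as a slow
  error component in long sequences.
* No temporal regularisation across frames (deliberately out of scope);
  the warm start is the only coupling.

## Interfaces

All stages are exported R functions operating on plain containers
(`volume3d`, `projection_stack`, `dvf`, `pca_motion_model`). Volumes and
fields read/write NIfTI (`RNifti`); traces, assignments, coefficients and
reports are CSV/plain text. `run_pipeline()` executes the whole chain from
a single `run_config()` and freezes the resolved configuration in the run
directory. A thin command-line wrapper (`inst/cli/fluorovol`) exposes
`run` and `phantom` subcommands; the remaining stages are used directly as
R functions.
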