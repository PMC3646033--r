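---
title: "Repeated deterministic streamline tractography: model, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeated deterministic streamline tractography: model, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrack)
```

## The method in brief

`retrack` segments a white-matter bundle from diffusion tensor data by
turning one deterministic reconstruction into many. A single two-ROI
tensor-deflection (TEND) tracking run gives an initial fiber mask; its
centerline is extracted; planar seed regions are generated along the
centerline (ray-cast contours of the initial mask, spline-smoothed,
optionally pushed outward); tracking is repeated from every region; and the
per-region binary masks are accumulated into a voxel visitation-count mask.
Thresholding the count mask at a fiber-bundle-membership (FBM) level yields
the segmentation: a voxel belongs to the FBM-X object when at least X% of
the repeated reconstructions visited it. Quality is scored against ground
truth with the Dice similarity coefficient (DSC).

The rationale: deterministic tractography estimates the bundle *core* well
but underestimates the *extent*, partly because partial-volume effects
depress anisotropy at the border and partly because clinical seed ROIs
(e.g. the cerebral peduncle for the corticospinal tract) are compact
landmarks that the bundle fans away from. Re-seeding along the bundle and
accumulating results recovers the rim while the FBM threshold controls how
much of the uncertain rim is admitted.

## Tracking model and parameters

Propagation integrates the direction field of the diffusion tensor
$D$ with Euler steps (RK4 available via `tracking_params(method = "rk4")`;
the two agree to fractions of a millimetre in smooth fields, and Euler
matches the implementations this method class was designed for):

$$v_{out} = \mathrm{normalize}\!\left(f e_1 + (1-f)\left[(1-g)v_{in} + g \hat D v_{in}\right]\right),
\qquad \hat D = D / \lambda_1 .$$

`tracking_params()` defaults, with units and reasons:

| parameter | default | unit | why |
|---|---|---|---|
| `step_mm` | 1.0 | mm | half a voxel at the 2 mm acquisition resolution |
| `fa_threshold` | 0.15 | – | standard white-matter stopping value |
| `max_angle_deg` | 45 | °/step | excludes implausible kinks, admits the arc curvature |
| `max_steps` | 600 | – | generous bound: 600 mm of track at 1 mm steps |
| `f`, `g` | 0, 1 | – | pure tensor deflection $v \propto D v$, the variant most widely deployed clinically |

The tensor is normalized by its largest eigenvalue before deflection so that
step geometry is independent of the diffusivity scale. Tracking runs in both
directions from each seed (initial directions $\pm e_1$) and the half-tracks
are concatenated with the seed appearing once; stopping tests (volume exit,
FA, angle) are applied to the *candidate* point before it is appended, so
streamlines end in supra-threshold tissue rather than one step beyond it.
Tensors are interpolated component-wise (trilinear); interpolating
coefficients rather than eigenvectors avoids sign-flip artifacts.

## Centerline and seed regions

Streamlines are orientation-aligned (flipped when their endpoints match the
reversed reference — the longest streamline — better), arc-length resampled
to `n_centerline` points and averaged point-wise. `n_centerline = 129`
because every seed-region count used in the factorial design
(2, 3, 5, 9, 17, 33, 65, 129, all of the form $2^k+1$) is then an exact
equally spaced subset including both endpoints.

At each selected centerline point a plane perpendicular to the local
direction (two consecutive centerline points; the final point reuses the
preceding segment) is cut. 36 rays at 10° spacing, sampled every 0.5 mm up
to 30 mm, find the first point outside the initial fiber mask; a closed
periodic cubic spline through the 36 contour points (128 dense samples)
gives the region outline. Scaling moves every contour point outward along
its ray by the SCALING offset in millimetres. Seeds are a 1 mm in-plane
grid clipped to the outline (point-in-polygon), plus the plane origin —
1 mm is half the acquisition voxel, balancing coverage against cost. When
averaging pulls a centerline point just outside the rasterized mask, the
contour origin is re-anchored on the nearest in-mask voxel center within
two voxels; if none exists the region degenerates to the single origin
seed.

Repeated-tracking results are filtered with the initial seed and include
ROIs as *alternative* include regions (a streamline is kept when it reaches
either), not as a conjunction: requiring both would discard exactly the
near-border and fanning fibers the method exists to recover. The initial
two-ROI result does not enter the count mask; the count denominator is the
number of generated seed regions, which is what the FBM percentage refers
to. The FBM threshold is $\lceil \mathrm{FBM}/100 \cdot n\rceil$ with ties
kept ("X% or more").

## The synthetic phantom

The generator (`phantom_config()`, `make_phantom()`) emulates the situation
the method targets rather than any specific anatomy: a tube swept along a
quarter-circle arc (the bend of a corticospinal-tract-like bundle) inside an
isotropic background, on a 64³ grid of 2 mm voxels.

Defaults and rationale:

* **arc radius 30 mm, tube radius 6 mm** — a large bundle whose curvature is
  mild relative to the 45° angle criterion;
* **taper 0.5** — the tube narrows linearly to half its radius toward the
  seed end, and the seed ROI is the narrow one-voxel-thick end-cap (the
  include ROI is the wide end-cap). This models a bundle fanning out from a
  compact landmark, which is precisely why end-cap-seeded two-ROI tracking
  underestimates extent: streamlines stay at their radial offset, so only
  the core reachable from the narrow cap is reconstructed. Without the taper
  (set `taper = 1`) the phantom is a symmetric tube, used in the tests for
  symmetry and analytic-volume checks;
* **bundle eigenvalues (1.7, 0.3, 0.3)·10⁻³ mm²/s** — a strongly prolate
  white-matter-like tensor, FA ≈ 0.80;
* **background diffusivity 2.0·10⁻³ mm²/s** — an isotropic fluid-like
  embedding, giving a clear anisotropy gradient at the border;
* **partial-volume shell** — voxels within one voxel of the tube surface, on
  both sides, get a linear blend of bundle and background tensors. This
  reproduces the FA drop at the *true* border: the outermost ground-truth
  voxels are the hardest to track, as in real data;
* **signals** — $S_k = S_0 e^{-b g_k^\top D g_k}$, $S_0 = 1000$, one shell at
  $b = 1000\,\mathrm{s/mm^2}$ with 30 directions from a fixed golden-spiral
  hemisphere table shipped as a text fixture (bit-reproducible; the fit's
  normal-equation matrix has condition number ≈ 2.3);
* **noise** — complex Gaussian (Rician magnitude), per-channel σ chosen as
  mean noise-free $b_0$ over the bundle divided by the target SNR: levels
  1 and 2 target SNR 65 and 32, the quality range of clinical 3 T DTI. The
  estimator is deliberately simple since only the level matters here.

Ground truth is the set of voxel centers inside the (capped) tube. What the
phantom does **not** model: crossing or kissing fibers, anatomical
background structure, eddy-current/motion artifacts, field inhomogeneity.
Passing tests on it therefore demonstrate the mechanics of the method —
re-seeding recovers extent lost to narrow seeding and border noise, FBM
trades core against rim — not performance on clinical data, where
crossing-fiber geometry is the dominant unmodelled difficulty.

## Evaluation design

`build_parameter_grid()` enumerates the full factorial design
NOISE {0,1,2} × SEEDS {2,3,5,9,17,33,65,129} × SCALING {0..5} mm ×
FBM {10..100}% — 1440 cells, 480 per noise level, 144 per FBM level.
`run_sweep()` tracks once per (noise, seeds, scaling) triple and re-uses the
count mask across its ten FBM rows. `group_summary()` reports mean, sample
standard deviation (n−1 denominator), minimum and maximum DSC in percent per
group. Inferential statistics are intentionally out of scope; the sweep CSV
is designed for consumption by any statistics package.

The packaged evaluation (tests and `scripts/acceptance.R`) runs a reduced
sweep — the full 64³ phantom at all three noise levels with SEEDS {5, 33},
SCALING {0, 2} and all ten FBM levels — which exercises every pipeline stage
in well under a minute per noise level on one CPU; these problem sizes are
the package's chosen test conditions. The checks are directional: repeated
tracking over the preferred band (SCALING 1–5 mm, SEEDS > 2, FBM 30–50%)
must beat the two-ROI baseline at every noise level, the SCALING 2 group
must not fall behind SCALING 0, and the band mean must be stable across
noise levels. Absolute DSC values are phantom-specific by nature.

## Numerical choices and degenerate inputs

* Tensor fit: ordinary least squares on $\log(S_k/S_0)$, one shared
  normal-equation solve for all voxels; weighted LLS (weights $S_k^2$)
  behind `weighted = TRUE`. Signals are floored at a small epsilon before
  the log; negative eigenvalues (noise) are clamped to zero and counted in
  `n_clamped`. Collinear gradient schemes are rejected.
* Eigenvector sign convention: nonnegative x component, ties broken on y
  then z; degenerate (isotropic) tensors are flagged but still return a unit
  vector.
* DSC of two empty masks is defined as 1, with a warning.
* Contour rays that never leave the mask are clamped at the 30 mm cap and
  flagged. A degenerate (near-zero) contour yields exactly one seed.
* Coincident consecutive centerline points fall back to the nearest distinct
  neighbors for the plane normal; an all-coincident centerline is an error.
* NIfTI support is axis-aligned only; oblique affines are rejected with a
  clear message rather than resampled. World coordinates are millimetres,
  voxel centers at `origin + (index − 0.5) · voxel_size` (1-based indices);
  the convention is recorded in every provenance JSON.
* All pipeline stages are deterministic given their inputs; the only random
  element is the phantom noise, controlled by `rng_seed` and isolated from
  the caller's RNG state.

## Known limitations

Single-tensor model only (no crossing-fiber handling, by design of the
method class); Euler default integration; per-region contours are convex-ish
star-shaped sets around the centerline (strongly branching bundles would
need a different region model); whole-volume baselines seed every
FA-suprathreshold voxel, which on small phantoms is affordable but scales
linearly with volume; probabilistic tractography is out of scope.
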