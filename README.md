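# retrack

Repeated deterministic streamline tractography for fiber-bundle
segmentation in diffusion tensor imaging (DTI).

## The problem

Deterministic streamline tractography — the workhorse of presurgical white
matter mapping — systematically **underestimates the spatial extent** of
large fiber bundles such as the corticospinal tract. Two effects conspire:
partial-volume averaging depresses fractional anisotropy (FA) at the bundle
border, so streamlines terminate early there, and the classical *two-ROI
approach* seeds only from a compact anatomical landmark (e.g. the cerebral
peduncle), so fibers that fan out away from the seed region are never
reconstructed at all. For neurosurgical planning this is the dangerous
direction of error: the tract is larger than its reconstruction.

`retrack` implements a re-seeding strategy that turns a single deterministic
reconstruction into a statistical one, without new data acquisition:

1. **Initial tracking** — tensor-deflection (TEND) streamlines from the seed
   ROI, kept if they reach the include ROI, rasterized to a binary fiber
   mask. TEND propagates a direction $v$ by
   $v_{out} \propto f\,e_1 + (1-f)\bigl((1-g)\,v_{in} + g\,\hat D\,v_{in}\bigr)$
   with $\hat D = D/\lambda_1$ (defaults $f=0$, $g=1$).
2. **Centerline** — each streamline is arc-length resampled to $n$ points
   (129 by default) and averaged point-wise.
3. **Seed-region generation** — at SEEDS equally spaced centerline points, a
   plane perpendicular to the local direction is cut; rays cast in the plane
   find the fiber-mask outline, a periodic cubic spline smooths it, and the
   contour is pushed outward by SCALING millimetres.
4. **Repeated tracking** — every generated region is tracked, with the
   initial seed and include ROIs as *alternative* (ANY) include regions; each
   result becomes a binary mask.
5. **Count mask and FBM** — the per-region masks are summed into a
   visitation-count mask (values $0..n$). Thresholding at a
   fiber-bundle-membership level keeps voxels covered by at least FBM % of
   the reconstructions:
   $\mathrm{mask}_{FBM} = \{x : \mathrm{count}(x) \ge \lceil \mathrm{FBM}/100 \cdot n\rceil\}$.

Segmentation quality against ground truth is measured with the Dice
similarity coefficient, $DSC = 2|A \cap B| / (|A| + |B|)$.

The package also ships a ground-truthed synthetic DWI phantom (a curved,
tapering fiber bundle with Stejskal–Tanner signals,
$S_k = S_0 e^{-b\,g_k^\top D g_k}$, degraded by complex Gaussian noise at
SNR ≈ 65 or ≈ 32), a log-linear least-squares tensor fit, the full factorial
parameter sweep NOISE × SEEDS × SCALING × FBM (3·8·6·10 = 1440 cells) with
descriptive group statistics, and NIfTI / FSL bval-bvec / TrackVis TRK I/O.

## Worked example

```r
library(retrack)

cfg <- phantom_config(noise_level = 1, rng_seed = 7)   # SNR ~ 65
ph  <- make_phantom(cfg)
field <- fit_tensor_loglinear(ph$dwi)

baseline <- run_two_roi(field, ph$truth$seed_roi, ph$truth$include_roi)
res <- run_repeated_tracking(field, ph$truth$seed_roi, ph$truth$include_roi,
                             seed_plan(n_seeds = 33, scaling_mm = 2))

cat(sprintf("two-ROI baseline DSC: %.1f%%\n",
            100 * dice(baseline$mask, ph$truth$bundle_mask)))
for (f in c(30, 40, 50))
  cat(sprintf("repeated tracking, FBM %d%%: DSC %.1f%%\n", f,
              100 * dice(fbm_threshold(res$count_mask, f), ph$truth$bundle_mask)))
```

Output:

```
two-ROI baseline DSC: 70.9%
repeated tracking, FBM 30%: DSC 79.6%
repeated tracking, FBM 40%: DSC 81.6%
repeated tracking, FBM 50%: DSC 83.4%
```

The two-ROI reconstruction misses the outer part of the tapering bundle;
re-seeding along the centerline with a 2 mm outward contour offset recovers
it, and mid-range FBM levels (30–50 %) give the best trade-off between the
bundle core (always covered) and its uncertain rim.

A command-line interface wraps the same pipeline
(`exec/retrack phantom | fit | track | repeat | sweep | eval`); every run
writes a provenance JSON with the full parameter set.

## Vignette

`vignettes/repeated-tractography.Rmd` documents the model, the phantom
design and its rationale, all tunable parameters with units and defaults,
numerical choices, and known limitations.
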