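---
title: "Interactive refinement of automated liver-cyst segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactive refinement of automated liver-cyst segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisseg)
```

## The problem

In polycystic liver disease (commonly accompanying autosomal dominant
polycystic kidney disease), total liver cyst volume is a clinical biomarker,
but livers can carry hundreds of cysts. Cysts are fluid-filled and therefore
bright on T2-weighted MRI — and so are hepatic vessels and bile ducts. On
the thick axial slices of breath-hold acquisitions, a vessel's in-plane
cross-section is a bright disk that is geometrically indistinguishable from
a small cyst, so any intensity-driven automated method includes vessels in
its cyst mask. Manual delineation is accurate but takes tens of minutes per
liver; fully automated segmentation is fast but over-segments.

`irisseg` implements the middle road: an automated two-phase level-set
segmentation restricted to a liver region of interest (ROI), followed by a
small number of single-click edits — intensity-affinity region growth to
add a missed lesion or remove an included vessel — replayed
deterministically from a session script. A synthetic phantom generator with
exact ground truth makes the whole pipeline testable end to end.

All grids use the axis order (slice, row, col) with 1-based indices — the
native indexing convention of R — and spacing in mm per axis in the same
order. Coordinates in JSON session scripts follow the same convention.

## Automated stage: two-phase piecewise-constant level set

Within the liver ROI each axial slice is partitioned into two phases by
minimizing the classical two-phase piecewise-constant (Chan–Vese) energy

$$E(C, c_1, c_2) \;=\; \mu\,\mathrm{Per}(C)
  \;+\; \lambda_1 \sum_{v \in C} (I_v - c_1)^2
  \;+\; \lambda_2 \sum_{v \in \Omega \setminus C} (I_v - c_2)^2,$$

where $\Omega$ is the ROI restricted to the slice, $C$ the inside region,
$c_1, c_2$ the phase means, and $\mathrm{Per}$ the 4-neighbor boundary
length. Intensities are min–max normalized to $[0,1]$ beforehand
(`normalize_minmax()`; by default over the whole volume, optionally over
the ROI only). The evolution is initialized with a small square
(`2*init_patch + 1` per side) centered on the ROI voxel of minimum
intensity on that slice, ties broken lexicographically by (row, col). The
phase with the higher mean is reported as foreground, because the lesions
of interest are T2-hyperintense; the output is always a subset of the ROI.

### The discrete minimizer

Rather than evolving a continuous level-set function with an explicit PDE
scheme, the energy is minimized directly over binary configurations in two
stages:

1. **Unregularized assignment.** Ignoring $\mu$, the energy is separable:
   alternating the exact updates "means given partition" and "pointwise
   best phase given means" is a Lloyd iteration that weakly decreases the
   fidelity energy and converges in a handful of sweeps.
2. **Length-regularized flips.** With the full energy, single-voxel flips
   are applied on a checkerboard schedule. Voxels of one parity are never
   4-adjacent, so simultaneously flipping every parity-`p` voxel whose flip
   strictly decreases the energy changes the total energy by the sum of the
   individual (negative) contributions. Phase means are refreshed between
   iterations, which also cannot increase the energy.

Consequences that the continuous schemes do not offer: the result is
exactly deterministic, exact on noiseless two-constant images, and the
recorded energy trace is non-increasing by construction (the test suite
asserts this to a 1e-6 relative tolerance, which in practice is slack — the
decrease is exact up to floating-point addition order).

Stopping: the regularized stage stops when the relative energy change
falls below `tolerance` (default 1e-3), when no flip is possible, or at
`max_iterations` (default 200, counting both stages; typical phantom
slices converge in well under 10).

### Parameter choices

* `mu = 0.05`. The flip criterion makes the role of $\mu$ transparent: an
  isolated misclassified voxel is removed when $4\mu$ exceeds its fidelity
  preference, while a single-voxel protrusion attached by one edge is
  eroded when $2\mu$ exceeds the squared lesion contrast. With lesion
  contrasts of 0.3–0.6 in normalized units and noise-level fidelity
  differences of order 0.01, any $\mu$ in roughly $(0.01, 0.08)$ removes
  speckle without nibbling lesion boundaries; 0.05 sits in the middle.
* `lambda1 = lambda2 = 1`: no asymmetry between phases is wanted.
* `min_contrast = 0.1`. A two-phase split always *exists*, even on a slice
  containing nothing but noise and a smooth bias field, where the best
  split separates the phase means by roughly $1.6\sigma \approx 0.05$.
  A slice whose optimal split separates the means by less than
  `min_contrast` is therefore declared to have no separable phases and
  reports no foreground — the conservative generalization of the
  constant-slice rule (no cysts claimed without contrast). Real fluid
  lesions sit at contrasts of 0.3 and above, far from the guard.
* Degenerate cases: an empty ROI slice, a collapse of one phase to the
  empty set, or a sub-threshold contrast all yield an empty slice result
  rather than an error, so pipelines over phantom stacks do not abort.

A per-slice 2D evolution (not a coupled 3D one) matches thick-slice
clinical acquisitions, where in-plane resolution is several times finer
than the slice spacing; one level set serves the whole slice.

## Interactive stage: affinity region growth

A click at seed voxel $s$ grows a region by breadth-first expansion: a
frontier voxel $g$ adjacent to an accepted voxel $s'$ is accepted when the
intensity affinity

$$\rho_{g,s'} = 1 - \frac{\lvert I_g - I_{s'} \rvert}{a} \;\ge\; t,$$

with adjustable sensitivity $a$ (default 0.2 in normalized units) and
threshold $t$ (default 0.5, the boundary case accepted); growth stops when
no frontier voxel reaches the threshold. Equivalently, a step is allowed
when the intensity difference is at most $a(1-t)$ — $a/2$ at the default
threshold.

Two comparison modes are provided because the growth rule can reasonably
be read either way; the package defaults to `chain`:

* `chain` (default): each candidate is compared to the accepted neighbor
  it grows from. The accepted set is the least fixed point of the step
  relation, so it is invariant to frontier ordering (BFS and DFS agree; the
  implementation expands whole frontiers at once and the tests check
  order-invariance against queue- and stack-based oracles).
* `seed`: every candidate is compared to the originally clicked voxel; the
  region is then the connected component of the thresholded-difference set
  containing the seed.

`smart_click()` grows over the volume, applies an in-plane morphological
closing (disk radius `closing_radius`, default 1) to the grown region to
fill interior holes caused by intensity heterogeneity, and unions the
result with the current mask — it can only add. `anti_smart_click()` grows
the same way but restricted to voxels currently in the mask, and erases
the grown region — it can only remove. No closing is applied on removal:
closing exists to fill holes within a grown lesion, and closing a removal
would refill the erased hole. A removal click outside the mask is a warning
no-op. Growth is restricted to the clicked slice by default (`scope =
"2d"`, matching slice-wise editing); `scope = "3d"` additionally crosses
face-adjacent slices, which is what the scripted vessel cleanup uses so one
click follows a tube through the stack. In-plane connectivity defaults to
4-neighbor — deliberately conservative, so growth cannot jump the diagonal
gaps between neighboring cysts.

The closing is computed exactly: each slice is padded by the disk radius
before dilation, so dilation is never clipped and
erosion-after-dilation equals closing on the unbounded plane. This makes
the operation extensive (output ⊇ input) and idempotent including at array
borders, properties the tests verify against a brute-force morphology
oracle.

Edits are never applied interactively: an `edit_session` (an ordered list
of `click_event`s plus a base configuration, serializable to JSON) is
replayed by `replay_session()`, which applies events strictly in order and
records per-event voxel-count deltas. Determinism of the replay — identical
inputs give bit-identical masks — stands in for a graphical interface and
makes edit histories auditable and reproducible.

## Agreement metrics

For candidate and reference masks/volumes the package reports the standard
method-comparison suite, with these conventions:

* **Dice** $2|A \cap B| / (|A| + |B|)$; two empty masks score 1 (perfect
  agreement on absence) with a warning.
* **Normalized volume error** $|V_\mathrm{ref} - V_\mathrm{cand}| /
  V_\mathrm{ref}$.
* **ICC**: computed from the two-way ANOVA mean squares of the
  case-by-method table. The default form is ICC(2,1) — two-way random
  effects, single measure, *absolute agreement* — the standard choice for
  method comparison of volumes, since a systematic offset between methods
  should lower agreement. The consistency form (offset-invariant) is
  available as an option; the report records which form was used. Note the
  ICC of a cohort depends on the between-case volume spread: cohorts of
  same-specification phantoms have deliberately similar total volumes, so
  a method with a systematic offset (the automated stage, which adds the
  vessel volume) can score a low ICC even when errors are consistent.
* **RMSE** over paired volumes, in mL.
* **Bland–Altman (percent)**: per-case difference normalized by the
  per-case mean of the two measurements, $100 (V_\mathrm{cand} -
  V_\mathrm{ref}) / \bar V$; bias is the mean of these and the limits of
  agreement are bias ± 1.96·STD. Normalizing by the pairwise mean is the
  standard percent-difference construction; normalizing by the reference
  instead would change the numbers by a factor $\bar V / V_\mathrm{ref}$
  per case.
* **SNR / CNR**: cyst ROI mean over its standard deviation, and
  cyst-minus-liver mean difference over the cyst standard deviation.
* **STD convention**: the sample (n−1) standard deviation everywhere —
  cohort summaries, Bland–Altman, SNR/CNR.
* Cohort tables report Mean / Median / [Min, Max] / STD rows, and the
  benchmark accompanies them with paired two-sided t-tests on the per-case
  Dice and volume-error values of the two methods.

## The phantom generator

`generate_phantom()` emulates exactly the features that make the clinical
problem hard, with exact ground truth:

* **Liver ROI**: an ellipsoid (the ROI is an *input* in the clinical
  pipeline, produced upstream; here it is synthesized).
* **Cysts**: spheres in voxel units, radii uniform in 2–8, intensities
  uniform in 0.7–1.0 per cyst, placed by rejection sampling fully inside
  the ROI with a minimum surface-to-surface separation (default 2 voxels) —
  preserving the inter-cyst gaps that both manual raters and automated
  methods handle inconsistently.
* **Vessels**: bright tubes (intensity 0.85) of in-plane radius 3 drifting
  gently across all slices, so that per-slice segmentation sees a
  cyst-like disk on every slice. Vessels are carved to keep at least one
  voxel of parenchyma between themselves and any cyst, so a removal click
  can never chain from a vessel into a cyst. The default vessel load
  (6 tubes) is calibrated so that the automated stage's normalized volume
  error lands in the several-tens-of-percent regime reported for clinical
  T2 liver imaging, giving the interactive stage something realistic to
  correct.
* **Bias field**: a fixed low-order polynomial (linear + bilinear +
  quadratic terms) of amplitude 0.05, emulating coil shading.
* **Noise**: additive Gaussian, default sigma 0.03. Real magnitude MR
  noise is Rician; at the SNR levels of interest the Gaussian
  approximation is adequate for testing segmentation logic, and the
  deviation is deliberate.
* **Geometry**: 64×96×96 grid at (8, 1.5, 1.5) mm — thick axial slices,
  mirroring breath-hold acquisitions and exercising anisotropic volume
  computation.

Everything is reproducible: the spec carries the RNG seed, and identical
(spec, seed) pairs give bit-identical phantoms.

What the phantom does *not* model — and hence what passing tests do not
show about clinical data: partial-volume voxels at lesion borders (masks
are binary by construction), Rician noise statistics, motion and
misregistration between breath-holds, bile ducts, irregular (non-spherical)
cysts, and true inter-observer variability in the reference standard.
Phantom results demonstrate the correctness of the machinery, not clinical
accuracy.

`scripted_cleanup_session()` plays the operator: one `smart_remove` per
connected vessel component present in the automated mask (seeded at the
component centroid snapped to the nearest member voxel) and one
`smart_add` per ground-truth cyst component entirely missing from it, all
with 3D scope. On default phantoms the automated stage reliably captures
every cyst, so sessions are typically removal-only.

## Problem sizes and runtime

The test suite and the acceptance script are sized to run on a single CPU
in a few minutes: oracle-equivalence sweeps use 100 random 32×32 images,
inverse-edit checks 50 random small blob volumes, the correctness limit
disks of radius 3–15, and the cohort benchmark 10 default-sized phantoms
(a full phantom takes ~1 s to generate, ~1 s to segment, and a few seconds
to clean up and score). These sizes are the package's own choices and scale
linearly if larger studies are wanted.

## Known limitations

* The two-stage minimizer finds a local minimum of the discrete energy;
  like all local level-set schemes its basin depends on the
  initialization. The lowest-intensity initialization plus the assignment
  stage makes it behave like a spatially regularized two-means split,
  which is the intended clinical behavior, but adversarial intensity
  profiles can produce other local minima.
* One level set per slice: two phases only. Lesions darker than parenchyma
  or multi-class problems are out of scope.
* `anti_smart_click` after `smart_click` at the same seed is an exact
  inverse when the click added a region disjoint from the prior mask
  (e.g. on an empty mask). If the grown region touches pre-existing mask
  content, the removal can extend into it — the removal is restricted to
  the current mask but not to the voxels the click added.
* Volumes must already share one grid; no resampling or registration is
  performed, and DICOM series are not read (convert to NIfTI upstream).
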