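# irisseg

Semi-automated segmentation of T2-hyperintense liver cysts, for researchers
measuring hepatic cyst burden in polycystic liver/kidney disease and for
anyone who needs a tested, scriptable implementation of
click-to-edit lesion segmentation.

## The problem and the method

Polycystic livers carry up to hundreds of fluid-bright cysts on
T2-weighted MRI. Total cyst volume is the clinical endpoint, but manual
delineation takes tens of minutes per liver, while automated
intensity-based segmentation systematically includes hepatic vessels and
bile ducts — on thick axial slices a bright tube's cross-section looks
exactly like a small cyst. `irisseg` implements the two-stage workflow
that resolves this:

1. **Automated stage.** Per axial slice, inside a liver region of interest
   (ROI), the two-phase piecewise-constant (Chan–Vese) energy

   *E* = μ · Per(*C*) + λ₁ Σ_in (*I* − *c*₁)² + λ₂ Σ_out (*I* − *c*₂)²

   is minimized over binary configurations by a deterministic two-stage
   discrete scheme (unregularized mean/assignment alternation, then
   length-regularized checkerboard flips), initialized at a small square on
   the slice's lowest-intensity ROI voxel. The brighter phase is the cyst
   candidate mask.
2. **Interactive stage.** Single-click edits, replayed deterministically
   from a JSON session script: growth from a clicked seed accepts a
   neighbor voxel *g* of an accepted voxel *s* while the intensity affinity
   ρ = 1 − |*I_g* − *I_s*| / *a* stays at or above a threshold (default
   0.5); `smart_click` adds the grown region (after an in-plane
   morphological closing that fills interior holes), `anti_smart_click`
   erases the affinity-connected region inside the current mask — one
   click removes a whole vessel — and a paintbrush handles the rest.

The package also provides the full method-comparison metric suite (Dice,
normalized volume error, ICC(2,1), RMSE, Bland–Altman limits of agreement,
SNR/CNR, cohort summary tables with paired t-tests) and a synthetic
phantom generator with exact ground truth that reproduces the clinical
failure modes (bright tubular vessels, inter-cyst gaps, bias field,
noise). Conventions: arrays are (slice, row, col) with 1-based indices;
NIfTI-1 for all volumes and masks; spacing in mm.

## Worked example

Generate a default phantom (64×96×96, thick 8 mm slices, 25 cysts,
6 confounding vessels), segment it, script the cleanup an operator would
click, and score both masks against ground truth:

```r
library(irisseg)

ph   <- generate_phantom(phantom_spec(seed = 7))
vol  <- normalize_minmax(ph$volume)
ls   <- chan_vese_segment(vol, ph$liver_roi)
sess <- scripted_cleanup_session(ls, ph$vessel_mask, ph$cyst_mask)
iris <- replay_session(vol, ls, sess)

print(sess)
cat(sprintf("Dice vs ground truth:  LS %.3f  ->  IRIS %.3f\n",
            dice(ls, ph$cyst_mask), dice(iris, ph$cyst_mask)))
cat(sprintf("Volume (mL):  GT %.1f   LS %.1f   IRIS %.1f\n",
            volume_ml(ph$cyst_mask), volume_ml(ls), volume_ml(iris)))
```

```
<edit_session> 6 event(s)
   1. smart_remove at (42, 64, 27) [scope=3d]
   2. smart_remove at (35, 27, 31) [scope=3d]
   3. smart_remove at (15, 59, 31) [scope=3d]
   4. smart_remove at (32, 68, 39) [scope=3d]
   5. smart_remove at (32, 43, 44) [scope=3d]
   6. smart_remove at (34, 67, 68) [scope=3d]
Dice vs ground truth:  LS 0.805  ->  IRIS 0.999
Volume (mL):  GT 225.8   LS 334.4   IRIS 225.6
```

The automated mask (LS) contains all 25 cysts *and* the 6 vessels — a
48% volume overestimate. Six removal clicks (one per vessel, each growing
through the stack with 3D scope) bring the volume error below 0.1% and the
Dice overlap to 0.999.

The same pipeline is available from a shell via the wrapper in
`inst/cli/iris.R`:

```sh
Rscript inst/cli/iris.R phantom  --out-dir ph --seed 7
Rscript inst/cli/iris.R segment  --volume ph/volume.nii.gz --roi ph/liver_roi.nii.gz --out ls.nii.gz
Rscript inst/cli/iris.R edit     --volume ph/volume.nii.gz --mask ls.nii.gz --session edits.json --out iris.nii.gz
Rscript inst/cli/iris.R eval     --ref ph/cyst_gt.nii.gz --cand iris.nii.gz
Rscript inst/cli/iris.R benchmark --seeds 1,2,3,4,5 --out-dir reports
```

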