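# retmodal

Multimodal quantification of **hyper-reflective foci (HRF)** in SD-OCT
volumes and **hard exudates (HE)** in color fundus photographs of eyes with
diabetic retinopathy, and classification of disease severity (NPDR vs PDR)
from the resulting lesion features.

HRF are small bright intraretinal dots on SD-OCT, deposited mainly around
the outer plexiform / outer nuclear layer border, and are thought to be
precursors of the clinically visible hard exudates seen on fundus
photography. Relating the two requires registering the 2D fundus image onto
the OCT en-face frame, detecting each lesion family in its own modality,
and comparing their measurements per eye. `retmodal` implements the full
chain for researchers in retinal image analysis:

* **Layer segmentation** — per-B-scan dynamic programming on the axial
  gradient after bilateral denoising: minimum-cost paths for the lower
  nerve-fiber-layer boundary, the IS/OS junction and Bruch's membrane, with
  stacked search bands and a per-step jump limit.
* **HRF detection** — inside the narrow band between the NFL lower boundary
  and IS/OS: seeds at intensity > mu + k sigma of the band (k = 2), seeded
  region growing (admission >= seed-component mean - 10 gray levels), and
  26-connected 3D linking. A topographic height map gives axial lesion
  thickness per en-face position.
* **Registration** — least-squares similarity (or affine) transform from
  vessel-crossing landmarks; en-face projection as the mean intensity over
  the inclusive IS/OS-to-BM band; bilinear inverse warping of the fundus
  image onto the en-face grid.
* **HE segmentation** — multiscale CIELab local-contrast saliency: at scale
  h, C(i,j) = || v1 - v2 || where v1 and v2 are the mean (L, a, b) vectors
  of the centred (2h+1)^2 square and its surrounding annulus, summed over
  scales S = sum_h C_h, thresholded by Otsu with minimum-area filtering and
  an add/remove correction-mask interface for pseudo-exudates.
* **Features and statistics** — five per-eye features (average area in
  mm^2, amount, average en-face distance to the fovea in um, average axial
  altitude in um, average reflectivity on the 8-bit scale), Pearson
  agreement (r, p, regression slope) between CFP and OCT HE areas.
* **Severity classification** — leave-one-out RBF SVM over the eight
  feature combinations built on {area, amount}, with a deterministic inner
  grid search, reporting Sen = TP/(TP+FN), Spe = TN/(TN+FP),
  Acc = (TP+TN)/N and MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
  with NPDR eyes positive.
* **Phantom generator** — paired synthetic OCT volumes and fundus images
  with full ground truth (layer surfaces, focus masks, exudate masks,
  landmarks, the true transform), so the whole pipeline is testable without
  patient data.

## Worked example

```r
library(retmodal)

cfg  <- phantom_config(grid_dims = c(128L, 32L, 256L),
                       n_foci = 8L, n_exudates = 3L, rng_seed = 42L)
case <- generate_phantom_case(cfg, eye_id = "demo", label = "PDR")

dvol  <- denoise_volume(case$oct)                      # bilateral, per B-scan
surf  <- build_surfaces(dvol, layer_params(denoise = FALSE))
band  <- build_narrow_band(surf, margin_vox = 3L, n_axial = 256L)
dvol2 <- denoise_volume(dvol, sigma_spatial = 2, sigma_range = 12)
lesions <- detect_hrf(dvol2, band)
lesions
#> lesion_set: 8 lesions, 255 voxels total on a 128 x 32 x 256 grid

tm <- estimate_transform(case$landmarks, "similarity")
tm$residual_rms_px                       # exact landmarks -> ~5e-15 px

split <- split_by_he(lesions, case$truth_he_mask_enface)
length(split$he$lesions); length(split$focus$lesions)
#> 3 hard exudates, 5 plain foci

compute_eye_features(lesions, case$oct, case$fovea)
#>   eye_id label avg_area_mm2 amount avg_distance_um avg_altitude_um avg_reflectivity
#> 1   demo   PDR      0.05713      8            2080           29.04            151.4
```

All 8 generated foci are recovered as 8 lesions; the 3 large, axially tall
foci that were drawn as fundus exudates are labeled HE by footprint overlap
with the registered HE mask. The mean altitude (29 um) sits in the range
typical of plain foci; the per-lesion height map peaks at 70 um over the
exudates. The metric engine on a confusion quadruple:

```r
compute_metrics(confusion_counts(tp = 13, fp = 7, tn = 12, fn = 1))
#> Sen 92.86%  Spe 63.16%  Acc 75.76%  MCC 0.5666
```

`run_end_to_end(run_config(...))` chains every stage over a phantom cohort
and writes the three per-eye feature tables, the agreement report, the
severity table (8 combinations x 3 lesion groups) and a JSON manifest with
seed, parameters and output checksums. A thin command-line dispatcher with
the same stages is installed at `inst/cli/retmodal`.

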