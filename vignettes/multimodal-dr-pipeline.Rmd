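---
title: "Quantifying hyper-reflective foci and hard exudates across SD-OCT and fundus photography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyper-reflective foci and hard exudates across SD-OCT and fundus photography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmodal)
```

## The problem

In diabetic retinopathy, breakdown of the blood-retinal barrier deposits
lipid and proteinaceous material in the outer retina. On spectral-domain
optical coherence tomography (SD-OCT) these deposits appear as small bright
dots — hyper-reflective foci (HRF) — concentrated around the border of the
outer plexiform and outer nuclear layers. When foci accumulate into large,
thick deposits they become clinically visible on color fundus photography
(CFP) as hard exudates (HE). Quantifying both lesion families, and relating
the 2D fundus view to the 3D OCT view, supports two questions: do HE
measured on CFP agree with the corresponding hyper-reflective lesions on
OCT, and do lesion burden features separate non-proliferative from
proliferative disease (NPDR vs PDR)?

`retmodal` implements that analysis end to end:

1. **OCT layer segmentation** (`build_surfaces`) bounds the lesion search
   region.
2. **HRF detection** (`detect_hrf`) finds bright foci inside the band.
3. **Registration** (`estimate_transform`, `warp_crop_fundus`) maps the
   fundus photograph onto the OCT en-face grid via vessel-crossing
   landmarks.
4. **HE segmentation** (`saliency_multiscale`, `segment_he`) extracts hard
   exudates from the registered fundus image.
5. **Feature extraction and statistics** (`compute_eye_features`,
   `agreement_report`) quantify five per-eye features and the
   cross-modality agreement.
6. **Severity classification** (`loo_evaluate`, `severity_report`)
   evaluates NPDR-vs-PDR prediction with a leave-one-out RBF SVM over
   eight feature combinations.

No patient data ship with the package; a phantom generator
(`generate_phantom_case`, `generate_cohort`) produces paired OCT/fundus
cases with complete ground truth so every stage is testable.

## Geometry and conventions

The canonical macular cube covers 6 x 6 x 2 mm sampled at 512 x 128 x 1024
voxels, i.e. a voxel pitch of (11.72, 46.88, 1.95) micrometres on the
(A-scan, B-scan, axial) axes. Axis order is (x = A-scan, y = B-scan,
z = axial), z increasing from vitreous to choroid, and **all indices are
1-based**, on disk as well as in memory. Intensities live on the 8-bit
0-255 scale.

## Layer segmentation

Each B-scan is first denoised with a bilateral filter (spatial sd 2
voxels, range sd 35 gray levels): speckle is multiplicative, so averaging
must be confined to pixels of similar intensity or layer boundaries smear.
Three boundaries are then traced per B-scan as minimum-cost left-to-right
paths by dynamic programming, with the per-pixel cost the signed axial
gradient (sign selects dark-to-bright or bright-to-dark transitions) and a
per-step jump limit of 2 voxels (ties resolve to the smaller depth):

* the lower nerve-fiber-layer boundary (bright-to-dark) in the upper 5-30%
  of the axial range,
* the photoreceptor inner/outer segment junction, IS/OS (dark-to-bright),
  below it,
* Bruch's membrane (bright-to-dark) below the IS/OS.

Each later surface is searched strictly below the previous one (a 3-voxel
gap), which is what makes the stack robust to bright foci: a focus in the
outer nuclear layer produces a locally attractive dark-to-bright edge, but
the globally cheapest path still follows the continuous IS/OS. Surfaces
are finally median-filtered across the (A-scan, B-scan) grid with a 5 x 5
window. On phantoms the mean absolute surface error is about 0.5 voxels
(~1 um axially at canonical sampling).

## The narrow band and HRF detection

HRF compete in intensity with the nerve fiber layer above and the
photoreceptor/RPE complex below, so detection is confined to the *narrow
band* between the NFL lower boundary and the IS/OS. The band is eroded
axially by 3 voxels on each side: bilateral smoothing smears the bright
NFL about the spatial kernel width (~2-3 voxels) into the band, and a
1-voxel margin provably admits that residue as false seeds.

Detection then proceeds in three steps:

* **Seeding.** Seeds are band voxels brighter than mean + k x SD (k = 2)
  of the band intensities. The statistics are pooled over the whole
  volume by default (`threshold_scope = "volume"`): per-B-scan statistics
  are inflated when a large exudate shares the B-scan, which silently
  raises the threshold above small co-planar foci. The per-B-scan variant
  remains available (`adaptive_seeds`).
* **Region growing.** Each 8-connected seed component grows over pixels
  within the band whose intensity is at least the component mean minus
  delta (10 gray levels), so growth can never leave the band nor bleed
  into the darker background.
* **3D linking.** Per-B-scan masks are stacked and labeled with
  26-connectivity. `detect_hrf` additionally bridges 1-voxel gaps
  (`bridge_gap = 1`): speckle occasionally dims a single voxel inside a
  focus below the growth admission, splitting one focus into two
  fragments that would otherwise be double-counted.

Seeding and growing run on a *second*, range-selective bilateral pass
(range sd 12): after the first pass, clusters of correlated bright
speckle survive (the range kernel protects exactly the high-contrast
structure we want to keep), and these clusters seed false lesions. The
second pass suppresses the remaining low-contrast clusters (~15-30 gray
levels above background) while leaving the ~90-gray-level focus contrast
untouched. The minimum lesion size is 1 voxel: with the volume-scope
threshold on the twice-denoised image, false seeds were absent across 45
validation phantoms, and genuinely sub-voxel foci must be allowed to
survive as single-voxel detections.

The topographic height map (`height_map`) converts per-column lesion
voxel counts to micrometres of axial thickness; it conserves total lesion
volume by construction.

## Registration and en-face projection

The en-face image is the mean intensity over the inclusive axial band
from the IS/OS to Bruch's membrane — the standard projection in which
retinal vessels cast dark shadows, giving CFP and OCT a common vascular
pattern. Vessel crossing points, picked in both modalities, are the
landmark input; the fundus-to-en-face transform is fitted by least
squares (closed-form similarity by default; full affine by flag) and the
fundus image is inverse-mapped onto the en-face grid with bilinear
interpolation, zero fill, and a validity mask. Landmark *detection* is
deliberately out of scope: the clinical procedure is semi-automatic with
human-chosen crossings, and the phantom emits exact crossing coordinates.

## Hard-exudate segmentation

Hard exudates are compact, yellowish, locally contrasted blobs. The
saliency of a pixel at one scale is the Euclidean distance between the
mean CIELab vector of the centred (2h+1)^2 inner square and that of the
square annulus of width h around it; the final map sums the per-scale
maps over h in {3, 7, 15} pixels (mirror padding at borders). Segmentation
applies Otsu's threshold to the summed map and drops components below
`min_area_px`. Lab means make the measure respond to joint luminance and
chromatic contrast, and a uniform image is exactly zero-salient.

Dark structures are salient too (the distance is unsigned), so vessel
crossings — locally blob-like — survive thresholding as pseudo-exudates.
The package mirrors the clinical workflow programmatically: a
correction-mask interface (`apply_correction`) removes known pseudo-HE
regions, e.g. disks at the landmark crossings. Cotton-wool spots and
other real-image pseudo-HEs are likewise handled through correction
masks, not modeled.

HE/HRF fusion: a 3D lesion is labeled a hard exudate iff at least half of
its en-face footprint lies inside the registered fundus HE mask
(`split_by_he`); the split is exhaustive and disjoint, giving the three
lesion groups used downstream (HE only, HRF excluding HE, all HRF).

## Features and statistics

Five per-eye features, each the mean over lesions:

| feature | definition | units |
|---|---|---|
| `avg_area_mm2` | en-face footprint pixels x lateral pixel area | mm^2 |
| `amount` | lesion count | - |
| `avg_distance_um` | en-face Euclidean distance, lesion centroid to fovea | um |
| `avg_altitude_um` | mean per-column axial extent x axial pitch | um |
| `avg_reflectivity` | mean raw intensity over lesion voxels | 0-255 |

The fovea is an input (clinically it is marked manually; the phantom
supplies truth). Distance is measured in the en-face plane: lesions live
at varying depths and the clinically reported distance-to-fovea is an
en-face quantity; a 3D reading would mix axial position into a lateral
biomarker. Altitude is the per-column voxel count (not max-min), matching
the height-map convention, so one lesion's mean altitude times its
footprint area recovers its volume.

Cross-modality agreement (`agreement_report`) compares per-eye HE areas
measured on CFP and on OCT: Pearson r with a two-sided t-test p-value and
the ordinary least-squares slope, per severity group and pooled. Groups
with fewer than 3 eyes are skipped with a warning; p-values are reported
raw (no multiplicity correction).

## Severity classification

Eyes are classified NPDR (positive) vs PDR (negative) with an RBF-kernel
SVM under leave-one-out cross-validation, over eight feature combinations
that all contain average area and average amount. Features are min-max
normalized cohort-wide *before* the leave-one-out loop — this follows the
described analysis order, and the train/test leakage it introduces is a
known caveat of that order; the grids and fold assignment are
deterministic (per-class round-robin inner folds; ties in the inner grid
search resolve to the smallest cost, then the smallest kernel width).
Default grids are powers of two, 2^-8 to 2^8 in steps of 4x, with inner
5-fold selection. Metrics are sensitivity, specificity, accuracy and the
Matthews correlation coefficient from the pooled confusion counts; a zero
factor in the MCC denominator yields MCC = 0 with a flag.

## The phantom: what it emulates, what it does not

The generator's defaults define the study conditions and were fixed
before the validation experiments:

* geometry: canonical 512 x 128 x 1024 cube over 6 x 6 x 2 mm (tests and
  the acceptance script use 128 x 32 x 256 to stay within desk-scale
  budgets; the vignette states problem sizes as the package's own choice);
* five smoothly undulating surfaces (ILM 200, NFL-lower 260, OPL/ONL 500,
  IS/OS 700, BM 800 um nominal depth, +/-15 um undulation plus tilt) with
  six compartment reflectivities (vitreous 10, NFL 120, inner retina 60,
  ONL 40, IS/OS-RPE 140, choroid 50);
* multiplicative Gamma speckle with relative sd 0.15, the standard
  fully-developed-speckle approximation, quantized to 8 bits;
* foci as axis-aligned ellipsoids centred near the OPL/ONL border at
  gray level 150: plain foci with 40-80 um lateral semi-axes and 12-20 um
  axial semi-axes (altitudes ~30 um), HE-destined foci with 120-250 um
  lateral and 25-40 um axial semi-axes (altitudes ~60 um) — the
  HE-vs-HRF altitude difference runs in the clinically reported
  direction;
* cohort structure: NPDR eyes draw 4-10 foci with 1-3 exudates, PDR eyes
  12-24 foci with 3-8 exudates, so area and amount separate the classes;
* a paired fundus image (1.4x the en-face grid) with radial vignetting,
  four moderately dark sinusoidal vessels whose crossings are emitted as
  exact landmarks, and one exudate blob per HE-destined focus, drawn as
  the transform-preimage of the focus's en-face ellipse so fundus truth
  maps exactly onto OCT truth.

Deliberate simplifications: no foveal pit is carved into the surfaces
(the fovea is a coordinate, not a shape), no vessel shadows in the OCT
volume, no back-shadowing under large lesions, no photoreceptor
disruption, no motion artifacts, and vessel contrast is kept below
exudate contrast (the single-threshold regime the saliency method
assumes; residual pseudo-HEs go through the correction interface).
Passing phantom tests therefore demonstrates algorithmic correctness
under known geometry and noise — not clinical performance on real
images, where shadowing, pathology other than HRF/HE, and acquisition
artifacts dominate the error budget.

Foci are placed by rejection sampling with disjoint, 2-voxel-padded
bounding boxes, guaranteeing a >= 4-voxel gap: the truth mask has exactly
`n_foci` 26-connected components and fragment bridging in detection can
never merge two distinct foci. A physically sub-voxel focus still lights
the voxel it falls in (partial volume).

## Numerical choices and degenerate inputs

* DP tie-break: smallest axial index; brute-force enumeration confirms
  optimality on small grids.
* Constant images are rejected by `segment_boundary` (no gradient
  evidence) rather than returning an arbitrary path.
* Otsu on a constant saliency map is an error advising a fixed threshold.
* Bilateral borders: out-of-bounds neighbours are skipped and weights
  renormalized; clamped indexing would over-weight border pixels and
  leave edge columns unsmoothed.
* Eyes without lesions carry NA means (flagged); for classification the
  normalized features of such eyes are zero.
* Empty seed sets grow to empty masks; empty lesion sets give zero height
  maps.
* MCC with a zero denominator factor is reported as 0 and flagged.

## Reproducibility

Every stochastic step is seeded: a phantom is bit-identical given its
config and seed, per-case cohort seeds derive from the master seed, and
the LOO/grid-search path is deterministic. `run_end_to_end` writes a JSON
manifest with the seed, parameters, per-stage timings and MD5 checksums
of all outputs; reruns with the same config reproduce the checksums.

## Known limitations

* The saliency halo (pixels just outside a blob are salient at large
  scales) dilates HE masks by a few pixels; Dice against truth is
  typically 0.7-0.85 on the fundus, tighter at smaller scales.
* Detection of foci far smaller than the B-scan spacing is resolution
  limited: at 4x-reduced grids a 2-voxel focus whose second voxel drew a
  deep speckle fade can be detected as a single voxel (Dice 0.67) or,
  rarely, missed.
* Cohort-wide normalization before LOO leaks the held-out eye's range
  into training; the effect is small for min-max scaling but real.
* The agreement slope between modalities is a property of the data, not
  the method; the phantom checks recovery of a known slope, not the
  clinically observed value.
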