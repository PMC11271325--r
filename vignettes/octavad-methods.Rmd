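---
title: "Quantifying perfusion around macular lesions in en-face OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perfusion around macular lesions in en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Acute macular neuroretinopathy (AMN) presents as a sharply demarcated,
hyporeflective parafoveal lesion on infrared (IR) fundus reflectance. Whether
the underlying perfusion deficit sits in the retinal capillary plexuses or in
the choroidal circulation is read off OCT angiography (OCTA) by comparing
vessel area density (VAD) inside the lesion against control tissue *of the
same eye*. octavad implements that comparison end to end:

1. **Inputs.** Per eye, five co-registered en-face OCTA slabs — superficial
   (SVP), intermediate (ICP) and deep (DCP) capillary plexus,
   choriocapillaris (CC), and choroid — plus the IR image and a human
   segmentation of the AMN lesion and the foveal avascular zone (FAZ) as an
   integer label map (ITK-Snap convention, lesion = 1, FAZ = 2). The package
   reads PNG exports and NIfTI-1; nothing is ever resampled — all images of
   one eye must already share dimensions, and mismatches are errors.
2. **Control regions.** Two intra-eye comparators are derived from the
   segmentation alone (`region_set()`):
   - the *adjacent tissue control* (ATC): the lesion footprint scaled about
     its centroid by a linear factor of 2, minus the lesion, minus any FAZ
     overlap — a one-lesion-radius band of directly adjacent tissue;
   - the *ring segment* (RS): the closed fovea-centred annulus whose inner
     and outer circles pass through the lesion's nearest and farthest pixel
     (tangent circles), minus the lesion. Tissue at equal distance from the
     fovea has comparable capillary density, which is what makes this a
     control.
3. **VAD.** Per slab, an Otsu threshold on the full-image 256-bin histogram
   separates perfused (strictly above threshold) from non-perfused pixels;
   VAD of a region is the perfused fraction of its pixels
   (`quantify_eye()`). In the SVP the large arcades would dominate the
   capillary signal, so pixels flagged by a large-scale Frangi vesselness
   filter are removed from numerator and denominator; the CC and choroid are
   thresholded without any vesselness filtering, which distorts granular
   choroidal texture.
4. **En-face overlap.** The lesion is also segmented on en-face OCT
   reconstructions at the ellipsoid zone (EZ) and at the OPL/Henle-fibre
   junction; agreement with the IR segmentation is scored with the
   Sørensen–Dice coefficient `2|A∩B|/(|A|+|B|)` (`enface_overlap_analysis()`).
5. **Cohort statistics.** Per slab and comparator, a two-sided paired t-test
   across eyes of lesion VAD vs control VAD, a percent reduction of cohort
   means, and Bonferroni correction with an explicit family size
   (`summarize_cohort()`).

## Design choices where the construction was open

Several steps of the region construction admit more than one reading; the
package fixes one interpretation each and keeps the alternatives reachable:

- **"Doubled in size"** is taken as a *linear* scale factor of 2 about the
  lesion centroid (4x area for a solid shape), leaving an adjacent band
  roughly one lesion-radius wide. `build_atc(scale = sqrt(2))` gives the
  area-doubling alternative.
- **The midpoint** of the scaling is the centroid (mean pixel centre) of the
  lesion mask rather than its bounding-box centre; the centroid is robust to
  ragged outlines.
- **Rasterisation** of the scaled footprint is by inverse affine mapping
  with nearest-neighbour lookup (half-up rounding), so the footprint is
  exactly the preimage of the mask under the scaling — this is what the
  brute-force per-pixel oracle in the test suite checks.
- **The ring centre** is the FAZ centroid: the FAZ segmentation is the only
  fovea-referencing input, and its centroid is the only construction that
  uses exactly that input.
- **The annulus is closed** (`r_min <= d <= r_max`, pixel centres), and the
  RS is *not* FAZ-excluded — FAZ exclusion is applied to the ATC only. Any
  RS/FAZ overlap is reported as a diagnostic (`rs_faz_overlap_px`); in
  practice a lesion outside the FAZ puts the inner circle beyond the FAZ.
- **One Otsu threshold per slab**, reused for all three regions. A
  per-region threshold would adapt to a lesion-localised deficit and pull
  the comparison towards the null; the per-region mode exists behind
  `quantify_config(per_region_threshold = TRUE)` for sensitivity analysis
  only. Intensities equal to the threshold count as non-perfused.
- **Excluded large-vessel pixels leave both numerator and denominator**:
  "excluded from analysis" is read as removing the pixels from the evaluated
  area, not as counting them non-perfused.
- **Bonferroni family size** defaults to `m = 10` (5 slabs x 2 comparators
  treated as one family) and is a recorded argument, never an implicit
  count, so any reproduction states its multiplicity choice. The test is
  two-sided. Percent reduction is computed on cohort means by default, with
  a mean-of-per-eye-reductions variant behind a flag.

## Frangi configuration

The vesselness filter follows the standard two-eigenvalue form with
blobness weight `beta = 0.5`. Two choices matter:

- **Scales**: `sigmas = 4:10` px by default, matching arcade calibres of
  several pixels at typical en-face sampling, and deliberately excluding
  capillary-scale structure.
- **Cutoff policy**: the response is thresholded by Otsu on its non-zero
  values, with a floor of 0.2 on the vesselness itself. The floor comes from
  theory, not fitting: an isotropic (blob-like) structure has eigenvalue
  ratio 1 and response at most `exp(-1/(2 beta^2)) ~ 0.135`, so 0.2 can only
  be reached by genuinely elongated structure. The structureness scale is
  anchored to the image's dynamic range (`c = range/4`) rather than to the
  image's own maximum Hessian norm: a matched bright ridge reaches a Hessian
  norm of roughly 0.4x its contrast while noise stays below ~0.15x the full
  range, so structure-free images keep a uniformly weak response instead of
  being renormalised to their own noise tail.

## The synthetic phantom

Because no patient imagery ships with the package, every pipeline stage is
validated on seeded phantoms (`generate_eye()`, `generate_cohort()`):

- **Perfusion texture** is thresholded band-pass noise: a Gaussian-smoothed
  white-noise field, normalised so its marginal is exactly standard normal,
  is compared against the per-pixel perfusion probability. Each pixel is
  perfused with *exactly* the configured probability (so binomial
  expectations hold by construction) while neighbouring pixels remain
  correlated at the configured texture scale — capillary-fine for SVP/ICP/DCP
  (2.5–3 px), granular for the CC (1.5 px), coarse and lobular for the
  choroid (6 px).
- **Deficits** multiply the perfusion probability inside the lesion by
  `1 - deficit`, per layer. Default per-layer base fractions (0.38/0.32/0.34
  retinal, 0.42 CC, 0.39 choroid) are chosen so that a 27% CC and 41%
  choroid deficit leave lesion densities near the clinically reported
  magnitudes (~0.31 and ~0.23).
- **Geometry** scales with the frame: FAZ radius `0.09 min(shape)`, an
  elliptical parafoveal lesion with semi-axes `(0.07, 0.055) min(shape)` at
  eccentricity `0.22 min(shape)`, always outside the FAZ (overlap is a
  configuration error). The FAZ is rendered avascular in the retinal layers
  and perfused in the choroidal ones.
- **Large vessels** are bright quadratic arcs crossing the SVP frame, with
  the rasterised centre lines and dilated tube masks exported as ground
  truth for the exclusion filter.
- **Intensities** are `background 30 + perfused x 170`, arcs at 240,
  additive Gaussian noise of sd 18, clipped to 8 bits. These levels give a
  cleanly bimodal histogram, so Otsu recovers the underlying binary texture
  nearly exactly; that is intentional — it lets the tests separate geometry
  and statistics errors from classification noise. A multiplicative speckle
  mode exists behind `speckle = TRUE`.
- **En-face footprints**: the EZ mask equals the IR lesion footprint by
  default; the OPL mask is displaced along the ray from the fovea through
  the lesion centroid (or nasally when configured), emulating Henle-fibre
  obliquity. `displacement_for_dice()` inverts the closed-form two-circle
  lens area so fixtures can be calibrated to a target Dice.

What the phantom does *not* emulate: anatomically grown vascular trees,
OCT speckle physics, projection artifacts from overlying vessels, or
segmentation errors of the device's layer segmentation. Passing tests
therefore demonstrate the correctness of the geometry, thresholding and
statistics, not robustness to device-specific artifacts.

## Validation problem sizes

The test suite validates properties at sizes chosen to balance statistical
resolution against desk-scale runtime, stated here as the package's own
choices:

- Otsu against an exhaustive 256-candidate scan on 100 randomised 64 x 64
  images (exact bin equality).
- Region geometry invariants and the brute-force annulus/scaling oracles on
  200 randomised placements at 96 x 96.
- Null calibration: 1000 cohorts of 6 zero-deficit eyes at 96 x 96; raw
  rejection of the paired test at `alpha = 0.05` must land in [0.03, 0.07]
  for every slab and comparator.
- Effect recovery: 50 cohorts of 6 eyes at the native 512 x 512 scale with
  CC/choroid deficits of 0.27/0.41; the recovered mean percent reductions
  must sit within 5 points of the injected values, the CC-vs-ATC corrected
  test must reject in at least 80% of cohorts, and the retinal layers must
  stay non-significant in at least 90%. The 512 px frame matters here: a
  lesion of ~3000 px averages enough texture clusters (the choroid's 6 px
  correlation scale leaves only ~30 independent clusters per lesion) for
  the paired test to see the effect.

## Degenerate inputs and numerical conventions

- Pixel centres sit at integer indices; all real-valued snapping uses
  half-up rounding (`floor(x + 0.5)`), which keeps the region constructions
  translation-equivariant (R's own `round()` is round-half-even).
- Constant images have no Otsu threshold and raise a "degenerate histogram"
  error; all-equal paired differences raise a "degenerate differences"
  error rather than returning p = 0.
- A single-radius lesion degenerates the annulus to a one-pixel-wide ring
  (with a warning); an ATC emptied by its exclusions is an error carrying
  the lesion/overlap areas as diagnostics.
- Regions touching the frame are clipped silently; Otsu ties break to the
  smallest qualifying threshold; all pipelines are deterministic given their
  seeds, and the synthetic module never touches the caller's RNG state.

## Limitations

The comparison inherits the method's own caveats: choroidal OCTA signal is
vulnerable to shadowing from overlying alterations, the ring segment mixes
quadrants whose density is known to fluctuate, and a slab-global Otsu
threshold couples all regions to the full-frame histogram. The phantom's
clean bimodal intensities mean the package's accuracy statements concern
the analysis pipeline, not acquisition noise. En-face eligibility (whether
a lesion is distinguishable at both the EZ and OPL levels) is a manual
input, not an algorithmic decision.
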