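# octavad

Vessel area density and lesion overlap analysis for en-face OCT angiography
(OCTA), built around the question: when a focal macular lesion such as acute
macular neuroretinopathy (AMN) appears, *which vascular layer is
underperfused* — the retinal capillary plexuses or the choroidal
circulation?

The package is aimed at retinal imaging researchers who have, per eye, a set
of co-registered en-face OCTA slab exports (SVP, ICP, DCP, choriocapillaris,
choroid), the infrared (IR) image, and a human segmentation of the lesion
and the foveal avascular zone (FAZ). It provides:

- **Intra-eye control regions** derived from the lesion segmentation alone:
  the *adjacent tissue control* (ATC), i.e. the lesion scaled ×2 linearly
  about its centroid minus the lesion and any FAZ overlap, and the *ring
  segment* (RS), the fovea-centred annulus whose circles are tangent to the
  lesion, minus the lesion.
- **Vessel area density** (VAD): per slab, an Otsu threshold on the 256-bin
  histogram separates perfused from non-perfused pixels and

  `VAD(region) = #{pixels in region with intensity > t_Otsu} / #{pixels in region}`,

  with large superficial vessels removed from the SVP measurement by a
  large-scale Frangi vesselness filter (excluded pixels leave numerator and
  denominator).
- **En-face overlap**: Sørensen–Dice score `2|A∩B|/(|A|+|B|)` between the IR
  lesion segmentation and lesion segmentations on en-face OCT
  reconstructions at the ellipsoid zone (EZ) and the OPL/Henle-fibre
  junction.
- **Cohort statistics**: per slab and comparator, a two-sided paired t-test
  of lesion vs control VAD across eyes, percent reduction of cohort means,
  and Bonferroni correction with an explicit family size
  (`p_corr = min(1, m·p)`).
- **A seeded synthetic phantom generator** (fovea-centred textures with an
  avascular FAZ, parafoveal lesion with per-layer perfusion deficits, bright
  SVP arcades, displaced en-face footprints) so the entire pipeline is
  testable without patient data.

File formats go through standard packages: PNG slab exports (`png`),
NIfTI-1 images and ITK-Snap-style label maps (`RNifti`), CSV result tables,
YAML per-eye manifests. See the vignette
(`vignettes/octavad-methods.Rmd`) for the model, parameter choices and
limitations.

## Worked example

Simulate a six-eye cohort at the native 512×512 scale with a
lesion-localised choriocapillaris deficit of 27% and a choroidal deficit of
41% (retinal layers untouched), quantify it, and summarise:

```r
library(octavad)

base <- synthetic_config(seed = 7, shape = c(512, 512),
                         lesion_deficit = c(CC = 0.27, CHOROID = 0.41))
cohort <- generate_cohort(6, base)
vad    <- quantify_cohort(cohort)          # 15 VAD records per eye
res    <- summarize_cohort(vad, m_comparisons = 10)
res[res$comparator == "ATC",
    c("layer", "mean_vad_amn", "mean_vad_comparator",
      "percent_reduction", "p_raw", "p_corrected")]
#>    layer mean_vad_amn mean_vad_comparator percent_reduction   p_raw p_corrected
#>      SVP        0.295               0.331             10.90 0.45393      1.0000
#>      ICP        0.293               0.286             -2.53 0.85772      1.0000
#>      DCP        0.300               0.358             16.17 0.04054      0.4054
#>      CC        0.293               0.416             29.64 0.00164      0.0164
#>  CHOROID        0.272               0.395             31.00 0.16352      1.0000
```

Reading this: lesion VAD (`mean_vad_amn`) in the choriocapillaris is ~29%
below its adjacent-tissue control and the Bonferroni-corrected paired test
rejects (p = 0.016), while the three retinal plexuses show no corrected
signal — the injected effect is recovered with layer specificity. The
choroid's coarse lobular texture makes its per-eye VAD noisy (only ~30
independent texture clusters fit in a lesion), so a single six-eye cohort,
as here, often shows the reduction without reaching significance.

En-face overlap with displacement calibrated to Dice targets 0.89 (EZ) and
0.65 (OPL):

```r
r <- 20
enf_base <- synthetic_config(seed = 3, shape = c(256, 256),
    lesion = list(axes = c(r, r)),
    ez_displacement_px  = displacement_for_dice(r, 0.89),
    opl_displacement_px = displacement_for_dice(r, 0.65))
enf <- dice_cohort(generate_cohort(6, enf_base, modality = "enface"))
compare_dice_pairs(enf)
#> $n_eyes        [1] 6
#> $mean_dice_ez  [1] 0.887
#> $mean_dice_opl [1] 0.653
#> $t_stat        [1] 43.7
#> $p_value       [1] 1.19e-07
```

The EZ footprint tracks the IR lesion far better than the radially displaced
OPL footprint, and the paired comparison flags the difference.

A thin command-line wrapper over the same functions ships in
`inst/cli/octavad.R` (`simulate`, `quantify`, `dice`, `stats`).

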