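# picquant

Quantitative analysis of pseudoisocyanine chloride (PIC) J-aggregation
assays used as a non-protein sensor for intracellular macromolecular
crowding.

PIC switches between a monomeric state (weak broad emission, 520–650 nm,
maximum near 560 nm) and a fibrillar J-aggregated state (intense sharp
~575 nm band) depending on the crowding of its environment. Assays built
on this switch need several quantitative pipelines, all implemented here
for R users working on phase separation and condensate biophysics:

* **Spectral pixel classification** — J-aggregate vs monomer vs background
  in multichannel confocal images (aggregate band 565–585 nm, threshold
  400 of 4095 counts), automatic nucleolus exclusion, cytoplasm aggregate
  area fractions, stress-granule colocalization and monomer enrichment.
* **Morphometrics** — threshold/wand segmentation, area, circularity
  4πA/P², background-corrected intensities, boxplot summaries with t-test
  and ANOVA.
* **FRAP** — easyFRAP-style double + full-scale normalization and the
  single-exponential recovery fit I(t) = I₀ − a·e^(−βt), with I₀ the
  mobile fraction and β the recovery rate.
* **Time-resolved SLS/DLS** — momentum transfer q = (4πn/λ₀)sin(θ/2),
  excess Rayleigh ratios against a toluene standard, Zimm and Guinier fits
  (M_w, R_g, A₂), per-angle cumulant analysis, extrapolation of D to
  q² → 0 (D_z), Stokes–Einstein R_h = k_B·T/(6πη·D_z), the shape ratio
  ρ = R_g/R_h (≈ 0.775 for solid spheres) and induction-time detection for
  droplet growth.
* **UV–Vis cooling ramps** — detection of the J-aggregation threshold
  temperature T_JA from the appearance of the sharp 573 nm absorbance
  peak, with censoring and per-condition replicate averaging.
* **Synthetic data generators** for all of the above, with ground truth
  emitted alongside every dataset.

## Worked example

Generate a synthetic heat-stressed droplet-growth experiment and run the
full scattering evaluation:

```r
library(picquant)

calib <- ls_calibration(rr_std = 1.35e-5)      # toluene standard, 1/cm
series <- generate_scattering_series(
  droplet_growth_model(nucleation_time = 300), # droplets appear at 300 s
  calib, n_frames = 45, noise = 0.01, seed = 1)
res <- analyze_series(series)
res$induction_time_s
#> [1] 320
tail(res$results, 3)
#>    t_s  Mw_g_mol    Rg_nm      Dz_m2_s    Rh_nm       rho
#> 55 420 477832340 84.82617 2.239834e-12 109.4267 0.7751869
#> 56 430 610070720 88.45164 2.150004e-12 113.9987 0.7759001
#> 57 440 756535325 92.90450 2.073585e-12 118.2000 0.7859943
```

The detected induction time is 320 s: the detector (baseline mean + 3 SD
for 3 consecutive frames) fires two 10-s frames after the planted
nucleation, a deterministic lag, so condition *differences* are recovered
at frame resolution. M_w climbs from the 1.5×10⁵ g/mol baseline into the
10⁸–10⁹ g/mol range as droplets grow, and ρ sits at the solid-sphere value
≈ 0.775 once droplet scattering dominates.

Classify a synthetic cell image and quantify aggregate coverage:

```r
scene  <- cell_scene(planted_aggregate_fraction = 0.41, seed = 2)
cell   <- generate_cell_image(scene)
excl   <- mask_nucleoli(cell$image, cell$rois$nucleus)
cmap   <- classify_pixels(cell$image, classifier_params(), exclude = excl)
aggregate_area_fraction(cmap, cell$rois$cytoplasm)
#> [1] 41.00216
```

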