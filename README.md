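# aeoscan

Satellite-based monitoring of aeolian (wind-driven) desertification, for
dry-land remote-sensing and land-degradation researchers who need annual
desertified-area maps without waiting for the next field survey.

## The method

The monitoring core works on an annual series of 8-day composite
surface-reflectance rasters (46 composites per year, 1 km cells after
aggregation):

1. **NDDI** per pixel and composite:
   `NDDI = (ρ_red − ρ_NIR) / (ρ_red + ρ_NIR)` — the negative of NDVI, so
   desertified surfaces score high and nearly seasonless while vegetation
   dips sharply in the growing season.
2. **Reference curve**: the mean NDDI trajectory over *pure* desertified
   coarse cells (fine-resolution desertified proportion strictly > 70%,
   found by classifying a pan-sharpened fine scene with a degree-2
   polynomial-kernel SVM and tallying per-cell class proportions on a 1-km
   grid frame), smoothed with a Savitzky–Golay filter (window 5, order 2).
3. **MAD matching**: `MAD_ij = (1/n) Σ_k |NDDI_ijk − ref_k|`, n = 46 —
   distance of each pixel's annual trajectory from the desertified
   standard.
4. **p-tile segmentation**: threshold the MAD map at the empirical
   quantile of a prior area fraction; pixels at or below it are
   desertified; counts × cell area give km², validated against survey
   areas by relative error.

Two supporting modules mirror the surrounding workflow: a pan-sharpening
comparison (PCA / multiplicative / Brovey with mean, standard deviation,
entropy and correlation metrics) that selects the fusion algorithm for the
fine scene, and a multispatial convergent-cross-mapping (CCM) module that
tests whether climate or population variables force desertified-area
dynamics, with bootstrap convergence p-values over composite
(across-site) libraries. Synthetic-scene and coupled-dynamics generators
with full ground truth make every stage testable offline.

## Worked example

```r
library(aeoscan)

scene <- generate_scene(scene_spec(coarse_n_rows = 40, coarse_n_cols = 40,
                                   seed = 1))
frame <- build_grid_frame(scene$truth_fine$geometry, 1000)
frame <- class_proportions(scene$truth_fine, frame)
pure  <- select_pure_pixels(frame)          # strict > 0.70 / > 0.90
cube  <- build_nddi_cube(scene$coarse_stacks)
ref   <- build_reference_curve(cube, pure, frame)
mad   <- compute_mad(cube, ref)
thr   <- ptile_threshold(mad, prior_fraction = 0.3)
mask  <- classify_desertified(mad, thr)

print(ref); print(mad)
cat("threshold:", round(thr, 4), "\n")
cat("estimated area:", area_estimate(mask), "km2 | truth:",
    scene$truth_area_km2, "km2\n")
```

```
<reference_curve> class 'desertified', n = 46, SG window 5 order 2
<mad_map> 40 x 40, MAD range [0.06134, 0.7199]
threshold: 0.1478
estimated area: 480 km2 | truth: 480 km2
```

The reference curve was built from the scene's pure desertified cells; the
p-tile threshold 0.1478 puts 30% of pixels at or below it, and the
resulting binary map recovers the true 480 km² exactly (98.75% of pixels
agree with the truth mask).

Driver attribution on a simulated 40-site × 15-year panel in which wind
speed truly forces desertified area:

```r
panel <- generate_coupled_panel(coupled_system_spec(
  x_name = "wind_speed", y_name = "desertified_area", seed = 2))
ccm_curve(panel, cause = "wind_speed", effect = "desertified_area",
          lengths = c(20, 100, 400), n_boot = 200, seed = 3)
```

```
<ccm_result> does 'wind_speed' force 'desertified_area'? (cross map 'wind_speed' from M_desertified_area)
  E = 4, tau = 1, 200 bootstrap iterations
   L rho_mean rho_sd
  20    0.233  0.096
 100    0.447  0.037
 400    0.513  0.024
  full-library rho = 0.566, convergence p = 0
```

Cross-map skill rises from 0.23 to 0.51 as the library grows — the
convergence signature of real forcing — and no bootstrap iteration saw the
long-library skill fail to beat the short-library skill (p = 0).

An end-to-end run (simulate → fuse → classify → link → NDDI → MAD →
threshold → area → CCM) with artifacts, manifest and log in one
directory:

```r
run_pipeline(pipeline_config(seed = 1), "runs/demo")
report("runs/demo")
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/aeoscan.R run --out runs/demo --seed 1
Rscript inst/cli/aeoscan.R report runs/demo
```

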