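# dasypop

Fine-scale population estimation from high-resolution optical satellite
imagery, for researchers in urban epidemiology, emergency response and
planning who need per-building population counts where only coarse census
totals exist.

The package reconstructs a simple 3D model of every residential building —
footprint from a built-up index, height from the geometry of its cast
shadow — and disaggregates census population onto the buildings with a
volume-preserving dasymetric model:

- **PanTex**: built-up presence as the minimum over displacement directions
  of the windowed gray-level co-occurrence contrast
  `Contrast = sum_{i,j} (i-j)^2 P(i,j)`.
- **MBI / MSI**: morphological building / shadow index, the mean over
  directions `d` and scales `s` of the differential white / black
  top-hat-by-reconstruction profile of the brightness image
  `MBI = sum_{d,s} |DMP(d,s)| / (D x S)`.
- **Object rules**: threshold + 8-connected labelling, then per-object
  feature rules (brightness, NDVI, length/width ratio, rectangular fit,
  shape index) and nearest-POI residential refinement.
- **Heights**: shadow masks via maximum between-class-variance (Otsu)
  thresholding of the MSI or of the local variance of
  `c3 = arctan(B / max(R,G))`; per-component shadow length `L` measured by
  scan lines along the solar azimuth + 180°, and `H = L tan(beta)`.
- **Population**: `pop_i = (FS_t / LA_t)(BH_t / AH_t) + C + eps_t` per
  building, with zone survey parameters `LA` (m²/person) and `AH` (m/floor),
  a least-squares per-zone correction `eps_t`, and the constant `C` chosen
  so totals match the census exactly (pycnophylactic property).
- **Metrics**: confusion matrix with kappa, signed relative error,
  `RTAE = sum|P_model - P_stat| / sum P_stat`, and 2.5 m height error bins.

A fully ground-truthed synthetic scene generator (`random_scene_spec()`,
`render_scene()`) emulates imagery, POIs, zones and census totals so the
whole chain is testable end-to-end without satellite downloads.

## Worked example

```r
library(dasypop)

spec <- random_scene_spec(n_buildings = 20, nrow = 512, ncol = 512, seed = 1)
run  <- run_synthetic_pipeline(spec)
print(run)
#> Pipeline run: 20 buildings, 20 shadow components
#>   per-unit RTAE: 0.0133
#>   height MAE vs truth: 0.995 m
```

All 20 synthetic buildings are recovered (footprints exact on a noiseless
scene); the mean absolute height error, 0.995 m, sits well under the
one-pixel shadow resolution `pixel_size * tan(beta)` = 6.4 m, and the
per-unit population totals deviate from the generated census by an RTAE of
0.013 (0 is perfect, 2 completely wrong).

Published accuracy tables ship as fixture CSVs and their summary statistics
are recomputed by the package:

```r
reproduce_tables()
#> Building detection (recomputed from printed confusion matrices):
#>   MBI:    overall 0.85, kappa 0.67
#>   PanTex: overall 0.73, kappa 0.34
#> ...
#> Population: mean |RE| 16.46%, RTAE 0.158, model total 2045560.434 over 42 units
```

A thin command-line front end with subcommands (`simulate`, `indices`,
`extract-buildings`, `extract-shadows`, `heights`, `population`,
`evaluate`, `reproduce-tables`) lives at `inst/cli/dasypop.R`.

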