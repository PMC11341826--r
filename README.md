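# greencube

Urban greenspace is both *fractional* — street trees, lawns and shrubs
occupy parts of a 10-m satellite pixel — and *seasonal*. `greencube` maps
both at once: it estimates each pixel's annual maximum sub-pixel greenspace
fraction by constrained spectral unmixing of the annual greenest composite,
reconstructs the pixel's 10-day NDVI phenology, and combines them into a
36-layer annual greenspace coverage data cube

```
G_t = G_max × NDVI_t / NDVI_max ,
```

where `G_max` is the vegetation fraction of the greenest composite and
`NDVI_t / NDVI_max` is the normalised seasonal greenness trajectory. On top
of the cube it estimates pixel-level vegetation **cooling efficiency** (CE,
°C of land-surface-temperature reduction per 1% greenspace) by
moving-window regression against LST rasters, and provides the block-level
aggregation and agreement metrics used to validate coverage products across
sensors and resolutions.

The package is aimed at people building or analysing greenspace seasonality
products from multispectral reflectance time series (blue/green/red/NIR
plus per-pixel cloud information). Because such archives are terabytes, a
fully ground-truthed **synthetic scene generator** is part of the package:
every stage — masking, compositing, unmixing, phenology, cube assembly,
cooling regression — is testable end-to-end by parameter recovery, with no
external data.

## What is in the box

| Stage | Functions |
|---|---|
| Synthetic scenes | `scene_truth()`, `render_reflectance()`, `render_lst()`, `make_fraction_maps()`, `vegetation_ndvi_curve()` |
| Features & masking | `compute_ndvi()`, `compute_ndwi()`, `apply_cloud_mask()`, `build_feature_stack()` |
| Compositing | `greenest_composite()`, `composite_10day()`, `interval_index()`, `temporal_grid()` |
| Unmixing | `select_endmember_candidates()`, `derive_endmember_signatures()`, `unmix_pixel()`, `unmix_image()`, `gmax_layer()` |
| Phenology | `gap_fill_linear()`, `rmmeh_smooth()`, `extract_ndvi_max()`, `build_ndvi_phenology()` |
| Cube | `assemble_cube()`, `write_cube()`, `read_cube()` (36 bands, 0.001 scale, nodata −1) |
| Cooling | `match_lst_to_cube()`, `cooling_efficiency()`, `window_sensitivity()` |
| Validation | `block_aggregate()`, `agreement_metrics()` |

Results come back as tidy objects where that is natural: `tidy()` /
`glance()` methods for fraction maps, CE maps and cubes; `autoplot()`
methods for maps and seasonality curves; tibbles from the sensitivity and
validation routines. A thin command-line wrapper with `simulate`,
`composite`, `unmix`, `phenology`, `cube`, `cooling` and `validate`
subcommands ships in `inst/cli/greencube`.

## Worked example

```r
library(greencube)

truth <- scene_truth(seed = 42)           # 128 x 128 reference scene
truth
#> <scene_truth> 128 x 128 pixels, 73 dates (DOY 3-363)
#>   phenology: unimodal, peak DOY 200, NDVI 0.15-0.90
#>   noise sd 0.010, mean cloud cover 0.20, CE 0.010-0.050 degC/%

series <- apply_cloud_mask(render_reflectance(truth), prob_threshold = 50)
comp   <- greenest_composite(build_feature_stack(series))
em     <- derive_endmember_signatures(comp, select_endmember_candidates(comp))
em
#> <endmember_set> 3 classes (percentile)
#>              blue  green    red    nir   ndvi    ndwi
#> vegetation 0.0319 0.0601 0.0097 0.4713 0.9585 -0.7732
#> bare       0.2015 0.2512 0.2831 0.3675 0.1282 -0.1881
#> water      0.0597 0.0873 0.0274 0.0280 0.0016  0.5069
#> candidate pixels: vegetation 1042, bare 1278, water 175

fm   <- unmix_image(comp, em)             # fractions on the unit simplex
phen <- build_ndvi_phenology(series)      # gap-fill -> 10-day -> smooth
cube <- assemble_cube(fm, phen, year = 2020)
cube
#> <greenspace_cube> 128 x 128 pixels x 36 ten-day layers (2020)
#>   coverage: mean 0.166, max 1.000; 100% valid, 7.2% aseasonal
```

The derived endmember signatures sit within ~0.01 reflectance of the
generator's true spectra, and the scene-wide vegetation-fraction RMSE
against truth is 0.024 at the scene's 0.01 reflectance noise (the
constrained least-squares noise floor at this endmember contrast — see the
methods vignette). Coupling the cube to a thermal scene from mid-summer
(DOY 199 matches 10-day slot 20):

```r
slot  <- match_lst_to_cube(199)$slot      # 20
green <- cube$layers[, , slot]
lst   <- render_lst(green, truth$ce_truth, base_lst = 40, noise_sd = 0.5,
                    seed = 43)
cem   <- cooling_efficiency(lst, green)   # 5 x 5 window
glance(cem)
#> # A tibble: 1 × 6
#>   window mean_ce median_ce   sd_ce valid_frac median_r2
#>    <int>   <dbl>     <dbl>   <dbl>      <dbl>     <dbl>
#> 1      5  0.0275    0.0272 0.00966      0.886     0.666
```

The estimated median CE of 0.027 °C/% recovers the scene's true slope field
(0.01–0.05 °C/%, mean 0.03); 89% of pixels pass the validity masks
(enough valid neighbours, enough greenspace variation). `write_cube(cube,
"cube_2020.tif")` stores the cube as a 36-band integer-scaled TIFF that
round-trips within 0.0005 coverage.

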