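---
title: "Methods: phenology-informed sub-pixel greenspace mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology-informed sub-pixel greenspace mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greencube)
```

## The model

Urban greenspace changes on two axes that a single land-cover map cannot
capture: *how much* of each pixel is vegetated at the height of the growing
season, and *how that cover waxes and wanes* through the year. `greencube`
separates the two and recombines them into a daily-interpretable coverage
model. For a pixel with annual maximum sub-pixel greenspace fraction
$G_{\max}$ and a reconstructed NDVI trajectory $NDVI_t$ with annual maximum
$NDVI_{\max}$, coverage at 10-day slot $t$ is

$$G_t \;=\; G_{\max} \times \frac{NDVI_t}{NDVI_{\max}},$$

i.e. the annual maximum extent modulated by normalised greenness phenology.
The two ingredients are estimated independently:

* $G_{\max}$ by fully constrained linear spectral unmixing of the annual
  *greenest composite*, and
* $NDVI_t$ by a three-stage reconstruction of the cloud-masked NDVI series
  (linear gap-fill, 10-day mean compositing, compound upper-envelope
  smoothing).

A year is always represented by exactly 36 slots: slots 1–35 cover days
$10(k-1)+1 \dots 10k$ and slot 36 absorbs the year tail (DOY 351 to 365 or
366). The long final slot is a deliberate convention — the alternative, a
37th stub slot, would break the fixed-depth annual product format.

## Sub-pixel greenspace from constrained unmixing

Each pixel's signature is modelled as a convex combination of a small set of
spectrally pure endmembers — vegetation, bare surface, water — plus
residual:

$$S_i = \sum_{k=1}^{n} f_{ik}\, C_k + \varepsilon_i,
  \qquad f_{ik} \ge 0,\; \sum_k f_{ik} = 1 .$$

The vegetation fraction of the greenest composite is $G_{\max}$.

**Solver.** The constrained least-squares problem is solved exactly by
combinatorial active-set enumeration: the optimum has some support of
strictly positive fractions; for each of the $2^n - 1$ candidate supports
the equality-constrained subproblem is a small KKT system, and the feasible
solution with minimal residual is the global optimum. With $n = 3$ this is
seven 4×4 solves per pixel — machine-precision exact, with no iterative
convergence failure modes. Tests verify it against an exhaustive simplex
grid search (step $10^{-3}$) and against an independent NNLS-based route.

**Which bands enter the fit.** Feature images carry six bands — blue,
green, red, NIR, NDVI, NDWI — but by default only the four reflectance
bands enter the unmixing fit (`bands = 1:4`). The reason is structural:
reflectance mixes linearly over sub-pixel covers, but the two indices are
*ratios* of reflectances and do not. Including them biases fractions in
mixed pixels even with perfect endmembers and no noise (errors up to ~0.1
in mid mixtures on synthetic scenes). The indices instead do the jobs they
are suited to: NDVI orders observations for compositing and thresholds
vegetation/bare candidates, NDWI thresholds water candidates. Six-band
fitting remains available (`bands = 1:6`) for comparability with pipelines
that unmix the full feature stack.

**Endmember automation.** Production workflows often draw endmember regions
of interest by hand. Here the step is automated and reproducible:
candidates are thresholded on the composite (NDVI > 0.8 for vegetation,
NDVI < 0.2 for bare, NDWI > 0.3 for water; the water threshold is exposed
in `select_endmember_candidates()` since conventions vary), pixels meeting
the water criterion are removed from the bare pool (low NDVI alone cannot
separate dark water from soil), and each class signature is the
componentwise median of its purest quartile of candidates, ranked by a
class-specific purity index — NDVI for vegetation, broadband brightness for
bare (bare soil is the brightest scene component; ranking bare by *low*
NDVI would promote water-contaminated pixels), NDWI for water. The median
over a sizeable quantile matters under noise: the mean of a narrowly
ranked tail inherits the selection bias of whatever noise pushed those
pixels up the ranking. A plain mean over all candidates is available as
`strategy = "mean"`.

## Phenology reconstruction

The per-pixel NDVI series is processed in a fixed order:

1. **Linear gap-fill** on the native irregular acquisition axis: cloud-masked
   observations are replaced by linear interpolation between the nearest
   valid neighbours in time; leading/trailing gaps extend the nearest valid
   value. Pixels with no valid observation at all become no-data rather than
   errors.
2. **10-day compositing**: slot value = arithmetic mean of gap-filled values
   whose DOY falls in the slot.
3. **Compound upper-envelope smoothing** (`rmmeh_smooth()`): per pass, each
   interior slot becomes
   $\max\!\big(v_t,\ \mathrm{med}(v_{t-1}, v_t, v_{t+1}),\ \tfrac{v_{t-1}+v_{t+1}}{2}\big)$,
   endpoints copied; two passes by default. The max-with-original makes the
   smoother an upper envelope, matching the physics of residual cloud and
   shadow contamination, which can only bias NDVI downward. The smoother
   family is configurable behind this contract (window and pass count are
   parameters); any variant preserving the upper-envelope property can be
   substituted.

One convention is ours: an interval containing *no* acquisition at all
cannot be filled by step 1, so the same linear interpolation rule is
re-applied on the 36-slot axis between steps 2 and 3. Every pixel with at
least one valid observation therefore ends with 36 finite slots.

$NDVI_{\max}$ is taken from the *smoothed* series (first argmax on ties), so
the ratio in the coverage model is ≤ 1 by construction and coverage at the
peak slot equals $G_{\max}$ exactly.

Two side effects are worth knowing. The upper envelope slightly inflates
convex stretches of the trajectory (the neighbour mean exceeds the centre
value there), so shoulder-season slots are biased a few percent high on
smooth synthetic curves. And 10-day averaging flattens the peak slightly;
peak-slot recovery on synthetic scenes is exact to ±1 slot.

## The data cube

`assemble_cube()` applies the coverage model with three guard rails, all
package conventions where the product format is silent:

* negative $NDVI_t$ (shadow/water artifacts) clamps to 0 before the ratio;
* the ratio is clamped into $[0, G_{\max}]$;
* pixels with $NDVI_{\max}$ below `eps_floor` (default 0.05 — barren or
  water surfaces with no seasonality signal) get constant $G_t = G_{\max}$
  and an `aseasonal` flag, since the ratio would be numerically meaningless.

Files are written as 36-band TIFFs of integers $\mathrm{round}(G / 0.001)$
(half away from zero; banker's rounding would map an exact 0.0005 boundary
inconsistently), nodata −1, with the scale factor, nodata code, year,
affine transform and CRS in a JSON sidecar. In-file samples are unsigned
16-bit with a +1 offset so the −1 nodata code survives bit-exactly;
round-trips are exact at the integer level and within 0.0005 in coverage.
The environment's TIFF codec does not embed geokeys, hence the sidecar; the
pixel payload is a standard multi-page TIFF readable by any imaging tool.

## Cooling efficiency

Cooling efficiency (CE) is the LST reduction per 1% greenspace increase. In
a `window × window` neighbourhood (default 5×5) assumed to share one
climate background, LST is regressed by OLS on greenspace *in percent*, and
CE is the negated slope so that positive CE means cooling. Thermal
acquisition dates are matched to the cube slot with the nearest interval
midpoint (ties to the earlier slot). Windows are masked — not errored —
when fewer than `min_valid = 10` pairs are valid or the coverage standard
deviation is below `min_green_sd = 0.05`, where the slope is undefined or
noise-dominated; both cutoffs are package defaults, chosen as the loosest
values that keep the slope identifiable, and are exposed as arguments.
`window_sensitivity()` repeats the estimate over windows 5–13 and
summarises mean/median CE and estimable fraction per window; on synthetic
scenes the means agree within a few percent, so the window choice is not a
sensitive tuning knob.

The regression is computed for all centres simultaneously by sliding-window
sum accumulation (sums of $x$, $y$, $xy$, $x^2$, $y^2$ and counts), which
makes the estimator exactly equal to per-window `lm()` fits (tested) at a
fraction of the cost.

## Block-level validation

Cross-resolution comparisons aggregate *both* rasters onto a common block
grid (default 200 m, aligned to the raster transform) instead of resampling
pixel-to-pixel; blocks below 50% valid pixels are dropped.
`agreement_metrics()` reports $r^2$ as squared Pearson correlation —
invariant to affine rescaling of either series, appropriate when the two
sources measure greenness on different scales — together with RMSE, which
deliberately is not invariant. Fewer than 3 pairs or zero variance yields
an explicit `defined = FALSE` rather than an error or a fabricated number.

## The synthetic scene generator

Every stage is testable by parameter recovery on scenes with known truth.
The generator emulates, per pixel: a convex 3-class composition; a seasonal
vegetation reflectance trajectory; random patchy cloud occlusion; additive
Gaussian sensor noise; and an LST field linearly coupled to greenspace with
a known smooth slope field.

* **Fractions** are drawn per `patch_scale` × `patch_scale` block
  (Dirichlet means), with optional pixel-level Dirichlet texture inside
  mixed blocks. The reference scene uses concentration 2, giving
  within-neighbourhood coverage sd ≈ 0.3 — the pixel-to-pixel contrast of
  buildings beside street trees in a 10-m urban mosaic, and the variation
  the moving-window CE estimator depends on. A share of blocks is exactly
  pure (at least one per class, always), providing the pure pixels
  endmember extraction needs.
* **Phenology** is a baseline plus one or two logistic rise/fall pulses,
  normalised so the peak value is exactly baseline + amplitude. Logistic
  pulses were chosen for interpretable peak/rate parameters; any smooth
  family with controlled modality would do.
* **Endmember spectra**: vegetation red and NIR co-vary against a fixed sum
  so the vegetation endmember's NDVI tracks the scene phenology curve; bare
  and water are static (optionally jittered seasonally). Values are typical
  surface-reflectance magnitudes (peak vegetation NIR ≈ 0.48, bright soil
  0.20–0.35, dark water ≤ 0.08).
* **Clouds** are per-date, per-patch Bernoulli with probability 0.2;
  real spatial/temporal cloud statistics are not emulated.
* **CE truth** is a bilinear interpolation of uniform draws on a coarse
  node lattice (0.01–0.05 °C/%): smooth at window scale, consistent with
  the estimator's homogeneous-background assumption and with cooling
  efficiency tracking climate/urban-form gradients rather than parcel
  boundaries.

All randomness derives from one scene seed with a documented stream order
(fractions, then cloud schedule, then CE field; rendering noise on a
derived stream), so scenes are bit-reproducible.

The reference scene is 128 × 128 pixels (16-pixel patches), 73 observations
every 5 days, unimodal phenology peaking at DOY 200 with NDVI 0.15–0.9,
reflectance noise sd 0.01, 20% cloud cover, LST noise sd 0.5 °C. These
sizes keep the full annual pipeline under half a minute while leaving
every estimator's behaviour measurable; module tests use 32 × 32 variants.

**What passing tests do and do not show.** The generator's world is linear
mixing with Gaussian noise, a single scene-wide phenology, static
non-vegetation spectra, rectangular clouds, and no shadows, BRDF,
atmosphere, registration error or sensor PSF. Recovery results on it
validate the *algorithms* — solver optimality, compositing logic, smoother
contracts, estimator calibration — not performance on real imagery, where
endmember variability and shadow contamination dominate error budgets.

## Numerical choices and limitations

* Argmax ties in compositing and in $NDVI_{\max}$ go to the earliest
  observation/slot; the composite takes **all six bands jointly** from the
  argmax date, keeping signatures physically consistent.
* Index computations return invalid (not 0) on zero denominators, so
  degenerate pixels cannot masquerade as observations in compositing.
* A note on recovery floors: with reflectance noise sd 0.01, a single
  4-band constrained LS fit has an interior per-pixel error sd of ≈ 0.028
  at the reference endmember contrast — vegetation and water differ
  essentially only in NIR, which bounds the conditioning. Scene-level
  fraction RMSE at that noise level therefore settles near 0.024 (pure
  pixels clip smaller errors), whatever the endmember derivation does; the
  greenest composite's max-selection over noisy NDVI adds a small
  vegetation-ward bias on top. Sub-0.02 recovery at this noise level would
  require temporal averaging foreign to the greenest-composite design.
* Cross-year behaviour (multi-year stitching, leap-year alignment beyond
  the 366-day grid) and polygon-accurate boundary masking (only bounding
  boxes are supported) are out of scope.
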