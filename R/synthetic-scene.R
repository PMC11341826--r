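#' Seasonal vegetation phenology parameters
#'
#' Parameterises the annual NDVI trajectory of the vegetation endmember as a
#' baseline plus one (unimodal, e.g. tree crowns with a single growth peak) or
#' two (bimodal, e.g. grassland with spring and autumn growth) logistic
#' rise/fall pulses.
#'
#' @param baseline_ndvi Off-season NDVI, in `[0, 1)`.
#' @param amplitude Peak NDVI above baseline; `baseline_ndvi + amplitude`
#'   must not exceed 1.
#' @param peak_doys Day-of-year of each growth peak (1 value for unimodal,
#'   exactly 2 strictly increasing values for bimodal), in `[1, 366]`.
#' @param rise_rate,fall_rate Logistic steepness of green-up and senescence,
#'   in 1/day. Larger is steeper; 0.1/day gives a ~6-week transition.
#' @param mode `"unimodal"` or `"bimodal"`.
#' @param pulse_half_width Half-duration of each growth pulse in days
#'   (distance from peak to the logistic midpoints); default 45.
#' @return An object of class `phenology_params`.
#' @export
phenology_params <- function(baseline_ndvi = 0.15, amplitude = 0.75,
                             peak_doys = 200, rise_rate = 0.10,
                             fall_rate = 0.08,
                             mode = c("unimodal", "bimodal"),
                             pulse_half_width = 45) {
  mode <- match.arg(mode)
  stopifnot(baseline_ndvi >= 0, baseline_ndvi < 1, amplitude >= 0)
  if (baseline_ndvi + amplitude > 1 + 1e-12) {
    stop("baseline_ndvi + amplitude must be <= 1", call. = FALSE)
  }
  if (any(peak_doys < 1 | peak_doys > 366)) {
    stop("peak_doys must lie in [1, 366]", call. = FALSE)
  }
  if (is.unsorted(peak_doys, strictly = TRUE)) {
    stop("peak_doys must be strictly increasing", call. = FALSE)
  }
  n_expected <- if (mode == "bimodal") 2L else 1L
  if (length(peak_doys) != n_expected) {
    stop(sprintf("%s phenology requires exactly %d peak(s)", mode, n_expected),
         call. = FALSE)
  }
  stopifnot(rise_rate > 0, fall_rate > 0, pulse_half_width > 0)
  structure(list(baseline_ndvi = baseline_ndvi, amplitude = amplitude,
                 peak_doys = as.numeric(peak_doys), rise_rate = rise_rate,
                 fall_rate = fall_rate, mode = mode,
                 pulse_half_width = pulse_half_width),
            class = "phenology_params")
}

# One logistic rise/fall pulse, normalised so its value at the peak is 1.
logistic_pulse <- function(doy, peak, rise, fall, hw) {
  up <- function(d) stats::plogis(rise * (d - (peak - hw)))
  dn <- function(d) stats::plogis(-fall * (d - (peak + hw)))
  up(doy) * dn(doy) / (up(peak) * dn(peak))
}

#' Evaluate the vegetation NDVI trajectory
#'
#' The curve is `baseline + amplitude * max_j pulse_j(doy)` where each pulse
#' is a product of a rising and a falling logistic normalised to 1 at its
#' peak, so the value at a peak day equals exactly
#' `baseline_ndvi + amplitude` and the curve never leaves
#' `[baseline_ndvi, baseline_ndvi + amplitude]`.
#'
#' @param params A [phenology_params()] object.
#' @param doy Integer day(s) of year in `[1, 366]`; vectorised.
#' @return NDVI value(s), same length as `doy`.
#' @export
vegetation_ndvi_curve <- function(params, doy) {
  stopifnot(inherits(params, "phenology_params"))
  if (any(doy < 1 | doy > 366)) stop("doy must lie in [1, 366]", call. = FALSE)
  pulses <- vapply(params$peak_doys, function(p) {
    logistic_pulse(doy, p, params$rise_rate, params$fall_rate,
                   params$pulse_half_width)
  }, numeric(length(doy)))
  pulses <- matrix(pulses, nrow = length(doy))
  params$baseline_ndvi + params$amplitude * apply(pulses, 1, max)
}

#' Generate a spatially autocorrelated ground-truth fraction map
#'
#' The scene is tiled into `patch_scale` x `patch_scale` blocks. Each block
#' is either a pure patch of one class (with probability `pure_frac`,
#' guaranteeing spectrally pure pixels for endmember extraction) or a mixed
#' patch with a mean composition drawn from a Dirichlet distribution. With
#' the default `within_concentration = Inf`, pixels inside a block share the
#' block composition exactly (so a `patch_scale` covering the whole scene
#' yields a single shared fraction vector); a finite value adds pixel-level
#' texture by drawing each mixed-block pixel from
#' `Dirichlet(within_concentration * block_mean)`, emulating the strong
#' pixel-to-pixel land-cover contrast of urban mosaics while keeping the
#' block-scale spatial autocorrelation. Pure patches stay exactly pure.
#' Every pixel's 3-vector (vegetation, bare, water) lies on the unit
#' simplex.
#'
#' @param seed Integer seed; identical seeds yield identical rasters.
#' @param shape Integer `c(rows, cols)`.
#' @param patch_scale Patch side length in pixels (>= 1).
#' @param alpha Dirichlet concentration for mixed patch means, length 3.
#' @param pure_frac Probability that a patch is pure, split evenly over the
#'   three classes.
#' @param within_concentration Dirichlet concentration of pixels around
#'   their block mean; `Inf` (default) for block-constant fractions.
#' @return A rows x cols x 3 array; third dimension ordered
#'   (vegetation, bare, water).
#' @export
make_fraction_maps <- function(seed, shape, patch_scale,
                               alpha = c(1.2, 1.2, 0.6), pure_frac = 0.15,
                               within_concentration = Inf) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape <= 0)) {
    stop("shape must be two positive integers", call. = FALSE)
  }
  if (patch_scale < 1) stop("patch_scale must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  nbr <- ceiling(shape[1] / patch_scale)
  nbc <- ceiling(shape[2] / patch_scale)
  n_blocks <- nbr * nbc
  # Dirichlet via normalised gammas
  g <- matrix(stats::rgamma(n_blocks * 3, shape = rep(alpha, each = n_blocks)),
              n_blocks, 3)
  fr <- g / rowSums(g)
  is_pure <- stats::runif(n_blocks) < pure_frac
  pure_class <- sample.int(3, n_blocks, replace = TRUE)
  if (pure_frac > 0 && n_blocks >= 3) {
    # endmember extraction needs at least one pure patch per class
    for (k in 1:3) {
      if (!any(is_pure & pure_class == k)) {
        cand <- which(!is_pure)
        pick <- cand[sample.int(length(cand), 1)]
        is_pure[pick] <- TRUE
        pure_class[pick] <- k
      }
    }
  }
  fr[is_pure, ] <- 0
  fr[cbind(which(is_pure), pure_class[is_pure])] <- 1
  out <- array(NA_real_, dim = c(shape, 3L))
  row_block <- pmin((seq_len(shape[1]) - 1L) %/% patch_scale + 1L, nbr)
  col_block <- pmin((seq_len(shape[2]) - 1L) %/% patch_scale + 1L, nbc)
  block_id <- outer(row_block, col_block, function(r, c) (c - 1L) * nbr + r)
  for (k in 1:3) out[, , k] <- matrix(fr[block_id, k], shape[1], shape[2])
  if (is.finite(within_concentration)) {
    mixed_px <- which(!is_pure[block_id])
    if (length(mixed_px)) {
      m <- matrix(fr[block_id[mixed_px], ], ncol = 3)
      g <- matrix(stats::rgamma(length(mixed_px) * 3,
                                shape = within_concentration * m), ncol = 3)
      g <- g / rowSums(g)
      # degenerate all-zero gamma draws fall back to the block mean
      bad <- !is.finite(g[, 1])
      if (any(bad)) g[bad, ] <- m[bad, ]
      for (k in 1:3) {
        layer <- out[, , k]
        layer[mixed_px] <- g[, k]
        out[, , k] <- layer
      }
    }
  }
  out
}

#' Build the time-varying endmember spectral library
#'
#' Returns a function of day-of-year giving the 3 x 4 endmember reflectance
#' matrix (rows: vegetation, bare, water; columns: blue, green, red, NIR).
#' The vegetation red and NIR bands co-vary so that the vegetation
#' endmember's NDVI tracks `veg_params` exactly (their sum is held fixed);
#' bare and water spectra are static apart from an optional small seasonal
#' jitter.
#'
#' @param veg_params [phenology_params()] driving vegetation NDVI.
#' @param veg_rn_sum Fixed red + NIR total reflectance of vegetation.
#' @param jitter Amplitude of a sinusoidal seasonal perturbation added to the
#'   bare and water spectra (reflectance units; default 0).
#' @return `function(doy) -> 3x4 matrix`.
#' @export
endmember_spectra_fn <- function(veg_params = phenology_params(),
                                 veg_rn_sum = 0.5, jitter = 0) {
  force(veg_params); force(veg_rn_sum); force(jitter)
  function(doy) {
    stopifnot(length(doy) == 1, doy >= 1, doy <= 366)
    n <- vegetation_ndvi_curve(veg_params, doy)
    veg <- c(0.03, 0.06, veg_rn_sum * (1 - n) / 2, veg_rn_sum * (1 + n) / 2)
    j <- jitter * sin(2 * pi * doy / 365)
    bare <- c(0.20, 0.25, 0.30, 0.35) + j
    water <- c(0.06, 0.08, 0.05, 0.02) + j
    m <- rbind(vegetation = veg, bare = bare, water = water)
    colnames(m) <- GC_BANDS[1:4]
    m
  }
}

#' Generate a smooth positive cooling-efficiency truth field
#'
#' Uniform draws on a coarse node grid (spacing `patch_scale` pixels),
#' bilinearly interpolated to full resolution, in degrees C per 1%
#' greenspace coverage. The field is continuous and varies on the scale of
#' neighbourhoods, mirroring how cooling efficiency tracks climate and
#' urban-form gradients rather than jumping at parcel boundaries; this also
#' matches the moving-window estimator's assumption of a locally
#' homogeneous background. Used by [render_lst()] as the known slope field.
#'
#' @param seed Integer seed.
#' @param shape `c(rows, cols)`.
#' @param patch_scale Correlation length in pixels (node spacing).
#' @param range Two positive numbers, min and max slope.
#' @return rows x cols matrix, all values in `range`.
#' @export
make_ce_field <- function(seed, shape, patch_scale = 16,
                          range = c(0.01, 0.05)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape > 0), all(range >= 0))
  set.seed(as.integer(seed))
  nbr <- ceiling(shape[1] / patch_scale) + 1L
  nbc <- ceiling(shape[2] / patch_scale) + 1L
  nodes <- matrix(stats::runif(nbr * nbc, range[1], range[2]), nbr, nbc)
  # bilinear interpolation of the node lattice to pixel centres
  ri <- (seq_len(shape[1]) - 1) / patch_scale
  ci <- (seq_len(shape[2]) - 1) / patch_scale
  r0 <- pmin(floor(ri) + 1L, nbr - 1L); fr <- ri - (r0 - 1L)
  c0 <- pmin(floor(ci) + 1L, nbc - 1L); fc <- ci - (c0 - 1L)
  a <- nodes[r0, c0] * outer(1 - fr, 1 - fc) +
    nodes[r0 + 1L, c0] * outer(fr, 1 - fc) +
    nodes[r0, c0 + 1L] * outer(1 - fr, fc) +
    nodes[r0 + 1L, c0 + 1L] * outer(fr, fc)
  a
}

#' Assemble a fully ground-truthed synthetic scene
#'
#' Bundles everything needed to render a multispectral year of observations
#' with known answers: per-pixel endmember fractions, the scene-level
#' vegetation phenology, the time-varying endmember spectra, a per-date
#' cloud occlusion schedule, a cooling-efficiency slope field, and the sensor
#' noise level. Randomness is drawn from `seed` in a fixed documented order
#' (fractions, cloud schedule, CE field), so a given seed always produces the
#' same truth.
#'
#' The defaults define the package's reference scene: a 128 x 128 pixel city
#' patchwork (16-pixel patches), 73 observations every 5 days, unimodal
#' vegetation phenology peaking at DOY 200 with peak NDVI 0.9, additive
#' reflectance noise of sd 0.01, and 20% patchy cloud cover per date.
#'
#' @param seed Integer seed controlling all randomness.
#' @param shape `c(rows, cols)`.
#' @param doys Observation days of year.
#' @param veg_params Scene-level vegetation [phenology_params()].
#' @param patch_scale Patch side in pixels for fractions, clouds and CE.
#' @param within_concentration Pixel-level Dirichlet concentration around
#'   block means (see [make_fraction_maps()]); the reference scene uses 2,
#'   giving the strong pixel-to-pixel land-cover contrast of a 10-m urban
#'   mosaic (within-neighbourhood coverage sd ~0.3).
#' @param pure_frac Probability that a patch is spectrally pure (passed to
#'   [make_fraction_maps()]); at least one pure patch per class is always
#'   present when positive.
#' @param noise_sd Additive Gaussian reflectance noise sd.
#' @param cloud_prob Per-patch, per-date probability of cloud occlusion.
#' @param ce_range Range of the cooling-efficiency truth field (degC per %).
#' @param jitter Seasonal jitter of the non-vegetation endmember spectra.
#' @return An object of class `scene_truth` with fields `fraction_truth`,
#'   `phenology`, `endmember_spectra`, `cloud_schedule`, `ce_truth`,
#'   `noise_sd`, `doys`, `shape`, `transform`, `crs`.
#' @export
scene_truth <- function(seed = 1, shape = c(128, 128),
                        doys = seq(3, 363, by = 5),
                        veg_params = phenology_params(),
                        patch_scale = 16, within_concentration = 2,
                        pure_frac = 0.15, noise_sd = 0.01,
                        cloud_prob = 0.2, ce_range = c(0.01, 0.05),
                        jitter = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape > 0), all(doys >= 1 & doys <= 366),
            length(doys) >= 1)
  seed <- as.integer(seed)
  fractions <- make_fraction_maps(seed, shape, patch_scale,
                                  pure_frac = pure_frac,
                                  within_concentration = within_concentration)
  # cloud schedule: patch-level Bernoulli per date (stream order: after fractions)
  set.seed(seed + 1L)
  nbr <- ceiling(shape[1] / patch_scale)
  nbc <- ceiling(shape[2] / patch_scale)
  row_block <- pmin((seq_len(shape[1]) - 1L) %/% patch_scale + 1L, nbr)
  col_block <- pmin((seq_len(shape[2]) - 1L) %/% patch_scale + 1L, nbc)
  block_id <- outer(row_block, col_block, function(r, c) (c - 1L) * nbr + r)
  clouds <- array(FALSE, dim = c(shape, length(doys)))
  for (t in seq_along(doys)) {
    hit <- stats::runif(nbr * nbc) < cloud_prob
    clouds[, , t] <- matrix(hit[block_id], shape[1], shape[2])
  }
  ce <- make_ce_field(seed + 2L, shape, patch_scale, ce_range)
  structure(list(
    fraction_truth = fractions,
    phenology = veg_params,
    endmember_spectra = endmember_spectra_fn(veg_params, jitter = jitter),
    cloud_schedule = clouds,
    ce_truth = ce,
    noise_sd = noise_sd,
    seed = seed,
    doys = as.integer(doys),
    shape = shape,
    transform = gc_transform(),
    crs = "local"
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d pixels, %d dates (DOY %d-%d)\n",
              x$shape[1], x$shape[2], length(x$doys), min(x$doys), max(x$doys)))
  cat(sprintf("  phenology: %s, peak DOY %s, NDVI %.2f-%.2f\n",
              x$phenology$mode, paste(x$phenology$peak_doys, collapse = "/"),
              x$phenology$baseline_ndvi,
              x$phenology$baseline_ndvi + x$phenology$amplitude))
  cat(sprintf("  noise sd %.3f, mean cloud cover %.2f, CE %.3f-%.3f degC/%%\n",
              x$noise_sd, mean(x$cloud_schedule),
              min(x$ce_truth), max(x$ce_truth)))
  invisible(x)
}

#' Render the multispectral observation series of a synthetic scene
#'
#' For each observation date, per-pixel reflectance is the convex combination
#' of the date's endmember spectra weighted by the pixel's true fractions,
#' plus additive Gaussian sensor noise. Observations scheduled as clouded in
#' the scene truth carry a raised cloud probability so that downstream cloud
#' masking removes them.
#'
#' @param truth A [scene_truth()] object.
#' @param doys Days of year to render; defaults to `truth$doys` (must be a
#'   subset of them, since the cloud schedule is indexed by date).
#' @param seed Seed for the noise stream (default: derived from the scene).
#' @return A [reflectance_series()] whose cloud rasters are 100 for clouded
#'   pixels and 0 elsewhere.
#' @export
render_reflectance <- function(truth, doys = truth$doys, seed = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  if (length(doys) == 0) stop("doys must be nonempty", call. = FALSE)
  if (any(doys < 1 | doys > 366)) stop("doy out of [1, 366]", call. = FALSE)
  idx <- match(doys, truth$doys)
  if (anyNA(idx)) stop("doys must be among the scene's scheduled dates",
                       call. = FALSE)
  if (is.null(seed)) seed <- truth$seed + 3L  # noise stream follows the truth streams
  set.seed(as.integer(seed))
  sh <- truth$shape
  npix <- prod(sh)
  fr <- matrix(truth$fraction_truth, npix, 3)
  obs <- vector("list", length(doys))
  for (t in seq_along(doys)) {
    E <- truth$endmember_spectra(doys[t])    # 3 x 4
    refl <- fr %*% E                          # npix x 4
    if (truth$noise_sd > 0) {
      refl <- refl + matrix(stats::rnorm(npix * 4, 0, truth$noise_sd), npix, 4)
    }
    bands <- array(refl, dim = c(sh, 4L))
    cloud <- matrix(0, sh[1], sh[2])
    cloud[truth$cloud_schedule[, , idx[t]]] <- 100
    obs[[t]] <- list(doy = as.integer(doys[t]), bands = bands, cloud = cloud)
  }
  reflectance_series(obs, transform = truth$transform, crs = truth$crs)
}

#' Render a land-surface-temperature raster coupled to greenspace
#'
#' `LST = base_lst - ce_truth * (100 * greenspace) + noise`, so a pixel with
#' full greenspace cover and slope 0.03 degC/% sits 3 degC below `base_lst`.
#'
#' @param greenspace Coverage raster in `[0, 1]`.
#' @param ce_truth Slope raster (degC per 1% coverage), co-registered.
#' @param base_lst Background temperature, degC.
#' @param noise_sd Additive Gaussian noise sd, degC.
#' @param seed Integer seed.
#' @return LST matrix in degC.
#' @export
render_lst <- function(greenspace, ce_truth, base_lst = 40, noise_sd = 0.5,
                       seed = 1) {
  check_same_shape(greenspace, ce_truth, "greenspace and ce_truth")
  set.seed(as.integer(seed))
  lst <- base_lst - ce_truth * (100 * greenspace)
  if (noise_sd > 0) {
    lst <- lst + matrix(stats::rnorm(length(lst), 0, noise_sd),
                        nrow(lst), ncol(lst))
  }
  lst
}

#' Write a rendered scene to disk
#'
#' One multi-band TIFF per observation date (4 reflectance bands + cloud
#' probability) plus a plain-text JSON manifest listing the dates, seed
#' parameters and file names, and TIFFs of the fraction and CE truth.
#'
#' @param truth A [scene_truth()].
#' @param series The rendered [reflectance_series()].
#' @param dir Output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_scene <- function(truth, series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(series$obs))
  for (t in seq_along(series$obs)) {
    o <- series$obs[[t]]
    stack <- array(c(o$bands, o$cloud), dim = c(dim(o$bands)[1:2], 5L))
    files[t] <- file.path(dir, sprintf("scene_doy%03d.tif", o$doy))
    write_geo_tiff(set_geo(stack, series$transform, series$crs), files[t])
  }
  write_geo_tiff(set_geo(truth$fraction_truth, truth$transform, truth$crs),
                 file.path(dir, "fraction_truth.tif"))
  write_geo_tiff(set_geo(truth$ce_truth, truth$transform, truth$crs),
                 file.path(dir, "ce_truth.tif"))
  manifest <- list(
    doys = vapply(series$obs, function(o) o$doy, integer(1)),
    shape = truth$shape, noise_sd = truth$noise_sd, seed = truth$seed,
    phenology = unclass(truth$phenology), files = basename(files)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Directory containing `manifest.json` and per-date TIFFs.
#' @return A [reflectance_series()].
#' @export
read_scene <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  obs <- lapply(seq_along(man$doys), function(t) {
    stack <- read_geo_tiff(file.path(dir, man$files[t]))
    list(doy = as.integer(man$doys[t]), bands = unclass(stack)[, , 1:4],
         cloud = unclass(stack)[, , 5])
  })
  first <- read_geo_tiff(file.path(dir, man$files[1]))
  reflectance_series(obs, transform = geo_transform(first),
                     crs = geo_crs(first))
}
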