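#' Construct a reflectance observation series
#'
#' The raw observational input: an ordered list of acquisition dates, each
#' with a four-band (blue, green, red, NIR) surface-reflectance array and a
#' cloud raster (percent probability in `[0, 100]`, or logical mask). All
#' rasters must be co-registered; dates must be nondecreasing.
#'
#' @param obs List of `list(doy, bands, cloud)` entries; `bands` is a
#'   rows x cols x 4 array, `cloud` a matrix or logical matrix.
#' @param transform,crs Shared georeferencing.
#' @return An object of class `reflectance_series` with fields `obs`,
#'   `shape`, `transform`, `crs`. Each observation gains a logical `valid`
#'   matrix (all `TRUE` until cloud masking).
#' @export
reflectance_series <- function(obs, transform = gc_transform(), crs = "local") {
  if (length(obs) == 0) stop("series must contain observations", call. = FALSE)
  doys <- vapply(obs, function(o) as.numeric(o$doy), numeric(1))
  if (is.unsorted(doys)) stop("observation doys must be nondecreasing", call. = FALSE)
  sh <- dim(obs[[1]]$bands)[1:2]
  obs <- lapply(obs, function(o) {
    if (!identical(dim(o$bands)[1:2], sh) || dim(o$bands)[3] != 4L) {
      stop("all observations must share shape and have 4 bands", call. = FALSE)
    }
    check_same_shape(o$bands, o$cloud, "bands and cloud raster")
    if (is.null(o$valid)) o$valid <- matrix(TRUE, sh[1], sh[2])
    o
  })
  structure(list(obs = obs, shape = sh, transform = transform, crs = crs),
            class = "reflectance_series")
}

#' @export
print.reflectance_series <- function(x, ...) {
  doys <- vapply(x$obs, function(o) o$doy, numeric(1))
  cat(sprintf("<reflectance_series> %d x %d pixels, %d observations (DOY %d-%d)\n",
              x$shape[1], x$shape[2], length(doys), min(doys), max(doys)))
  cat(sprintf("  valid fraction: %.2f\n",
              mean(vapply(x$obs, function(o) mean(o$valid), numeric(1)))))
  invisible(x)
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - red) / (NIR + red)`. Pixels where the denominator is zero
#' (or either input is missing) are returned as `NA`.
#'
#' @param red,nir Co-registered reflectance rasters, values >= 0.
#' @return NDVI raster in `[-1, 1]` where defined.
#' @export
compute_ndvi <- function(red, nir) {
  check_same_shape(red, nir, "red and NIR")
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Normalized difference water index (McFeeters form)
#'
#' `NDWI = (green - NIR) / (green + NIR)`; positive over open water. The
#' green-vs-NIR dialect is used because the index serves water-endmember
#' detection here.
#'
#' @param green,nir Co-registered reflectance rasters, values >= 0.
#' @return NDWI raster in `[-1, 1]` where defined; zero denominators are `NA`.
#' @export
compute_ndwi <- function(green, nir) {
  check_same_shape(green, nir, "green and NIR")
  den <- green + nir
  out <- (green - nir) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Mask cloud-contaminated pixels
#'
#' Pixels whose cloud probability is at or above `prob_threshold` percent
#' (or whose logical cloud mask is `TRUE`) are flagged invalid in the
#' observation's `valid` matrix. Reflectance values are left untouched;
#' downstream stages consult the validity flags.
#'
#' @param series A [reflectance_series()].
#' @param prob_threshold Percent in `[0, 100]`; default 50.
#' @return The series with updated `valid` matrices.
#' @export
apply_cloud_mask <- function(series, prob_threshold = 50) {
  stopifnot(inherits(series, "reflectance_series"))
  if (prob_threshold < 0 || prob_threshold > 100) {
    stop("prob_threshold must lie in [0, 100]", call. = FALSE)
  }
  series$obs <- lapply(series$obs, function(o) {
    clouded <- if (is.logical(o$cloud)) o$cloud else o$cloud >= prob_threshold
    o$valid <- o$valid & !clouded
    o
  })
  series
}

#' Assemble a six-band feature image from one observation
#'
#' @param bands rows x cols x 4 reflectance array.
#' @param valid Logical validity matrix.
#' @param doy Acquisition day of year.
#' @param transform,crs Georeferencing.
#' @return An object of class `feature_image`: rows x cols x 6 `bands`
#'   (ordered per [GC_BANDS]) plus `valid`, with invalid pixels `NA` in every
#'   band.
#' @export
feature_image <- function(bands, valid = NULL, doy = NA_integer_,
                          transform = gc_transform(), crs = "local") {
  sh <- dim(bands)[1:2]
  if (is.null(valid)) valid <- matrix(TRUE, sh[1], sh[2])
  ndvi <- compute_ndvi(bands[, , 3], bands[, , 4])
  ndwi <- compute_ndwi(bands[, , 2], bands[, , 4])
  feat <- array(c(bands, ndvi, ndwi), dim = c(sh, 6L))
  valid <- valid & !is.na(ndvi) & !is.na(ndwi) &
    apply(!is.na(bands), c(1, 2), all)
  feat[rep(!valid, 6)] <- NA_real_
  structure(list(bands = feat, valid = valid, doy = doy,
                 transform = transform, crs = crs),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("<feature_image> %d x %d pixels, DOY %s, %.0f%% valid\n",
              nrow(x$valid), ncol(x$valid),
              ifelse(is.na(x$doy), "?", x$doy), 100 * mean(x$valid)))
  invisible(x)
}

#' Build the six-band feature time series
#'
#' For every observation of a (cloud-masked) reflectance series, computes
#' NDVI and NDWI and stacks them after the four reflectance bands. Pixel
#' validity propagates from the cloud mask and from undefined index values.
#'
#' @param series A [reflectance_series()], normally after
#'   [apply_cloud_mask()].
#' @return List of [feature_image()] objects, one per observation.
#' @export
build_feature_stack <- function(series) {
  stopifnot(inherits(series, "reflectance_series"))
  if (length(series$obs) == 0) stop("empty series", call. = FALSE)
  lapply(series$obs, function(o) {
    feature_image(o$bands, o$valid, o$doy, series$transform, series$crs)
  })
}
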