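#' Linear gap-filling along the time axis
#'
#' Replaces invalid (cloud-masked) values with linear interpolation between
#' the nearest valid observations in time; leading and trailing gaps are
#' extended with the nearest valid value. A series with no valid value at
#' all is returned as all-`NA` (a no-data pixel, not an error).
#'
#' @param doys Observation times (days of year), length `n`.
#' @param values Length-`n` vector or `n` x `p` matrix (pixels in columns).
#' @param valid Logical mask of genuinely observed entries; defaults to
#'   `!is.na(values)`.
#' @return Filled values, same shape as `values`.
#' @export
gap_fill_linear <- function(doys, values, valid = NULL) {
  vec_in <- is.null(dim(values))
  v <- if (vec_in) matrix(values, ncol = 1) else values
  if (is.null(valid)) valid <- !is.na(v)
  valid <- valid & !is.na(v)
  stopifnot(length(doys) == nrow(v))
  out <- v
  for (j in seq_len(ncol(v))) {
    ok <- valid[, j]
    n_ok <- sum(ok)
    if (n_ok == 0) {
      out[, j] <- NA_real_
    } else if (n_ok == 1) {
      out[, j] <- v[ok, j]
    } else if (n_ok < nrow(v)) {
      out[, j] <- stats::approx(doys[ok], v[ok, j], xout = doys,
                                method = "linear", rule = 2, ties = "ordered")$y
    }
  }
  if (vec_in) out[, 1] else out
}

#' RMMEH compound upper-envelope smoothing
#'
#' One pass replaces each interior slot `t` by
#' `max(v_t, median(v_{t-1}, v_t, v_{t+1}), (v_{t-1} + v_{t+1}) / 2)`;
#' endpoints are copied unchanged. The maximum with the original value makes
#' the smoother an upper envelope, matching the physics of NDVI time series
#' where residual cloud contamination biases values downward. Series shorter
#' than 3 slots are returned unchanged.
#'
#' @param x Length-36 (or any length) vector, or a `p` x 36 matrix with
#'   pixels in rows and slots in columns.
#' @param passes Number of smoothing passes (default 2).
#' @return Smoothed values, same shape; always >= `x` pointwise.
#' @export
rmmeh_smooth <- function(x, passes = 2) {
  vec_in <- is.null(dim(x))
  v <- if (vec_in) matrix(x, nrow = 1) else x
  m <- ncol(v)
  if (m >= 3) {
    for (p in seq_len(passes)) {
      left <- v[, 1:(m - 2), drop = FALSE]
      mid <- v[, 2:(m - 1), drop = FALSE]
      right <- v[, 3:m, drop = FALSE]
      med3 <- left + mid + right - pmax(left, mid, right) - pmin(left, mid, right)
      v[, 2:(m - 1)] <- pmax(mid, med3, (left + right) / 2)
    }
  }
  if (vec_in) v[1, ] else v
}

#' Annual maximum of a smoothed NDVI series
#'
#' @param smoothed Length-36 vector, or `p` x 36 matrix (pixels in rows).
#' @return For a vector, `list(ndvi_max, peak_slot)` (first slot attaining
#'   the maximum); for a matrix, a list of two length-`p` vectors. All-`NA`
#'   pixels yield `NA` in both.
#' @export
extract_ndvi_max <- function(smoothed) {
  vec_in <- is.null(dim(smoothed))
  v <- if (vec_in) matrix(smoothed, nrow = 1) else smoothed
  ndvi_max <- rep(NA_real_, nrow(v))
  peak <- rep(NA_integer_, nrow(v))
  has <- rowSums(!is.na(v)) > 0
  if (any(has)) {
    ndvi_max[has] <- apply(v[has, , drop = FALSE], 1, max, na.rm = TRUE)
    peak[has] <- apply(v[has, , drop = FALSE], 1, which.max)
  }
  if (vec_in) list(ndvi_max = ndvi_max[1], peak_slot = peak[1])
  else list(ndvi_max = ndvi_max, peak_slot = peak)
}

#' Reconstruct per-pixel 36-slot NDVI phenology
#'
#' The three-stage reconstruction chain, in fixed order: (i) linear
#' gap-filling of the cloud-masked NDVI observations on their native
#' irregular DOY axis, (ii) 10-day mean compositing onto the 36-interval
#' annual grid, (iii) compound median/mean upper-envelope smoothing
#' ([rmmeh_smooth()]). Intervals that contain no observation date at all are
#' filled by the same linear interpolation rule on the slot axis before
#' smoothing, so every pixel with at least one valid observation ends with
#' 36 finite slots.
#'
#' @param series A cloud-masked [reflectance_series()].
#' @param grid A [temporal_grid()].
#' @param passes Smoothing passes (default 2).
#' @return An `ndvi_phenology`: `slots` (rows x cols x 36 array),
#'   `ndvi_max` and `peak_slot` matrices, `empty_slots` (36-vector count of
#'   pixels empty per slot before slot-filling), `valid` matrix
#'   (pixels with >= 1 valid observation), and georeferencing.
#' @export
build_ndvi_phenology <- function(series, grid = temporal_grid(), passes = 2) {
  stopifnot(inherits(series, "reflectance_series"))
  sh <- series$shape
  npix <- prod(sh)
  n_obs <- length(series$obs)
  doys <- vapply(series$obs, function(o) as.numeric(o$doy), numeric(1))
  vals <- matrix(NA_real_, n_obs, npix)
  valid <- matrix(FALSE, n_obs, npix)
  for (t in seq_len(n_obs)) {
    o <- series$obs[[t]]
    nd <- compute_ndvi(o$bands[, , 3], o$bands[, , 4])
    vals[t, ] <- as.vector(nd)
    valid[t, ] <- as.vector(o$valid & !is.na(nd))
  }
  filled <- gap_fill_linear(doys, vals, valid)
  slots <- composite_10day(doys, filled, grid = grid)   # 36 x npix
  empty_slots <- rowSums(is.na(slots) & rep(colSums(valid) > 0, each = 36))
  slots <- gap_fill_linear(grid$midpoints, slots)
  smoothed <- rmmeh_smooth(t(slots), passes = passes)    # npix x 36
  mx <- extract_ndvi_max(smoothed)
  structure(list(
    slots = array(t(smoothed), dim = c(36L, sh))|> aperm(c(2, 3, 1)),
    ndvi_max = matrix(mx$ndvi_max, sh[1], sh[2]),
    peak_slot = matrix(mx$peak_slot, sh[1], sh[2]),
    empty_slots = empty_slots,
    valid = matrix(colSums(valid) > 0, sh[1], sh[2]),
    grid = grid, passes = passes,
    transform = series$transform, crs = series$crs
  ), class = "ndvi_phenology")
}

#' @export
print.ndvi_phenology <- function(x, ...) {
  cat(sprintf("<ndvi_phenology> %d x %d pixels, 36 slots, %.0f%% valid\n",
              nrow(x$valid), ncol(x$valid), 100 * mean(x$valid)))
  cat(sprintf("  NDVI_max: median %.3f; modal peak slot %d\n",
              stats::median(x$ndvi_max, na.rm = TRUE),
              as.integer(names(sort(table(x$peak_slot), decreasing = TRUE))[1])))
  invisible(x)
}
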