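#' The 36-interval annual temporal grid
#'
#' One calendar year is partitioned into 36 ten-day intervals: interval `k`
#' (for `k` in 1..35) covers DOY `10(k-1)+1` to `10k`, and interval 36
#' absorbs the year's tail, DOY 351 to `year_length`. This convention keeps
#' every annual product at exactly 36 layers, matching the data-record
#' format.
#'
#' @param year_length 365 or 366.
#' @return An object of class `temporal_grid` with fields `year_length`,
#'   `n_intervals`, `starts`, `ends`, `midpoints`.
#' @export
temporal_grid <- function(year_length = 365) {
  if (!year_length %in% c(365, 366)) {
    stop("year_length must be 365 or 366", call. = FALSE)
  }
  starts <- 10 * (0:35) + 1
  ends <- c(10 * (1:35), year_length)
  structure(list(year_length = as.integer(year_length), n_intervals = 36L,
                 starts = starts, ends = ends,
                 midpoints = (starts + ends) / 2),
            class = "temporal_grid")
}

#' Map a day of year to its 10-day interval
#'
#' `k = min(ceiling(doy / 10), 36)`: DOY 41-50 falls in interval 5, and the
#' final days of the year (DOY 361+) are clamped into interval 36.
#'
#' @param doy Integer day(s) of year; vectorised.
#' @param year_length 365 or 366.
#' @return Integer interval index in 1..36.
#' @export
interval_index <- function(doy, year_length = 365) {
  if (any(doy < 1 | doy > year_length)) {
    stop(sprintf("doy must lie in [1, %d]", year_length), call. = FALSE)
  }
  pmin(ceiling(doy / 10), 36L)
}

#' Annual greenest composite ("quality mosaic")
#'
#' Per pixel, selects the single observation with the maximal valid NDVI and
#' takes all six feature bands jointly from that date, so the composited
#' signature remains physically consistent for unmixing. Ties are broken by
#' the earliest observation; pixels valid in no observation are invalid in
#' the composite.
#'
#' @param features List of [feature_image()] objects (from
#'   [build_feature_stack()]).
#' @return A [feature_image()]; its `doy` field is `NA` and a `pick` matrix
#'   attribute records the per-pixel source observation index.
#' @export
greenest_composite <- function(features) {
  if (length(features) == 0) stop("empty feature series", call. = FALSE)
  stopifnot(all(vapply(features, inherits, logical(1), "feature_image")))
  sh <- dim(features[[1]]$valid)
  best_ndvi <- matrix(-Inf, sh[1], sh[2])
  pick <- matrix(NA_integer_, sh[1], sh[2])
  for (t in seq_along(features)) {
    ndvi <- features[[t]]$bands[, , 5]
    better <- features[[t]]$valid & !is.na(ndvi) &
      (is.na(pick) | ndvi > best_ndvi)
    best_ndvi[better] <- ndvi[better]
    pick[better] <- t
  }
  bands <- array(NA_real_, dim = c(sh, 6L))
  for (t in seq_along(features)) {
    sel <- !is.na(pick) & pick == t
    if (!any(sel)) next
    for (b in 1:6) {
      layer <- bands[, , b]
      layer[sel] <- features[[t]]$bands[, , b][sel]
      bands[, , b] <- layer
    }
  }
  out <- structure(list(bands = bands, valid = !is.na(pick), doy = NA_integer_,
                        transform = features[[1]]$transform,
                        crs = features[[1]]$crs),
                   class = "feature_image")
  attr(out, "pick") <- pick
  out
}

#' Composite an irregular series onto the 10-day grid by averaging
#'
#' Slot `k` receives the arithmetic mean of all valid values whose DOY falls
#' in interval `k`; slots with no valid value are flagged empty (`NA`).
#'
#' @param doys Observation days of year, length `n`.
#' @param values Numeric vector of length `n`, or an `n` x `p` matrix
#'   (observations in rows, pixels in columns).
#' @param valid Logical mask, same shape as `values`; defaults to
#'   `!is.na(values)`.
#' @param grid A [temporal_grid()].
#' @return For vector input, a length-36 vector with `NA` for empty slots;
#'   for matrix input, a 36 x `p` matrix.
#' @export
composite_10day <- function(doys, values, valid = NULL, grid = temporal_grid()) {
  vec_in <- is.null(dim(values))
  v <- if (vec_in) matrix(values, ncol = 1) else values
  if (is.null(valid)) valid <- !is.na(v)
  valid <- valid & !is.na(v)
  stopifnot(length(doys) == nrow(v))
  k <- interval_index(doys, grid$year_length)
  vz <- v
  vz[!valid] <- 0
  sums <- rowsum(vz, group = k)
  counts <- rowsum(valid + 0, group = k)
  out <- matrix(NA_real_, 36L, ncol(v))
  rows <- as.integer(rownames(sums))
  out[rows, ] <- sums / ifelse(counts > 0, counts, NA_real_)
  if (vec_in) out[, 1] else out
}
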