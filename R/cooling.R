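#' Match LST acquisition dates to cube slots
#'
#' Thermal scenes arrive on arbitrary days; each one is paired with the
#' 10-day cube slot whose interval midpoint is nearest in time (ties go to
#' the earlier slot), mirroring nearest-date matching between sensors with
#' different temporal resolutions.
#'
#' @param lst_doys Integer days of year of the LST scenes.
#' @param grid A [temporal_grid()] (or a `greenspace_cube`, from which the
#'   default grid is assumed).
#' @return A tibble with columns `lst_doy` and `slot`.
#' @export
match_lst_to_cube <- function(lst_doys, grid = temporal_grid()) {
  if (inherits(grid, "greenspace_cube")) grid <- temporal_grid()
  if (any(lst_doys < 1 | lst_doys > 366)) {
    stop("lst_doys must lie in [1, 366]", call. = FALSE)
  }
  slot <- vapply(lst_doys, function(d) {
    which.min(abs(grid$midpoints - d))  # which.min takes the earliest tie
  }, integer(1))
  tibble::tibble(lst_doy = as.integer(lst_doys), slot = slot)
}

# Sliding-window sums by offset accumulation over a padded matrix.
window_sums <- function(x, h) {
  n <- nrow(x); m <- ncol(x)
  pad <- matrix(0, n + 2 * h, m + 2 * h)
  pad[(h + 1):(h + n), (h + 1):(h + m)] <- x
  acc <- matrix(0, n, m)
  for (di in -h:h) for (dj in -h:h) {
    acc <- acc + pad[(h + 1 + di):(h + n + di), (h + 1 + dj):(h + m + dj)]
  }
  acc
}

#' Moving-window cooling-efficiency estimation
#'
#' For each pixel, an ordinary least-squares regression of LST (degC) on
#' greenspace coverage expressed in percent (0-100) is fitted over the
#' surrounding `window` x `window` neighbourhood, under the assumption that
#' pixels within the window share the same climate background so LST
#' differences are attributable to greenspace differences. The cooling
#' efficiency is the negated slope, so `CE >= 0` means greenspace cools.
#' Centres are masked (not errors) where fewer than `min_valid` pixel pairs
#' are valid or where greenspace varies by less than `min_green_sd`
#' (coverage units), since the slope is then undefined or unstable.
#'
#' @param lst LST raster, degC.
#' @param green Greenspace coverage raster in `[0, 1]`, co-registered.
#' @param window Odd window side in pixels (default 5).
#' @param min_valid Minimum valid pairs in the window (default 10).
#' @param min_green_sd Minimum coverage standard deviation (default 0.05).
#' @return A `ce_map`: `ce` (degC per 1% coverage), `r2`, `n_used` matrices
#'   and the `window` used.
#' @export
cooling_efficiency <- function(lst, green, window = 5, min_valid = 10,
                               min_green_sd = 0.05) {
  check_same_shape(lst, green, "LST and greenspace")
  if (window %% 2 != 1 || window < 3) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  h <- (window - 1) %/% 2
  x <- 100 * green            # percent units match the CE definition
  y <- lst
  ok <- is.finite(x) & is.finite(y)
  xz <- ifelse(ok, x, 0)
  yz <- ifelse(ok, y, 0)
  n <- window_sums(ok + 0, h)
  sx <- window_sums(xz, h)
  sy <- window_sums(yz, h)
  sxx <- window_sums(xz^2, h)
  syy <- window_sums(yz^2, h)
  sxy <- window_sums(xz * yz, h)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  cxy <- n * sxy - sx * sy
  slope <- cxy / vx
  r2 <- cxy^2 / (vx * vy)
  sd_green <- sqrt(pmax(vx, 0) / (n * pmax(n - 1, 1))) / 100
  keep <- n >= max(min_valid, 3) & sd_green >= min_green_sd & vx > 0 & vy > 0
  ce <- -slope
  ce[!keep] <- NA_real_
  r2[!keep] <- NA_real_
  structure(list(ce = ce, r2 = r2, n_used = n, window = as.integer(window),
                 transform = geo_transform(lst), crs = geo_crs(lst)),
            class = "ce_map")
}

#' @export
print.ce_map <- function(x, ...) {
  cat(sprintf("<ce_map> %d x %d pixels, %d x %d window, %.0f%% estimable\n",
              nrow(x$ce), ncol(x$ce), x$window, x$window,
              100 * mean(is.finite(x$ce))))
  cat(sprintf("  CE degC/%%: median %.4f, mean %.4f; median r2 %.2f\n",
              stats::median(x$ce, na.rm = TRUE), mean(x$ce, na.rm = TRUE),
              stats::median(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' Window-size sensitivity of cooling-efficiency estimates
#'
#' Re-estimates the CE map for each candidate window size and summarises the
#' result, the standard check that the choice of neighbourhood size has
#' minimal impact on the estimated cooling effect.
#'
#' @param lst,green As in [cooling_efficiency()].
#' @param windows Odd window sides (default `c(5, 7, 9, 11, 13)`).
#' @param ... Passed on to [cooling_efficiency()].
#' @return A tibble with one row per window: `window`, `mean_ce`,
#'   `median_ce`, `sd_ce`, `valid_frac`.
#' @export
window_sensitivity <- function(lst, green, windows = c(5, 7, 9, 11, 13), ...) {
  stopifnot(all(windows %% 2 == 1 & windows >= 3))
  purrr::map_dfr(windows, function(w) {
    cem <- cooling_efficiency(lst, green, window = w, ...)
    tibble::tibble(
      window = as.integer(w),
      mean_ce = mean(cem$ce, na.rm = TRUE),
      median_ce = stats::median(cem$ce, na.rm = TRUE),
      sd_ce = stats::sd(cem$ce, na.rm = TRUE),
      valid_frac = mean(is.finite(cem$ce))
    )
  })
}
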