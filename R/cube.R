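#' Assemble the annual greenspace data cube
#'
#' Per pixel and 10-day slot `t`, coverage is
#' `G_t = G_max * max(NDVI_t, 0) / NDVI_max`, clamped to `[0, G_max]`:
#' the annual maximum sub-pixel greenspace fraction modulated by the
#' normalised NDVI phenology. Negative NDVI (shadow or water artifacts) is
#' clamped to zero before the ratio. Pixels whose smoothed `NDVI_max` falls
#' below `eps_floor` have no meaningful seasonality signal; they receive a
#' constant `G_t = G_max` in every slot and are flagged aseasonal.
#'
#' @param gmax `G_max` matrix (vegetation fraction of the greenest
#'   composite; see [gmax_layer()]) or a `fraction_map`.
#' @param phen An `ndvi_phenology` from [build_ndvi_phenology()].
#' @param year Calendar year tag (metadata only).
#' @param eps_floor NDVI_max floor below which a pixel is treated as
#'   aseasonal (default 0.05).
#' @return A `greenspace_cube`: `layers` (rows x cols x 36, in `[0, 1]`),
#'   `year`, `scale_factor` (0.001), `nodata_code` (-1), `aseasonal` and
#'   `valid` matrices, and georeferencing.
#' @export
assemble_cube <- function(gmax, phen, year = NA_integer_, eps_floor = 0.05) {
  if (inherits(gmax, "fraction_map")) gmax <- gmax_layer(gmax)
  stopifnot(inherits(phen, "ndvi_phenology"))
  check_same_shape(gmax, phen$ndvi_max, "G_max and phenology")
  sh <- dim(gmax)
  valid <- !is.na(gmax) & phen$valid
  aseasonal <- valid & phen$ndvi_max < eps_floor
  layers <- array(NA_real_, dim = c(sh, 36L))
  ratio_den <- ifelse(aseasonal | !valid, NA_real_, phen$ndvi_max)
  for (k in 1:36) {
    ndvi_t <- pmax(phen$slots[, , k], 0)
    g <- gmax * ndvi_t / ratio_den
    g <- pmin(pmax(g, 0), gmax)
    g[aseasonal] <- gmax[aseasonal]
    g[!valid] <- NA_real_
    layers[, , k] <- g
  }
  structure(list(layers = layers, year = year, scale_factor = 0.001,
                 nodata_code = -1L, aseasonal = aseasonal, valid = valid,
                 transform = geo_transform(gmax) %||% phen$transform,
                 crs = phen$crs),
            class = "greenspace_cube")
}

#' @export
print.greenspace_cube <- function(x, ...) {
  cat(sprintf("<greenspace_cube> %d x %d pixels x 36 ten-day layers%s\n",
              dim(x$layers)[1], dim(x$layers)[2],
              if (is.na(x$year)) "" else paste0(" (", x$year, ")")))
  cat(sprintf("  coverage: mean %.3f, max %.3f; %.0f%% valid, %.1f%% aseasonal\n",
              mean(x$layers, na.rm = TRUE), max(x$layers, na.rm = TRUE),
              100 * mean(x$valid), 100 * mean(x$aseasonal)))
  invisible(x)
}

#' Write a greenspace cube as a 36-band integer-scaled TIFF
#'
#' Coverage is stored as integers `round(G / 0.001)` (half away from zero),
#' one band per 10-day interval, with nodata coded as -1; the scale factor,
#' nodata code, year and georeferencing are recorded in a JSON sidecar.
#' Integers are carried in unsigned 16-bit samples with a +1 offset so that
#' the round trip is bit-exact.
#'
#' @param cube A `greenspace_cube`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "greenspace_cube"))
  codes <- round_half_away(cube$layers / cube$scale_factor)
  codes[is.na(codes)] <- cube$nodata_code
  pages <- lapply(1:36, function(k) (codes[, , k] + 1 + 0.1) / 65535)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!isTRUE(ok > 0)) stop("failed to write cube TIFF: ", path, call. = FALSE)
  meta <- list(driver = "greencube-cube", n_bands = 36L,
               scale_factor = cube$scale_factor,
               nodata = cube$nodata_code, offset = 1L,
               year = cube$year, transform = cube$transform, crs = cube$crs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a greenspace cube written by [write_cube()]
#'
#' @param path File path.
#' @return A `greenspace_cube` with physical coverage values (integer codes
#'   times the recorded scale factor); nodata cells are `NA`, never zero.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 36L) {
    stop(sprintf("cube format error: expected 36 bands, found %d",
                 length(pages)), call. = FALSE)
  }
  sh <- dim(pages[[1]])
  layers <- array(NA_real_, dim = c(sh, 36L))
  for (k in 1:36) {
    code <- pages[[k]] - meta$offset
    g <- code * meta$scale_factor
    g[code == meta$nodata] <- NA_real_
    layers[, , k] <- g
  }
  valid <- !is.na(layers[, , 1])
  structure(list(layers = layers,
                 year = if (is.null(meta$year)) NA_integer_ else meta$year,
                 scale_factor = meta$scale_factor,
                 nodata_code = meta$nodata,
                 aseasonal = NULL, valid = valid,
                 transform = unlist(meta$transform), crs = meta$crs),
            class = "greenspace_cube")
}

#' Crop a raster or cube to a rectangular boundary
#'
#' Minimal boundary masking: keeps pixels whose centre falls inside the
#' supplied axis-aligned bounding box (map units). Cells outside are set to
#' `NA`. Polygon boundaries from vector files should be rasterised upstream;
#' this package operates on their bounding boxes.
#'
#' @param x Matrix or rows x cols x b array with a `transform` attribute, or
#'   a `greenspace_cube`.
#' @param bbox `c(xmin, ymin, xmax, ymax)` in map units.
#' @return Same type as `x`, masked.
#' @export
crop_to_bbox <- function(x, bbox) {
  stopifnot(length(bbox) == 4, bbox[1] < bbox[3], bbox[2] < bbox[4])
  is_cube <- inherits(x, "greenspace_cube")
  tr <- if (is_cube) x$transform else geo_transform(x)
  if (is.null(tr)) stop("raster has no georeferencing", call. = FALSE)
  v <- if (is_cube) x$layers else x
  d <- dim(v)
  xs <- tr[1] + (seq_len(d[2]) - 0.5) * tr[2]
  ys <- tr[4] + (seq_len(d[1]) - 0.5) * tr[6]
  keep_col <- xs >= bbox[1] & xs <= bbox[3]
  keep_row <- ys >= bbox[2] & ys <= bbox[4]
  mask <- !outer(keep_row, keep_col, "&")
  if (length(d) == 3) {
    for (k in seq_len(d[3])) {
      layer <- v[, , k]; layer[mask] <- NA_real_; v[, , k] <- layer
    }
  } else {
    v[mask] <- NA_real_
  }
  if (is_cube) {
    x$layers <- v
    x$valid <- x$valid & !mask
    x
  } else {
    v
  }
}
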