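#' Band order used throughout the package
#'
#' Feature images carry six bands in this fixed order: the four reflectance
#' bands blue, green, red, NIR, followed by the two derived indices NDVI and
#' NDWI. All unmixing signatures and written files follow the same order.
#'
#' @format Character vector of length 6.
#' @export
GC_BANDS <- c("blue", "green", "red", "nir", "ndvi", "ndwi")

#' Build an affine geotransform
#'
#' GDAL-style 6-element geotransform `(x0, dx, 0, y0, 0, -dy)` for a
#' north-up raster whose upper-left corner is at `(origin_x, origin_y)` and
#' whose pixels are `px` metres on a side.
#'
#' @param origin_x,origin_y Upper-left corner coordinates (metres).
#' @param px Pixel size in metres (default 10, the native resolution of the
#'   reflectance data this pipeline targets).
#' @return Numeric vector of length 6.
#' @export
gc_transform <- function(origin_x = 0, origin_y = 0, px = 10) {
  stopifnot(is.numeric(px), length(px) == 1, px > 0)
  c(origin_x, px, 0, origin_y, 0, -px)
}

#' Attach georeferencing to a matrix or array
#'
#' Rasters in this package are plain matrices (single band) or 3-d arrays
#' (row x col x band) carrying a `transform` attribute (see [gc_transform()])
#' and a `crs` tag. Georeferencing is required by [block_aggregate()] and the
#' file writers; purely numerical stages ignore it.
#'
#' @param x Matrix or array.
#' @param transform Affine geotransform, length 6.
#' @param crs Coordinate reference system tag (free-form string, e.g.
#'   `"EPSG:32614"`).
#' @return `x` with `transform` and `crs` attributes set.
#' @export
set_geo <- function(x, transform = gc_transform(), crs = "local") {
  stopifnot(is.numeric(transform), length(transform) == 6)
  attr(x, "transform") <- transform
  attr(x, "crs") <- crs
  x
}

geo_transform <- function(x) attr(x, "transform", exact = TRUE)
geo_crs <- function(x) attr(x, "crs", exact = TRUE) %||% "local"

#' @importFrom rlang %||%
NULL

pixel_size <- function(transform) {
  c(abs(transform[2]), abs(transform[6]))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

check_same_shape <- function(a, b, what = "rasters") {
  da <- c(dim(a) %||% length(a), 1L)[1:2]
  db <- c(dim(b) %||% length(b), 1L)[1:2]
  if (any(da != db)) {
    stop(sprintf("%s are not co-registered: shapes %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a raster to a multi-page TIFF with a JSON sidecar
#'
#' Single-band matrices and multi-band arrays are written one band per TIFF
#' page. Values are stored as 32-bit floats after an affine rescale to the
#' unit interval; the rescale parameters, geotransform, CRS and band count are
#' recorded in a `<path>.aux.json` sidecar so that [read_geo_tiff()] restores
#' physical values. `NA` cells are stored through an extra validity page.
#'
#' @param x Matrix or row x col x band array.
#' @param path Output file path.
#' @param transform,crs Georeferencing; defaults to attributes on `x`.
#' @return `path`, invisibly.
#' @export
write_geo_tiff <- function(x, path, transform = geo_transform(x), crs = geo_crs(x)) {
  v <- unclass(x)
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  stopifnot(length(dim(v)) == 3)
  has_na <- anyNA(v)
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(v)[3]), function(k) {
    p <- (v[, , k] - rng[1]) / span
    p[is.na(p)] <- 0
    p
  })
  if (has_na) {
    pages <- c(pages, lapply(seq_len(dim(v)[3]), function(k) {
      m <- matrix(1, nrow(v), ncol(v))
      m[is.na(v[, , k])] <- 0
      m
    }))
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  if (!isTRUE(ok > 0)) stop("failed to write TIFF: ", path, call. = FALSE)
  meta <- list(
    driver = "greencube-tiff",
    n_bands = dim(v)[3],
    value_min = rng[1], value_max = rng[2],
    has_mask = has_na,
    transform = transform %||% gc_transform(),
    crs = crs
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_geo_tiff()]
#'
#' @param path File path.
#' @return Matrix (single band) or array with `transform`/`crs` attributes;
#'   masked cells are `NA`.
#' @export
read_geo_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- meta$n_bands
  v <- array(NA_real_, dim = c(dim(pages[[1]])[1:2], nb))
  for (k in seq_len(nb)) {
    p <- pages[[k]] * (meta$value_max - meta$value_min) + meta$value_min
    if (isTRUE(meta$has_mask)) p[pages[[nb + k]] < 0.5] <- NA_real_
    v[, , k] <- p
  }
  if (nb == 1L) v <- v[, , 1]
  set_geo(v, unlist(meta$transform), meta$crs)
}
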