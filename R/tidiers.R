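#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

raster_to_tibble <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' @importFrom rlang .data :=
NULL

#' Tidy an endmember set into a long tibble
#'
#' @param x An `endmember_set`.
#' @param ... Unused.
#' @return Tibble with columns `class`, `band`, `value`.
#' @export
tidy.endmember_set <- function(x, ...) {
  s <- x$signatures
  tibble::tibble(
    class = rep(rownames(s), times = ncol(s)),
    band = factor(rep(colnames(s), each = nrow(s)), levels = GC_BANDS),
    value = as.vector(s)
  )
}

#' Tidy a fraction map into per-pixel rows
#'
#' @param x A `fraction_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, one column per endmember fraction, and
#'   `residual`; invalid pixels are dropped.
#' @export
tidy.fraction_map <- function(x, ...) {
  out <- raster_to_tibble(x$residual, "residual")
  for (cls in dimnames(x$fractions)[[3]]) {
    out[[cls]] <- as.vector(x$fractions[, , cls])
  }
  dplyr::filter(out[, c("row", "col", dimnames(x$fractions)[[3]], "residual")],
                as.vector(x$valid))
}

#' Tidy a cooling-efficiency map into per-pixel rows
#'
#' @param x A `ce_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `ce`, `r2`, `n_used`; masked pixels
#'   dropped.
#' @export
tidy.ce_map <- function(x, ...) {
  out <- raster_to_tibble(x$ce, "ce")
  out$r2 <- as.vector(x$r2)
  out$n_used <- as.vector(x$n_used)
  dplyr::filter(out, is.finite(.data$ce))
}

#' One-row summary of a cooling-efficiency map
#'
#' @param x A `ce_map`.
#' @param ... Unused.
#' @return Tibble with `window`, `mean_ce`, `median_ce`, `sd_ce`,
#'   `valid_frac`, `median_r2`.
#' @export
glance.ce_map <- function(x, ...) {
  tibble::tibble(
    window = x$window,
    mean_ce = mean(x$ce, na.rm = TRUE),
    median_ce = stats::median(x$ce, na.rm = TRUE),
    sd_ce = stats::sd(x$ce, na.rm = TRUE),
    valid_frac = mean(is.finite(x$ce)),
    median_r2 = stats::median(x$r2, na.rm = TRUE)
  )
}

#' Tidy a greenspace cube into a long slot table
#'
#' @param x A `greenspace_cube`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `slot`, `doy_mid`, `coverage`.
#' @export
tidy.greenspace_cube <- function(x, ...) {
  grid <- temporal_grid()
  d <- dim(x$layers)
  tibble::tibble(
    row = rep(rep(seq_len(d[1]), times = d[2]), times = 36),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = 36),
    slot = rep(1:36, each = d[1] * d[2]),
    doy_mid = rep(grid$midpoints, each = d[1] * d[2]),
    coverage = as.vector(x$layers)
  )
}

#' One-row summary of a greenspace cube
#'
#' @param x A `greenspace_cube`.
#' @param ... Unused.
#' @return Tibble with `year`, `n_layers`, `mean_coverage`, `max_coverage`,
#'   `valid_frac`, `aseasonal_frac`.
#' @export
glance.greenspace_cube <- function(x, ...) {
  tibble::tibble(
    year = x$year,
    n_layers = dim(x$layers)[3],
    mean_coverage = mean(x$layers, na.rm = TRUE),
    max_coverage = max(x$layers, na.rm = TRUE),
    valid_frac = mean(x$valid),
    aseasonal_frac = if (is.null(x$aseasonal)) NA_real_ else mean(x$aseasonal)
  )
}
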