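#' Aggregate a raster to block-level means
#'
#' Cross-resolution comparison protocol: the raster is tiled into square
#' blocks of `block_size_m` metres (default 200 m, i.e. 20 x 20 pixels at
#' 10 m), aligned to the raster's own transform, and each block receives the
#' mean over its valid pixels. Blocks whose valid-pixel fraction falls below
#' `min_valid_frac` are dropped. Aggregating both rasters of a comparison to
#' the same block grid sidesteps pixel-to-pixel resampling between
#' resolutions.
#'
#' @param x Matrix (or single-band array) with a `transform` attribute; see
#'   [set_geo()]. Missing georeferencing is an error.
#' @param block_size_m Block side in metres.
#' @param min_valid_frac Minimum valid fraction per block (default 0.5).
#' @return A tibble with columns `block_row`, `block_col`, `mean`,
#'   `n_valid`, `n_total`.
#' @export
block_aggregate <- function(x, block_size_m = 200, min_valid_frac = 0.5) {
  tr <- geo_transform(x)
  if (is.null(tr)) {
    stop("raster has no georeferencing; attach one with set_geo()", call. = FALSE)
  }
  v <- unclass(x)
  if (length(dim(v)) == 3) v <- v[, , 1]
  px <- pixel_size(tr)
  bp <- block_size_m / px
  if (any(abs(bp - round(bp)) > 1e-9)) {
    stop("block_size_m must be an integer multiple of the pixel size", call. = FALSE)
  }
  bp <- round(bp)
  br <- (seq_len(nrow(v)) - 1L) %/% bp[2] + 1L
  bc <- (seq_len(ncol(v)) - 1L) %/% bp[1] + 1L
  id_row <- matrix(br, nrow(v), ncol(v))
  id_col <- matrix(bc, nrow(v), ncol(v), byrow = TRUE)
  key <- paste(id_row, id_col, sep = ":")
  ok <- is.finite(v)
  df <- tibble::tibble(
    block_row = as.vector(id_row), block_col = as.vector(id_col),
    value = as.vector(v), valid = as.vector(ok)
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$block_row, .data$block_col),
    mean = mean(.data$value[.data$valid]),
    n_valid = sum(.data$valid),
    n_total = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::filter(out, .data$n_valid / .data$n_total >= min_valid_frac,
                       .data$n_valid > 0)
  dplyr::arrange(out, .data$block_row, .data$block_col)
}

#' Agreement metrics between two block-level series
#'
#' Pairs blocks by their `(block_row, block_col)` keys (or positionally for
#' plain numeric vectors) and reports `r2` -- the squared Pearson
#' correlation, invariant to affine rescaling of either series -- the root
#' mean squared difference `rmse`, and the pair count `n`. With fewer than 3
#' pairs or zero variance in either series, `r2` is returned as `NA` and
#' `defined` is `FALSE` rather than raising an error.
#'
#' @param a,b Tibbles from [block_aggregate()] or plain numeric vectors of
#'   equal length.
#' @return One-row tibble: `r2`, `rmse`, `n`, `defined`.
#' @export
agreement_metrics <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    j <- dplyr::inner_join(a, b, by = c("block_row", "block_col"),
                           suffix = c("_a", "_b"))
    va <- j$mean_a
    vb <- j$mean_b
  } else {
    stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
    va <- a; vb <- b
  }
  keep <- is.finite(va) & is.finite(vb)
  va <- va[keep]; vb <- vb[keep]
  n <- length(va)
  rmse <- if (n > 0) sqrt(mean((va - vb)^2)) else NA_real_
  defined <- n >= 3 && stats::sd(va) > 0 && stats::sd(vb) > 0
  r2 <- if (defined) stats::cor(va, vb)^2 else NA_real_
  tibble::tibble(r2 = r2, rmse = rmse, n = n, defined = defined)
}
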