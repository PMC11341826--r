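#' Map candidate endmember pixels by index thresholds
#'
#' Candidate regions for the three endmember classes are mapped from the
#' greenest composite by empirical index rules: vegetation where
#' `NDVI > ndvi_veg_min` (default 0.8), bare surface where
#' `NDVI < ndvi_bare_max` (default 0.2), water where
#' `NDWI > ndwi_water_min` (default 0.3). Masks are restricted to valid
#' pixels and may overlap (notably bare and water); overlap is resolved when
#' signatures are derived.
#'
#' @param composite A [feature_image()] (normally the greenest composite).
#' @param ndvi_veg_min,ndvi_bare_max,ndwi_water_min Thresholds in `[-1, 1]`.
#' @return Named list of three logical matrices: `vegetation`, `bare`,
#'   `water`.
#' @export
select_endmember_candidates <- function(composite, ndvi_veg_min = 0.8,
                                        ndvi_bare_max = 0.2,
                                        ndwi_water_min = 0.3) {
  stopifnot(inherits(composite, "feature_image"))
  thr <- c(ndvi_veg_min, ndvi_bare_max, ndwi_water_min)
  if (any(thr < -1 | thr > 1)) stop("thresholds must lie in [-1, 1]", call. = FALSE)
  ndvi <- composite$bands[, , 5]
  ndwi <- composite$bands[, , 6]
  ok <- composite$valid
  list(
    vegetation = ok & !is.na(ndvi) & ndvi > ndvi_veg_min,
    bare       = ok & !is.na(ndvi) & ndvi < ndvi_bare_max,
    water      = ok & !is.na(ndwi) & ndwi > ndwi_water_min
  )
}

#' Derive endmember signatures from candidate pixels
#'
#' Automates the manual region-of-interest step. Candidate pools are first
#' disambiguated (pixels matching the water criterion are removed from the
#' bare pool, since low NDVI alone does not separate dark water from bright
#' soil). Under the default `"percentile"` strategy each class keeps only
#' its purest `purity_quantile` fraction of candidates, ranked by a
#' class-specific purity index -- NDVI (descending) for vegetation,
#' broadband brightness (descending) for bare surface, NDWI (descending)
#' for water -- and takes the componentwise median, which resists the
#' noise-selection bias a mean of a ranked tail would inherit. The
#' `"mean"` strategy averages all candidates componentwise.
#'
#' @param composite A [feature_image()].
#' @param masks Candidate masks from [select_endmember_candidates()].
#' @param strategy `"percentile"` (default) or `"mean"`.
#' @param purity_quantile Fraction of candidates kept under the percentile
#'   strategy (default 0.25).
#' @return An `endmember_set`: `signatures` (3 x 6 matrix, rows vegetation /
#'   bare / water, columns per [GC_BANDS]) plus per-class candidate counts.
#' @export
derive_endmember_signatures <- function(composite, masks,
                                        strategy = c("percentile", "mean"),
                                        purity_quantile = 0.25) {
  stopifnot(inherits(composite, "feature_image"))
  strategy <- match.arg(strategy)
  masks$bare <- masks$bare & !masks$water
  flat <- matrix(composite$bands, ncol = 6)
  purity <- list(
    vegetation = flat[, 5],
    bare = rowSums(flat[, 1:4, drop = FALSE]),
    water = flat[, 6]
  )
  sigs <- matrix(NA_real_, 3, 6,
                 dimnames = list(c("vegetation", "bare", "water"), GC_BANDS))
  counts <- integer(3)
  for (i in seq_len(3)) {
    cls <- rownames(sigs)[i]
    idx <- which(masks[[cls]])
    if (length(idx) == 0) {
      stop(sprintf("endmember not found: no candidate pixels for class '%s'", cls),
           call. = FALSE)
    }
    if (strategy == "percentile") {
      keep <- max(1L, ceiling(purity_quantile * length(idx)))
      idx <- idx[order(purity[[cls]][idx], decreasing = TRUE)[seq_len(keep)]]
      sigs[i, ] <- apply(flat[idx, , drop = FALSE], 2, stats::median)
    } else {
      sigs[i, ] <- colMeans(flat[idx, , drop = FALSE])
    }
    counts[i] <- length(idx)
  }
  structure(list(signatures = sigs,
                 counts = stats::setNames(counts, rownames(sigs)),
                 strategy = strategy),
            class = "endmember_set")
}

#' Construct an endmember set from known signatures
#'
#' @param signatures n x 6 numeric matrix (classes in rows, bands per
#'   [GC_BANDS]); rows must be finite and pairwise distinct, n >= 2.
#' @param provenance Free-form note on where the signatures came from.
#' @return An `endmember_set`.
#' @export
endmember_set <- function(signatures, provenance = "user-supplied") {
  signatures <- as.matrix(signatures)
  stopifnot(nrow(signatures) >= 2, ncol(signatures) == 6,
            all(is.finite(signatures)))
  if (anyDuplicated(signatures) > 0) {
    stop("endmember signatures must be pairwise distinct", call. = FALSE)
  }
  if (is.null(rownames(signatures))) {
    rownames(signatures) <- paste0("endmember", seq_len(nrow(signatures)))
  }
  colnames(signatures) <- GC_BANDS
  structure(list(signatures = signatures,
                 counts = NULL, strategy = provenance),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> %d classes (%s)\n", nrow(x$signatures),
              x$strategy))
  print(round(x$signatures, 4))
  if (!is.null(x$counts)) cat("candidate pixels:",
                              paste(names(x$counts), x$counts, collapse = ", "),
                              "\n")
  invisible(x)
}

# Fully constrained least squares: min ||s - t(C) f|| s.t. f >= 0, sum f = 1.
# Exact combinatorial active-set solve: the optimum has some support set of
# strictly positive fractions; for each candidate support the
# equality-constrained problem is a small KKT system. Enumerating all
# non-empty supports (2^n - 1; n is 3 here) and keeping the feasible
# solution with minimal residual yields the global optimum to machine
# precision, with no iterative convergence concerns.
fcls_supports <- function(n) {
  stopifnot(n <= 12)
  lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
}

fcls_kkt <- function(AtA, nS) {
  rbind(cbind(AtA, rep(1, nS)), c(rep(1, nS), 0))
}

fcls_solve <- function(s, C, bands = seq_len(ncol(C))) {
  A <- t(C[, bands, drop = FALSE])   # bands x n
  n <- ncol(A)
  b <- s[bands]
  best <- NULL
  best_rss <- Inf
  for (S in fcls_supports(n)) {
    K <- fcls_kkt(crossprod(A[, S, drop = FALSE]), length(S))
    sol <- tryCatch(solve(K, c(crossprod(A[, S, drop = FALSE], b), 1)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    fS <- sol[seq_along(S)]
    if (any(fS < -1e-9)) next
    f <- numeric(n)
    f[S] <- pmax(fS, 0)
    f <- f / sum(f)
    rss <- sum((b - as.vector(A %*% f))^2)
    if (rss < best_rss - 1e-15) {
      best_rss <- rss
      best <- f
    }
  }
  list(fractions = best, residual = sqrt(best_rss))
}

#' Unmix one pixel signature
#'
#' Solves the linear mixing model `S = sum_k f_k C_k + eps` under the
#' physical constraints `f_k >= 0` and `sum_k f_k = 1` by fully constrained
#' least squares.
#'
#' @param signature Length-6 feature vector (per [GC_BANDS]).
#' @param endmembers An `endmember_set`.
#' @param bands Indices of the bands used in the fit. The default (1:4)
#'   fits the four reflectance bands, for which the linear mixing model
#'   holds exactly; the derived NDVI/NDWI bands are ratios of reflectances
#'   and do not mix linearly, so including them (`bands = 1:6`) introduces a
#'   model bias in mixed pixels. The index bands' role in the pipeline is
#'   endmember candidate selection and composite ordering.
#' @return `list(fractions, residual)`; `fractions` sums to 1 with all
#'   entries nonnegative, `residual` is the remaining l2 misfit. A
#'   non-finite signature yields `NA` fractions rather than an error.
#' @export
unmix_pixel <- function(signature, endmembers, bands = 1:4) {
  stopifnot(inherits(endmembers, "endmember_set"))
  C <- endmembers$signatures
  if (length(signature) != ncol(C)) {
    stop("signature length must match endmember bands", call. = FALSE)
  }
  if (!all(is.finite(signature[bands]))) {
    return(list(fractions = rep(NA_real_, nrow(C)), residual = NA_real_))
  }
  res <- fcls_solve(signature, C, bands)
  names(res$fractions) <- rownames(C)
  res
}

#' Unmix every pixel of a feature image
#'
#' Applies [unmix_pixel()] per pixel of a (composited) feature image. The
#' vegetation fraction of the annual greenest composite is the annual
#' maximum greenspace coverage `G_max`.
#'
#' @param composite A [feature_image()].
#' @param endmembers An `endmember_set`.
#' @param bands Band indices used in the fit; see [unmix_pixel()].
#' @return A `fraction_map`: `fractions` (rows x cols x n array, third
#'   dimension named by class), `residual` matrix, `valid` matrix, and
#'   georeferencing.
#' @export
unmix_image <- function(composite, endmembers, bands = 1:4) {
  stopifnot(inherits(composite, "feature_image"),
            inherits(endmembers, "endmember_set"))
  C <- endmembers$signatures
  sh <- dim(composite$valid)
  flat <- matrix(composite$bands, ncol = 6)
  n <- nrow(C)
  fr <- matrix(NA_real_, nrow(flat), n)
  resid <- rep(NA_real_, nrow(flat))
  ok <- which(composite$valid & rowSums(!is.finite(flat[, bands, drop = FALSE])) == 0)
  # identical signatures (pure patches, ties) solved once
  key <- apply(flat[ok, bands, drop = FALSE], 1, paste, collapse = "\r")
  first <- !duplicated(key)
  sols <- lapply(which(first), function(j) fcls_solve(flat[ok[j], ], C, bands))
  map <- match(key, key[first])
  for (j in seq_along(ok)) {
    fr[ok[j], ] <- sols[[map[j]]]$fractions
    resid[ok[j]] <- sols[[map[j]]]$residual
  }
  fractions <- array(fr, dim = c(sh, n),
                     dimnames = list(NULL, NULL, rownames(C)))
  structure(list(fractions = fractions,
                 residual = matrix(resid, sh[1], sh[2]),
                 valid = composite$valid & !is.na(matrix(fr[, 1], sh[1], sh[2])),
                 endmembers = endmembers,
                 transform = composite$transform, crs = composite$crs),
            class = "fraction_map")
}

#' @export
print.fraction_map <- function(x, ...) {
  cat(sprintf("<fraction_map> %d x %d pixels, %d endmembers, %.0f%% valid\n",
              nrow(x$valid), ncol(x$valid), dim(x$fractions)[3],
              100 * mean(x$valid)))
  cat(sprintf("  mean vegetation fraction (G_max): %.3f\n",
              mean(x$fractions[, , 1], na.rm = TRUE)))
  invisible(x)
}

#' Extract the annual maximum greenspace coverage layer
#'
#' @param fraction_map A `fraction_map` from [unmix_image()].
#' @return Matrix of vegetation fractions (`G_max`), `NA` where invalid.
#' @export
gmax_layer <- function(fraction_map) {
  stopifnot(inherits(fraction_map, "fraction_map"))
  g <- fraction_map$fractions[, , "vegetation"]
  g[!fraction_map$valid] <- NA_real_
  g
}
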