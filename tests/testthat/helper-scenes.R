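# Shared fixtures: scenes are generated in code at test time.

# Small scene for fast module tests.
tiny_truth <- function(seed = 7, noise_sd = 0, cloud_prob = 0, ...) {
  scene_truth(seed = seed, shape = c(32, 32), doys = seq(5, 365, by = 10),
              patch_scale = 8, noise_sd = noise_sd, cloud_prob = cloud_prob,
              ...)
}

# The package's reference scene (128 x 128, noise sd 0.01, 20% cloud).
reference_truth <- function(seed = 7, ...) scene_truth(seed = seed, ...)

# Endmember set built from the generator's spectra at a given day,
# with the index bands appended.
truth_endmembers <- function(truth, doy) {
  E <- truth$endmember_spectra(doy)
  ndvi <- (E[, 4] - E[, 3]) / (E[, 4] + E[, 3])
  ndwi <- (E[, 2] - E[, 4]) / (E[, 2] + E[, 4])
  endmember_set(cbind(E, ndvi, ndwi), provenance = "generator truth")
}

run_annual_pipeline <- function(truth, prob_threshold = 50, ...) {
  series <- apply_cloud_mask(render_reflectance(truth), prob_threshold)
  feats <- build_feature_stack(series)
  comp <- greenest_composite(feats)
  em <- derive_endmember_signatures(comp, select_endmember_candidates(comp))
  fm <- unmix_image(comp, em, ...)
  phen <- build_ndvi_phenology(series)
  cube <- assemble_cube(fm, phen)
  list(series = series, comp = comp, em = em, fm = fm, phen = phen,
       cube = cube)
}

# Brute-force simplex grid search oracle for 3-endmember unmixing.
# The full grid at the given step is enumerated once and cached.
.simplex_grid_cache <- new.env(parent = emptyenv())

simplex_grid <- function(step = 1e-3) {
  key <- format(step)
  if (is.null(.simplex_grid_cache[[key]])) {
    n <- round(1 / step)
    i <- rep.int(0:n, n + 1 - (0:n))
    j <- sequence(n + 1 - (0:n)) - 1L
    .simplex_grid_cache[[key]] <- cbind(i, j, n - i - j) / n
  }
  .simplex_grid_cache[[key]]
}

grid_search_unmix <- function(s, C, bands = 1:4, step = 1e-3) {
  A <- t(C[, bands, drop = FALSE])
  b <- s[bands]
  FG <- simplex_grid(step)
  # rss for every grid point, expanded without forming b - A f explicitly
  G <- FG %*% crossprod(A)          # m x 3, rows f' (A'A)
  rss <- rowSums(G * FG) - 2 * as.vector(FG %*% crossprod(A, b)) + sum(b^2)
  k <- which.min(rss)
  list(fractions = FG[k, ], residual = sqrt(max(rss[k], 0)))
}

# Per-pixel noise-free NDVI slot reference for a scene (no clouds assumed).
truth_slot_reference <- function(truth) {
  npix <- prod(truth$shape)
  frm <- matrix(truth$fraction_truth, npix, 3)
  nd <- sapply(truth$doys, function(d) {
    E <- truth$endmember_spectra(d)
    R <- frm %*% E
    (R[, 4] - R[, 3]) / (R[, 4] + R[, 3])
  })
  composite_10day(truth$doys, t(nd))   # 36 x npix
}
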