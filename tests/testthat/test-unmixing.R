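test_that("candidate masks follow the index thresholds", {
  set.seed(5)
  bands <- array(runif(9 * 4, 0.05, 0.4), dim = c(3, 3, 4))
  # engineer NDVI/NDWI: pixel (1,1) vegetation-like, (2,2) bare-like,
  # (3,3) water-like, (1,2) ambiguous mid-range
  set_px <- function(b, i, j, refl) { b[i, j, ] <- refl; b }
  bands <- set_px(bands, 1, 1, c(0.03, 0.06, 0.02, 0.45))  # NDVI 0.915
  bands <- set_px(bands, 2, 2, c(0.20, 0.25, 0.30, 0.35))  # NDVI 0.077
  bands <- set_px(bands, 3, 3, c(0.06, 0.08, 0.05, 0.02))  # NDWI 0.6
  bands <- set_px(bands, 1, 2, c(0.10, 0.12, 0.15, 0.45))  # NDVI 0.5
  fi <- feature_image(bands)
  m <- select_endmember_candidates(fi)
  expect_true(m$vegetation[1, 1])
  expect_true(m$bare[2, 2])
  expect_true(m$water[3, 3])
  expect_false(m$vegetation[1, 2] || m$bare[1, 2] || m$water[1, 2])
  expect_error(select_endmember_candidates(fi, ndvi_veg_min = 1.5), "-1, 1")
})

test_that("signature derivation averages candidates and names missing classes", {
  b <- array(0, dim = c(2, 2, 4))
  b[1, 1, ] <- c(0.03, 0.06, 0.02, 0.45)
  b[1, 2, ] <- c(0.05, 0.08, 0.04, 0.47)
  b[2, 1, ] <- c(0.20, 0.25, 0.30, 0.35)
  b[2, 2, ] <- c(0.06, 0.08, 0.05, 0.02)
  fi <- feature_image(b)
  m <- select_endmember_candidates(fi)
  em <- derive_endmember_signatures(fi, m, strategy = "mean")
  # two vegetation candidates: componentwise average
  expect_equal(unname(em$signatures["vegetation", 1:4]),
               c(0.04, 0.07, 0.03, 0.46))
  expect_equal(unname(em$counts["vegetation"]), 2L)
  # identical candidates reproduce their spectrum exactly, both strategies
  em_p <- derive_endmember_signatures(fi, m, strategy = "percentile")
  expect_equal(unname(em_p$signatures["bare", 1:4]), c(0.20, 0.25, 0.30, 0.35))
  # remove water candidates entirely: explicit, named error
  m$water[] <- FALSE
  expect_error(derive_endmember_signatures(fi, m), "water")
})

test_that("derived vegetation signature recovers the generator spectrum", {
  truth <- reference_truth()
  peak_t <- which.min(abs(truth$doys - truth$phenology$peak_doys[1]))
  peak_doy <- truth$doys[peak_t]
  series <- apply_cloud_mask(render_reflectance(truth, doys = peak_doy), 50)
  fi <- build_feature_stack(series)[[1]]
  em <- derive_endmember_signatures(fi, select_endmember_candidates(fi))
  E <- truth$endmember_spectra(truth$doys[peak_t])
  expect_lt(max(abs(em$signatures["vegetation", 1:4] - E["vegetation", ])),
            truth$noise_sd)
  # bare/water purity indices amplify band noise more; allow twice the sd
  for (cls in c("bare", "water")) {
    expect_lt(max(abs(em$signatures[cls, 1:4] - E[cls, ])), 2 * truth$noise_sd)
  }
})

test_that("pixel unmixing solves the constrained least-squares problem", {
  truth <- tiny_truth()
  em <- truth_endmembers(truth, 200)
  C <- em$signatures
  r <- unmix_pixel(C["vegetation", ], em)
  expect_equal(unname(r$fractions), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(r$residual, 1e-9)
  mix <- 0.5 * C["vegetation", 1:4] + 0.5 * C["bare", 1:4]
  r2 <- unmix_pixel(c(mix, 0, 0), em, bands = 1:4)
  expect_equal(unname(r2$fractions), c(0.5, 0.5, 0), tolerance = 1e-9)
  # non-finite signatures degrade to NA, not an exception
  r3 <- unmix_pixel(c(NA, C["water", 2:6]), em)
  expect_true(all(is.na(r3$fractions)))
})

test_that("solver matches the simplex grid-search oracle and exact truth", {
  truth <- tiny_truth()
  em <- truth_endmembers(truth, 150)
  C <- em$signatures
  set.seed(9)
  n_cases <- 100
  g <- matrix(rgamma(n_cases * 3, 1), n_cases, 3)
  f_true <- g / rowSums(g)
  max_err <- 0
  for (i in seq_len(n_cases)) {
    s <- as.vector(t(C[, 1:4]) %*% f_true[i, ])
    r <- unmix_pixel(c(s, 0, 0), em, bands = 1:4)
    max_err <- max(max_err, max(abs(r$fractions - f_true[i, ])))
    expect_equal(sum(r$fractions), 1, tolerance = 1e-12)
    expect_true(all(r$fractions >= 0))
  }
  expect_lt(max_err, 1e-6)
  # grid oracle agreement within grid resolution on a subset
  for (i in 1:10) {
    s <- as.vector(t(C[, 1:4]) %*% f_true[i, ])
    o <- grid_search_unmix(c(s, 0, 0), C, step = 1e-3)
    r <- unmix_pixel(c(s, 0, 0), em, bands = 1:4)
    expect_lt(max(abs(r$fractions - o$fractions)), 1e-3)
    expect_lte(r$residual, o$residual + 1e-12)
  }
})

test_that("solver agrees with an independent NNLS route on noisy signatures", {
  truth <- tiny_truth()
  C <- truth_endmembers(truth, 150)$signatures
  set.seed(10)
  for (i in 1:25) {
    f <- rgamma(3, 1); f <- f / sum(f)
    s <- as.vector(t(C[, 1:4]) %*% f) + rnorm(4, 0, 0.02)
    r <- unmix_pixel(c(s, 0, 0), truth_endmembers(truth, 150), bands = 1:4)
    # independent route: NNLS with a weighted sum-to-one row
    A <- rbind(t(C[, 1:4]), 100)
    nn <- pracma::lsqnonneg(A, c(s, 100))$x
    nn <- nn / sum(nn)
    expect_equal(unname(r$fractions), nn, tolerance = 1e-4)
  }
})

test_that("image unmixing round-trips a noise-free rendered scene", {
  truth <- tiny_truth()
  out <- run_annual_pipeline(truth)
  expect_lt(max(abs(out$fm$fractions - truth$fraction_truth)), 1e-6)
  # constraint satisfaction on every valid pixel
  sums <- out$fm$fractions[, , 1] + out$fm$fractions[, , 2] +
    out$fm$fractions[, , 3]
  expect_lt(max(abs(sums[out$fm$valid] - 1)), 1e-9)
  expect_true(all(out$fm$fractions[!is.na(out$fm$fractions)] >= 0))
  expect_equal(dim(out$fm$fractions)[3], 3L)
  # G_max layer is the vegetation fraction
  expect_equal(gmax_layer(out$fm), out$fm$fractions[, , "vegetation"])
})
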