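test_that("fraction maps are convex, autocorrelated and reproducible", {
  fr <- make_fraction_maps(seed = 3, shape = c(24, 20), patch_scale = 6)
  expect_equal(dim(fr), c(24, 20, 3))
  sums <- fr[, , 1] + fr[, , 2] + fr[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(fr >= 0 & fr <= 1))

  # one patch covering the scene: a single shared composition
  one <- make_fraction_maps(seed = 5, shape = c(8, 8), patch_scale = 8)
  expect_equal(length(unique(as.vector(one[, , 1]))), 1)
  expect_equal(sum(one[1, 1, ]), 1, tolerance = 1e-12)

  expect_identical(make_fraction_maps(11, c(16, 16), 4),
                   make_fraction_maps(11, c(16, 16), 4))
  expect_error(make_fraction_maps(1, c(0, 4), 2), "positive")
})

test_that("within-patch texture keeps the simplex and pure patches", {
  fr <- make_fraction_maps(seed = 3, shape = c(32, 32), patch_scale = 8,
                           within_concentration = 2)
  sums <- fr[, , 1] + fr[, , 2] + fr[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-12)
  # pure patches are exactly pure: any pixel at 1 has the other two at 0
  pure <- which(fr == 1, arr.ind = TRUE)
  if (nrow(pure) > 0) {
    for (r in seq_len(nrow(pure))) {
      expect_equal(sum(fr[pure[r, 1], pure[r, 2], ]), 1)
    }
  }
  # mixed pixels genuinely vary within a block
  expect_gt(stats::sd(fr[, , 1]), 0.1)
})

test_that("phenology curve hits its declared peak and bounds", {
  p <- phenology_params(baseline_ndvi = 0.1, amplitude = 0.8, peak_doys = 180,
                        rise_rate = 0.5, fall_rate = 0.5)
  expect_equal(vegetation_ndvi_curve(p, 180), 0.9, tolerance = 1e-3)
  v <- vegetation_ndvi_curve(p, 1:365)
  expect_true(all(v >= 0.1 - 1e-12 & v <= 0.9 + 1e-12))

  flat <- phenology_params(baseline_ndvi = 0.3, amplitude = 0,
                           peak_doys = 100)
  expect_equal(vegetation_ndvi_curve(flat, c(1, 100, 250, 365)),
               rep(0.3, 4))
  expect_error(vegetation_ndvi_curve(p, 0), "doy")
  expect_error(vegetation_ndvi_curve(p, 367), "doy")
})

# brute-force modality scan: count +/- sign changes of forward differences,
# ignoring exactly-flat stretches
count_peaks <- function(v) {
  d <- diff(v)
  d <- d[d != 0]
  s <- sign(d)
  sum(s[-length(s)] > 0 & s[-1] < 0)
}

test_that("declared modality matches a brute-force scan of the curve", {
  uni <- phenology_params(baseline_ndvi = 0.15, amplitude = 0.7,
                          peak_doys = 200)
  expect_equal(count_peaks(vegetation_ndvi_curve(uni, 1:365)), 1)
  bi <- phenology_params(baseline_ndvi = 0.15, amplitude = 0.6,
                         peak_doys = c(120, 270), mode = "bimodal",
                         rise_rate = 0.15, fall_rate = 0.15,
                         pulse_half_width = 30)
  expect_equal(count_peaks(vegetation_ndvi_curve(bi, 1:365)), 2)
})

test_that("phenology parameter invariants are enforced", {
  expect_error(phenology_params(baseline_ndvi = 0.5, amplitude = 0.6),
               "<= 1")
  expect_error(phenology_params(peak_doys = c(200, 100), mode = "bimodal"),
               "increasing")
  expect_error(phenology_params(peak_doys = c(100, 200), mode = "unimodal"),
               "exactly 1")
  expect_error(phenology_params(peak_doys = 100, mode = "bimodal"),
               "exactly 2")
})

test_that("rendered reflectance is the convex mixture of endmember spectra", {
  truth <- tiny_truth()
  # locate a pure vegetation pixel and a pure bare pixel
  fv <- truth$fraction_truth
  pv <- which(fv[, , 1] == 1)[1]
  series <- render_reflectance(truth)
  t5 <- 5
  doy <- series$obs[[t5]]$doy
  E <- truth$endmember_spectra(doy)
  bands <- matrix(series$obs[[t5]]$bands, ncol = 4)
  ndvi_v <- (E[1, 4] - E[1, 3]) / (E[1, 4] + E[1, 3])
  expect_equal((bands[pv, 4] - bands[pv, 3]) / (bands[pv, 4] + bands[pv, 3]),
               unname(ndvi_v), tolerance = 1e-12)
  # a constructed half-half mixture sits at the spectral midpoint
  frm <- matrix(fv, ncol = 3)
  expect_equal(bands, frm %*% E, tolerance = 1e-12, ignore_attr = TRUE)

  # clouded observations are flagged at 100 percent cloud probability
  truth_c <- tiny_truth(cloud_prob = 0.5)
  ser_c <- render_reflectance(truth_c)
  for (t in seq_along(ser_c$obs)) {
    expect_identical(ser_c$obs[[t]]$cloud >= 50,
                     truth_c$cloud_schedule[, , t])
  }
  expect_identical(render_reflectance(truth, seed = 42)$obs[[1]]$bands,
                   render_reflectance(truth, seed = 42)$obs[[1]]$bands)
  expect_error(render_reflectance(truth, doys = 999), "1, 366")
})

test_that("rendered LST follows the linear coupling with known slope", {
  g0 <- matrix(0, 10, 10)
  expect_equal(render_lst(g0, matrix(0.03, 10, 10), base_lst = 40,
                          noise_sd = 0, seed = 1),
               matrix(40, 10, 10))
  g1 <- matrix(1, 10, 10)
  lst <- render_lst(g1, matrix(0.03, 10, 10), base_lst = 40, noise_sd = 0,
                    seed = 1)
  expect_equal(lst, matrix(37, 10, 10))  # 0.03 degC/% times 100%
  expect_identical(render_lst(g1, matrix(0.02, 10, 10), seed = 9),
                   render_lst(g1, matrix(0.02, 10, 10), seed = 9))
  expect_error(render_lst(matrix(0, 5, 5), matrix(0.03, 4, 4)),
               "co-registered")
})

test_that("scene export writes per-date rasters plus a manifest", {
  truth <- tiny_truth()
  series <- render_reflectance(truth, doys = truth$doys[1:3])
  dir <- withr::local_tempdir()
  mp <- write_scene(truth, series, dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  expect_equal(man$shape, truth$shape)
  f <- file.path(dir, man$files[1])
  expect_true(file.exists(f))
  back <- read_geo_tiff(f)
  expect_equal(back[, , 1:4], series$obs[[1]]$bands, tolerance = 1e-6,
               ignore_attr = TRUE)
  # the full series round-trips through the directory format
  series2 <- read_scene(dir)
  expect_length(series2$obs, 3)
  expect_equal(series2$obs[[2]]$bands, series$obs[[2]]$bands,
               tolerance = 1e-6)
  expect_equal(series2$obs[[2]]$doy, series$obs[[2]]$doy)
})
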