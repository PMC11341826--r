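# Minimal hand-built phenology object for identity checks.
fake_phen <- function(slots_vec, sh = c(1, 1)) {
  slots <- array(rep(slots_vec, each = prod(sh)), dim = c(sh, 36))
  mx <- extract_ndvi_max(matrix(slots_vec, nrow = 1))
  structure(list(
    slots = slots,
    ndvi_max = matrix(mx$ndvi_max, sh[1], sh[2]),
    peak_slot = matrix(mx$peak_slot, sh[1], sh[2]),
    empty_slots = rep(0, 36),
    valid = matrix(TRUE, sh[1], sh[2]),
    grid = temporal_grid(), passes = 2,
    transform = gc_transform(), crs = "local"
  ), class = "ndvi_phenology")
}

test_that("cube assembly follows the coverage model identities", {
  slots <- rep(0.3, 36); slots[20] <- 0.6; slots[5] <- 0
  phen <- fake_phen(slots)
  cube <- assemble_cube(matrix(0.8), phen)
  # at the peak slot the ratio is 1: G equals G_max
  expect_equal(cube$layers[1, 1, 20], 0.8)
  # zero NDVI gives zero coverage
  expect_equal(cube$layers[1, 1, 5], 0)
  # worked ratio: 0.8 * 0.3 / 0.6 = 0.4
  expect_equal(cube$layers[1, 1, 1], 0.4)
  # the ratio never exceeds 1: coverage capped by G_max
  expect_true(all(cube$layers <= 0.8 + 1e-12))
  expect_true(all(cube$layers >= 0))
  expect_error(assemble_cube(matrix(0.5, 2, 2), phen), "co-registered")
})

test_that("negative NDVI clamps to zero and weak seasonality is flagged", {
  slots <- rep(0.3, 36); slots[10] <- -0.2
  cube <- assemble_cube(matrix(0.6), fake_phen(slots))
  expect_equal(cube$layers[1, 1, 10], 0)
  # aseasonal pixel: NDVI_max below the floor -> constant G_max
  weak <- fake_phen(rep(0.01, 36))
  cube2 <- assemble_cube(matrix(0.02), weak, eps_floor = 0.05)
  expect_true(cube2$aseasonal[1, 1])
  expect_equal(cube2$layers[1, 1, ], rep(0.02, 36))
})

test_that("peak-slot coverage equals G_max across a full synthetic cube", {
  truth <- tiny_truth()
  out <- run_annual_pipeline(truth)
  g <- gmax_layer(out$fm)
  mx <- apply(out$cube$layers, c(1, 2), max)
  expect_lt(max(abs(mx - g), na.rm = TRUE), 1e-9)
})

test_that("cube files round-trip through the 0.001 integer encoding", {
  set.seed(8)
  sh <- c(9, 7)
  layers <- array(runif(prod(sh) * 36), dim = c(sh, 36))
  layers[2, 3, ] <- NA  # a nodata pixel
  layers[1, 1, ] <- 1   # exact full coverage
  layers[1, 2, ] <- 0
  cube <- structure(list(layers = layers, year = 2020L, scale_factor = 0.001,
                         nodata_code = -1L, aseasonal = NULL,
                         valid = !is.na(layers[, , 1]),
                         transform = gc_transform(500, 800), crs = "EPSG:32614"),
                    class = "greenspace_cube")
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  meta <- jsonlite::read_json(paste0(path, ".aux.json"), simplifyVector = TRUE)
  expect_equal(meta$scale_factor, 0.001)
  expect_equal(meta$n_bands, 36L)
  back <- read_cube(path)
  expect_equal(dim(back$layers), dim(layers))
  expect_lte(max(abs(back$layers - layers), na.rm = TRUE), 0.0005)
  # exact values at the encoding lattice survive bit-exactly
  expect_equal(back$layers[1, 1, 1], 1)
  expect_equal(back$layers[1, 2, 1], 0)
  # nodata stays missing, never zero
  expect_true(all(is.na(back$layers[2, 3, ])))
  expect_false(back$valid[2, 3])
  expect_equal(back$transform, cube$transform)
})

test_that("reading rejects files with the wrong band count", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:12, function(k) matrix(0.5, 4, 4))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(n_bands = 12, scale_factor = 0.001, nodata = -1,
                            offset = 1, transform = gc_transform(),
                            crs = "local"),
                       paste0(path, ".aux.json"), auto_unbox = TRUE)
  expect_error(read_cube(path), "36")
  expect_error(read_cube(file.path(tempdir(), "absent.tif")), "no such file")
})

test_that("bounding-box cropping masks outside pixels", {
  m <- set_geo(matrix(1, 10, 10), gc_transform(0, 100, px = 10))
  out <- crop_to_bbox(m, c(22, 22, 68, 68))
  expect_true(is.na(out[1, 1]))
  expect_equal(out[5, 5], 1)
  # pixel centres at 25, 35, 45, 55, 65 fall inside on each axis
  expect_equal(sum(!is.na(out)), 25)
})

test_that("cube tidiers summarise coverage", {
  truth <- tiny_truth()
  out <- run_annual_pipeline(truth)
  gl <- glance(out$cube)
  expect_equal(gl$n_layers, 36L)
  expect_true(gl$mean_coverage >= 0 && gl$mean_coverage <= 1)
  td <- tidy(out$cube)
  expect_equal(nrow(td), 32 * 32 * 36)
  expect_true(all(c("row", "col", "slot", "doy_mid", "coverage") %in% names(td)))
})
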