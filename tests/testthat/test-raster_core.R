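test_that("cell and mask areas follow exact cell counting", {
  r30 <- grid_raster(matrix(0, 5, 5), cell_size_m = 30)
  expect_equal(cell_area_ha(r30), 0.09)
  expect_equal(cell_area_ha(grid_raster(matrix(0, 2, 2), 100)), 1)
  expect_equal(cell_area_ha(grid_raster(matrix(0, 2, 2), 10)), 0.01)
  expect_error(grid_raster(matrix(0, 2, 2), -5), "cell_size_m")

  set.seed(11)
  m <- as_mask(matrix(FALSE, 10, 10), cell_size_m = 30)
  m$values[sample(100, 37)] <- TRUE
  expect_equal(mask_area_ha(m), 37 * 0.09)
  expect_equal(mask_area_ha(as_mask(matrix(FALSE, 4, 4), cell_size_m = 30)), 0)
  expect_equal(mask_area_ha(as_mask(matrix(TRUE, 100, 100), cell_size_m = 30)),
               900)
})

test_that("mask area is additive over disjoint masks and origin-invariant", {
  set.seed(12)
  a <- matrix(runif(400) < 0.3, 20, 20)
  b <- matrix(runif(400) < 0.3, 20, 20) & !a
  m_ab <- as_mask(a | b, cell_size_m = 30)
  expect_equal(mask_area_ha(m_ab),
               mask_area_ha(as_mask(a, cell_size_m = 30)) +
                 mask_area_ha(as_mask(b, cell_size_m = 30)))
  shifted <- as_mask(a | b, cell_size_m = 30, origin_xy = c(5e5, -3e4))
  expect_equal(mask_area_ha(shifted), mask_area_ha(m_ab))
})

test_that("dilation matches the brute-force Euclidean oracle", {
  m <- as_mask(matrix(FALSE, 7, 7), cell_size_m = 30)
  m$values[4, 4] <- TRUE
  expect_equal(sum(dilate_mask(m, 60)$values), 13)  # discrete disk, r = 2

  set.seed(21)
  for (k in 1:15) {
    m <- rand_mask(sample(5:40, 1), sample(5:40, 1), p = 0.08)
    d <- runif(1, 0, 12) * m$cell_size_m
    expect_identical(dilate_mask(m, d)$values, oracle_dilate(m, d))
  }
  expect_error(dilate_mask(m, -1), "non-negative")
})

test_that("dilation is the identity at 0, monotone and nested in distance", {
  set.seed(22)
  m <- rand_mask(30, 30, p = 0.05)
  expect_identical(dilate_mask(m, 0)$values, m$values)
  prev <- m$values
  for (d in c(5000, 10000, 15000, 20000)) {
    cur <- dilate_mask(m, d)$values
    expect_true(all(cur[prev]))  # superset of the smaller buffer
    prev <- cur
  }
  expect_true(all(dilate_mask(m, 90)$values[m$values]))  # output contains input
})

test_that("distance map is zero on the mask and consistent with dilation", {
  set.seed(23)
  m <- rand_mask(25, 25, p = 0.1)
  dm <- distance_map_m(m)
  expect_true(all(dm$values[m$values] == 0))
  expect_identical(dm$values <= 150 + 1e-9, dilate_mask(m, 150)$values)
})

test_that("distance transform cross-checks against an image-library implementation", {
  set.seed(24)
  for (k in 1:5) {
    m <- rand_mask(sample(10:40, 1), sample(10:40, 1), p = 0.07, cell = 1)
    if (!any(m$values)) next
    got <- distance_map_m(m)$values
    ref <- EBImage::distmap(EBImage::Image(1 - m$values, dim(m$values)),
                            metric = "euclidean")@.Data
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("connected components agree with a flood-fill oracle", {
  diag2 <- as_mask(rbind(c(TRUE, FALSE), c(FALSE, TRUE)), cell_size_m = 30)
  expect_equal(attr(connected_components(diag2, "edge"), "n_components"), 2)
  expect_equal(attr(connected_components(diag2, "edge+corner"),
                    "n_components"), 1)

  set.seed(31)
  for (k in 1:12) {
    m <- rand_mask(sample(5:40, 1), sample(5:40, 1), p = runif(1, 0.2, 0.6))
    for (conn in c("edge", "edge+corner")) {
      got <- connected_components(m, conn)
      want <- oracle_flood_fill(m$values, diagonal = conn == "edge+corner")
      expect_equal(attr(got, "n_components"), max(want))
      # same partition: cells share a package label iff they share an oracle one
      tv <- which(m$values)
      expect_equal(as.vector(table(got$values[tv], want[tv]) > 0) |> sum(),
                   max(want))
    }
  }
})

test_that("zonal extrema equal an exhaustive scan and reject empty zones", {
  uni <- grid_raster(matrix(12.5, 6, 6), 30)
  full <- as_mask(matrix(TRUE, 6, 6), cell_size_m = 30)
  expect_equal(zonal_min_max(uni, full), c(min = 12.5, max = 12.5))

  ramp <- grid_raster(matrix(1:25, 5, 5), 30)
  expect_equal(zonal_min_max(ramp, as_mask(matrix(TRUE, 5, 5),
                                           cell_size_m = 30)),
               c(min = 1, max = 25))

  set.seed(41)
  for (k in 1:10) {
    r <- grid_raster(matrix(rnorm(100), 10, 10), 30)
    z <- rand_mask(10, 10, p = 0.3)
    if (!any(z$values)) next
    vals <- r$values[z$values]
    expect_equal(zonal_min_max(r, z), c(min = min(vals), max = max(vals)))
  }
  empty <- as_mask(matrix(FALSE, 10, 10), cell_size_m = 30)
  expect_error(zonal_min_max(r, empty), "empty-zone")
  allna <- grid_raster(matrix(NA_real_, 10, 10), 30)
  expect_error(zonal_min_max(allna, z), "empty-zone")
})

test_that("layer bundles enforce their invariants", {
  mk <- function(v) grid_raster(matrix(v, 4, 4), 30)
  expect_error(climate_stack(rep(list(mk(1)), 11), rep(list(mk(0)), 12),
                             rep(list(mk(5)), 12)), "12 monthly")
  expect_error(climate_stack(rep(list(mk(1)), 12), rep(list(mk(9)), 12),
                             rep(list(mk(5)), 12)), "tmin exceeds tmax")
  expect_error(soil_layers(mk(-1), mk(2)), "non-negative")
  expect_error(landuse_layer(mk(3), c(other = 0)), "fallow_cropland")
  expect_error(landuse_layer(mk(3), c(other = 0, fallow_cropland = 61)),
               "absent from the code table")
  expect_error(zonal_min_max(grid_raster(matrix(1, 3, 3), 30),
                             as_mask(matrix(TRUE, 4, 4), cell_size_m = 30)),
               "alignment")
})

test_that("ASCII grid round trip preserves values, grid and nodata", {
  set.seed(51)
  v <- matrix(rnorm(48), 6, 8)
  v[2, 3] <- NA
  r <- grid_raster(v, 30, origin_xy = c(1000, 2000))
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values, r$values, tolerance = 1e-9)
  expect_equal(back$cell_size_m, 30)
  expect_equal(back$origin_xy, c(1000, 2000))

  m <- rand_mask(5, 7, 0.4)
  fm <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, fm)
  expect_identical(as_mask(read_ascii_grid(fm, "boolean"))$values, m$values)
})
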