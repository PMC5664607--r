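# compact layer builders on a shared 12 x 12 grid at 30 m
suit_fixture <- function(nr = 12, nc = 12, cell = 30) {
  const <- function(v, kind = "continuous") {
    grid_raster(matrix(v, nr, nc), cell, kind = kind)
  }
  climate <- climate_stack(
    precip = lapply(1:12, function(m) const(40 + m)),
    tmin = lapply(1:12, function(m) const(m)),
    tmax = lapply(1:12, function(m) const(m + 10))
  )
  soil <- soil_layers(const(120), const(2, "categorical"))
  lu <- matrix(0, nr, nc); lu[3:8, 3:8] <- 61
  landuse <- landuse_layer(grid_raster(lu, cell, kind = "categorical"),
                           c(other = 0, crop_x = 10, fallow_cropland = 61))
  region <- as_mask(matrix(TRUE, nr, nc), cell_size_m = cell)
  list(climate = climate, soil = soil, landuse = landuse, region = region,
       const = const)
}

test_that("derived bounds equal zonal extrema and admit their own zone", {
  fx <- suit_fixture()
  b <- derive_bounds(fx$climate, fx$region)
  expect_equal(b$precip[, "low"], 40 + 1:12)
  expect_equal(b$precip[, "high"], 40 + 1:12)
  expect_equal(b$tmin[, "low"], as.numeric(1:12))
  expect_equal(b$tmax[, "high"], 10 + 1:12)

  # ramp field: bounds are the zone's corner values
  nr <- 10; nc <- 10
  ramp <- grid_raster(matrix(rep(1:nr, nc), nr, nc), 30)
  stack <- climate_stack(rep(list(ramp), 12), rep(list(ramp), 12),
                         rep(list(ramp), 12))
  zone <- as_mask(matrix(FALSE, nr, nc), cell_size_m = 30)
  zone$values[3:7, 2:9] <- TRUE
  b2 <- derive_bounds(stack, zone)
  expect_true(all(b2$precip[, "low"] == 3 & b2$precip[, "high"] == 7))

  # random stack/zone vs exhaustive scan
  set.seed(81)
  rnd <- lapply(1:12, function(m) grid_raster(matrix(rnorm(100), 10, 10), 30))
  st <- climate_stack(rnd, rnd, lapply(rnd, function(r)
    grid_raster(r$values + 1, 30)))
  z <- rand_mask(10, 10, 0.3)
  b3 <- derive_bounds(st, z)
  for (m in 1:12) {
    vals <- rnd[[m]]$values[z$values]
    expect_equal(unname(b3$precip[m, ]), c(min(vals), max(vals)))
  }
  expect_error(derive_bounds(st, as_mask(matrix(FALSE, 10, 10),
                                         cell_size_m = 30)), "empty-zone")
})

test_that("crop clusters take the smallest size-sorted prefix reaching coverage", {
  # components of sizes 60, 30, 8, 2 laid out disjointly
  v <- matrix(0, 20, 30)
  v[1:6, 1:10] <- 10    # 60
  v[10:12, 1:10] <- 10  # 30
  v[15:16, 14:17] <- 10 # 8
  v[19, 20:21] <- 10    # 2
  lu <- landuse_layer(grid_raster(v, 30, kind = "categorical"),
                      c(other = 0, crop_x = 10, fallow_cropland = 61))
  cl <- crop_clusters(lu, "crop_x", coverage = 0.95)
  expect_equal(sum(cl$values), 98)          # 60 + 30 + 8 covers 98%
  expect_false(any(cl$values[19, 20:21]))   # smallest cluster dropped
  all_cells <- crop_clusters(lu, "crop_x", coverage = 1)
  expect_equal(sum(all_cells$values), 100)
  single <- crop_clusters(lu, 10, coverage = 0.5)
  expect_equal(sum(single$values), 60)      # one component suffices
  expect_error(crop_clusters(lu, "fallow_cropland"), "empty-crop")
  expect_error(crop_clusters(lu, "nope"), "not in the land-use code table")
})

test_that("suitability is the conjunction of active conditions over the region", {
  fx <- suit_fixture()
  b <- derive_bounds(fx$climate, fx$region)
  req <- crop_requirement("x", precip_bounds = b$precip,
                          tmin_bounds = b$tmin, tmax_bounds = b$tmax,
                          soil_depth_min_cm = 50, allowed_textures = c(1, 2),
                          require_fallow = TRUE)
  suit <- evaluate_suitability(fx$climate, fx$soil, fx$landuse, req, fx$region)
  # self-consistent bounds + uniform soil: suitable = fallow cells
  expect_identical(suit$values, fx$landuse$raster$values == 61)
  casc <- attr(suit, "cascade")
  expect_equal(unname(casc["region"]), 144)
  expect_true(all(diff(casc) <= 0))  # each condition can only remove cells

  # constructed ground truth: exactly one rectangle survives all layers
  nr <- 40; nc <- 40
  depth <- matrix(100, nr, nc); depth[1:10, ] <- 5
  text <- matrix(2, nr, nc); text[, 35:40] <- 7
  lu2 <- matrix(0, nr, nc); lu2[15:34, 5:34] <- 61  # 20 x 30 fallow block
  soil2 <- soil_layers(grid_raster(depth, 30), grid_raster(text, 30,
                                                           kind = "categorical"))
  landuse2 <- landuse_layer(grid_raster(lu2, 30, kind = "categorical"),
                            c(other = 0, fallow_cropland = 61))
  region2 <- as_mask(matrix(TRUE, nr, nc), cell_size_m = 30)
  climate2 <- climate_stack(
    lapply(1:12, function(m) grid_raster(matrix(50, nr, nc), 30)),
    lapply(1:12, function(m) grid_raster(matrix(5, nr, nc), 30)),
    lapply(1:12, function(m) grid_raster(matrix(20, nr, nc), 30))
  )
  breq <- derive_bounds(climate2, region2)
  req2 <- crop_requirement("x", precip_bounds = breq$precip,
                           soil_depth_min_cm = 50, allowed_textures = 2,
                           require_fallow = TRUE)
  suit2 <- evaluate_suitability(climate2, soil2, landuse2, req2, region2)
  want <- matrix(FALSE, nr, nc); want[15:34, 5:34] <- TRUE
  expect_identical(suit2$values, want)
  expect_equal(mask_area_ha(suit2), 600 * 0.09)

  # land-use-only model (indoor crop): climate and soil are ignored
  req3 <- crop_requirement("mushroom-style", require_fallow = TRUE,
                           active_conditions = "landuse")
  suit3 <- evaluate_suitability(NULL, NULL, landuse2, req3, region2)
  expect_identical(suit3$values, lu2 == 61)
})

test_that("nodata in any active layer makes a cell unsuitable", {
  fx <- suit_fixture()
  fx$soil$depth$values[5, 5] <- NA
  req <- crop_requirement("x", soil_depth_min_cm = 50, require_fallow = TRUE)
  suit <- evaluate_suitability(NULL, fx$soil, fx$landuse, req, fx$region)
  expect_false(suit$values[5, 5])
  expect_true(suit$values[6, 6])
})

test_that("adding conditions never gains cells; widening bounds never loses them", {
  set.seed(82)
  for (k in 1:8) {
    nr <- 15; nc <- 15
    climate <- climate_stack(
      lapply(1:12, function(m) grid_raster(matrix(runif(nr * nc, 30, 60),
                                                  nr, nc), 30)),
      lapply(1:12, function(m) grid_raster(matrix(runif(nr * nc, 0, 5),
                                                  nr, nc), 30)),
      lapply(1:12, function(m) grid_raster(matrix(runif(nr * nc, 10, 20),
                                                  nr, nc), 30))
    )
    soil <- soil_layers(grid_raster(matrix(runif(nr * nc, 0, 200), nr, nc), 30),
                        grid_raster(matrix(sample(1:4, nr * nc, TRUE),
                                           nr, nc), 30, kind = "categorical"))
    lu <- landuse_layer(grid_raster(matrix(sample(c(0, 61), nr * nc, TRUE),
                                           nr, nc), 30, kind = "categorical"),
                        c(other = 0, fallow_cropland = 61))
    region <- as_mask(matrix(TRUE, nr, nc), cell_size_m = 30)
    pb <- cbind(rep(35, 12), rep(55, 12))
    fewer <- crop_requirement("x", precip_bounds = pb, require_fallow = TRUE)
    more <- crop_requirement("x", precip_bounds = pb, soil_depth_min_cm = 100,
                             allowed_textures = c(1, 2), require_fallow = TRUE)
    n_fewer <- sum(evaluate_suitability(climate, soil, lu, fewer,
                                        region)$values)
    n_more <- sum(evaluate_suitability(climate, soil, lu, more,
                                       region)$values)
    expect_lte(n_more, n_fewer)

    wide <- crop_requirement("x", precip_bounds = cbind(rep(20, 12),
                                                        rep(70, 12)),
                             require_fallow = TRUE)
    n_wide <- sum(evaluate_suitability(climate, soil, lu, wide,
                                       region)$values)
    expect_gte(n_wide, n_fewer)

    # region nesting propagates to the result
    sub <- as_mask(matrix(FALSE, nr, nc), cell_size_m = 30)
    sub$values[1:8, 1:8] <- TRUE
    s_sub <- evaluate_suitability(climate, soil, lu, fewer, sub)$values
    s_full <- evaluate_suitability(climate, soil, lu, fewer, region)$values
    expect_true(all(s_full[s_sub]))
  }
})

test_that("requirement validation catches bad bounds and inactive parameters", {
  expect_error(crop_requirement("x", precip_bounds = cbind(1:12, 0:11)),
               "low > high")
  expect_error(crop_requirement("x", precip_bounds = cbind(1:6, 2:7)),
               "12 x 2")
  expect_error(crop_requirement("x", require_fallow = FALSE),
               "at least one condition")
  expect_warning(crop_requirement("x", soil_depth_min_cm = 50,
                                  allowed_textures = 1:2,
                                  active_conditions = c("soil_depth",
                                                        "landuse")),
                 "inactive")
  expect_error(crop_requirement("x", active_conditions = "precip"),
               "without parameters")
})
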