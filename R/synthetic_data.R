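# Seeded generators for grid-aligned input bundles with analytically known
# ground truth. They stand in for the national climate / soil / land-cover /
# county-acreage inputs of the real analysis, which are not packaged.

.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 1009) %% 2147483647)
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Grid specification for synthetic layers
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param cell_size_m cell side length (m); default 30 m, the working
#'   resolution of the real land-cover and suitability layers.
#' @param origin_xy planar coordinates of the upper-left outer corner.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(nrow = 300L, ncol = 300L, cell_size_m = 30,
                      origin_xy = c(0, 0)) {
  stopifnot(nrow >= 1L, ncol >= 1L, cell_size_m > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size_m = cell_size_m, origin_xy = origin_xy),
            class = "grid_spec")
}

.blank <- function(spec, fill = 0, kind = "continuous") {
  grid_raster(matrix(fill, spec$nrow, spec$ncol), spec$cell_size_m,
              spec$origin_xy, kind = kind)
}

# value(row) for one month: base + slope * (row - 1) + amp * sin wave.
# Fields vary along the row axis only, so zonal extrema over any zone that
# spans a contiguous row band equal the band's extreme-row values whenever
# slope dominates the wave.
.row_field <- function(spec, base, slope, amp, period, phase) {
  rows <- seq_len(spec$nrow)
  v <- base + slope * (rows - 1) + amp * sin(2 * pi * (rows / period + phase))
  matrix(v, spec$nrow, spec$ncol)
}

#' Generate a monthly climate stack
#'
#' Twelve months of precipitation and min/max surface temperature as smooth
#' north-south gradients (linear ramp along the row axis) plus a seeded
#' low-frequency sine perturbation, constant along columns. The ramp slope
#' is chosen to dominate the perturbation so the fields are strictly
#' monotone along rows; with `precip_amp = tmin_amp = 0` the stacks are pure
#' ramps with known endpoint extrema. `tmax` is `tmin` plus a positive
#' monthly offset, so `tmin <= tmax` holds everywhere by construction.
#'
#' @param spec a [grid_spec()].
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param precip_base,tmin_base length-12 monthly baselines (mm, degC).
#' @param precip_slope,tmin_slope ramp increments per row.
#' @param precip_amp,tmin_amp sine amplitudes (set 0 for pure ramps).
#' @param period sine period in rows.
#' @param tmax_offset monthly tmax minus tmin (positive).
#' @return A [climate_stack()].
#' @export
gen_climate <- function(spec, seed,
                        precip_base = 40 + 5 * sin(2 * pi * (1:12) / 12),
                        precip_slope = 1, precip_amp = 1,
                        tmin_base = 2 + 10 * sin(2 * pi * ((1:12) - 4) / 12),
                        tmin_slope = 0.1, tmin_amp = 0.02,
                        period = 80, tmax_offset = rep(9, 12)) {
  stopifnot(inherits(spec, "grid_spec"), all(tmax_offset > 0))
  phases <- .with_seed(.sub_seed(seed, 1L), stats::runif(24))
  mk <- function(base, slope, amp, phase) {
    grid_raster(.row_field(spec, base, slope, amp, period, phase),
                spec$cell_size_m, spec$origin_xy, kind = "continuous")
  }
  precip <- lapply(1:12, function(m)
    mk(precip_base[m], precip_slope, precip_amp, phases[m]))
  tmin <- lapply(1:12, function(m)
    mk(tmin_base[m], tmin_slope, tmin_amp, phases[12 + m]))
  tmax <- lapply(1:12, function(m) {
    r <- tmin[[m]]
    grid_raster(r$values + tmax_offset[m], spec$cell_size_m, spec$origin_xy,
                kind = "continuous")
  })
  climate_stack(precip, tmin, tmax)
}

#' Generate a county-label raster and acreage table
#'
#' Tiles the grid into a rectangular lattice of counties and builds a
#' harvested-acreage table (one crop) in which each county holds a
#' designated share of mean national acreage. Year-to-year variation is a
#' seeded multiplicative factor applied to every county alike, which leaves
#' all shares of the means exactly at their designated values.
#'
#' @param spec a [grid_spec()].
#' @param seed integer seed.
#' @param tiles `c(rows_of_tiles, cols_of_tiles)`; tiles must divide the
#'   grid evenly.
#' @param shares numeric vector, one share per tile in row-major tile order,
#'   summing to 1.
#' @param years years covered by the acreage table.
#' @param national_ha mean national harvested area (ha).
#' @param crop_id crop identifier written into the table.
#' @return List: `county_raster` (categorical codes 1..n, row-major tile
#'   order), `county_codes` (named code map, names `county_01`...),
#'   `acreage` tibble (`crop_id`, `county_id`, `state`, `year`, `acreage`).
#' @export
gen_counties <- function(spec, seed, tiles = c(3L, 3L), shares = NULL,
                         years = 2002:2012, national_ha = 1e4,
                         crop_id = "crop_a") {
  stopifnot(inherits(spec, "grid_spec"),
            spec$nrow %% tiles[1L] == 0L, spec$ncol %% tiles[2L] == 0L)
  n <- tiles[1L] * tiles[2L]
  if (is.null(shares)) shares <- rep(1 / n, n)
  if (length(shares) != n || any(shares < 0)) {
    stop("design error: need one non-negative share per county tile",
         call. = FALSE)
  }
  if (sum(shares) > 1 + 1e-9) {
    stop("design error: shares exceed 1", call. = FALSE)
  }
  th <- spec$nrow %/% tiles[1L]; tw <- spec$ncol %/% tiles[2L]
  tile_row <- (seq_len(spec$nrow) - 1L) %/% th
  tile_col <- (seq_len(spec$ncol) - 1L) %/% tw
  codes <- outer(tile_row, tile_col, function(r, co) r * tiles[2L] + co + 1)
  ids <- sprintf("county_%02d", seq_len(n))
  county_codes <- stats::setNames(seq_len(n), ids)
  year_factor <- .with_seed(.sub_seed(seed, 2L),
                            stats::runif(length(years), 0.8, 1.2))
  acreage <- tidyr::expand_grid(county = seq_len(n), yi = seq_along(years))
  acreage <- tibble::tibble(
    crop_id = crop_id,
    county_id = ids[acreage$county],
    state = sprintf("state_%02d", acreage$county),
    year = years[acreage$yi],
    acreage = national_ha * shares[acreage$county] * year_factor[acreage$yi] *
      length(years) / sum(year_factor)
  )
  list(
    county_raster = grid_raster(codes, spec$cell_size_m, spec$origin_xy,
                                kind = "categorical"),
    county_codes = county_codes,
    acreage = acreage
  )
}

#' Design for a ground-truth test case
#'
#' Fixes the geometry and economics of a [gen_truth_case()] bundle. One
#' county tile (the center tile of a 3 x 3 tiling, western column) holds the
#' dominant acreage share and becomes the single production center. A target
#' rectangle of fallow land inside that county is the only suitable land at
#' no expansion; one additional fallow rectangle sits analytically inside
#' each successive buffer annulus east of the county; distractor fallow
#' rectangles each fail exactly one condition (soil too shallow, texture not
#' allowed, climate outside the center's range, or beyond the largest
#' buffer).
#'
#' The default grid is 300 x 300 cells at 150 m (45 km x 45 km): large
#' enough that the full 0/5/10/15/20 km scenario set fits inside the grid
#' with the annulus rectangles placed strictly between consecutive buffer
#' fronts.
#'
#' @param nrow,ncol,cell_size_m grid geometry.
#' @param buffers_km scenario buffer distances (must start at 0, ascending).
#' @param center_share national-acreage share of the center county.
#' @param target_rows,target_cols number of rows/cols of the no-expansion
#'   target rectangle.
#' @param soil_depth_min_cm,allowed_textures requirement parameters.
#' @param yield_kg_ha,farm_loss,retail_loss,consumer_loss,cups_per_kg,population
#'   availability-chain parameters; `NULL` means draw from the seeded ranges
#'   in [gen_truth_case()].
#' @return A `truth_design` list.
#' @export
truth_design <- function(nrow = 300L, ncol = 300L, cell_size_m = 150,
                         buffers_km = c(0, 5, 10, 15, 20),
                         center_share = 0.55,
                         target_rows = 20L, target_cols = 30L,
                         soil_depth_min_cm = 50,
                         allowed_textures = c(1, 2, 3),
                         yield_kg_ha = NULL, farm_loss = NULL,
                         retail_loss = NULL, consumer_loss = NULL,
                         cups_per_kg = NULL, population = 1e6) {
  stopifnot(buffers_km[1L] == 0, !is.unsorted(buffers_km, strictly = TRUE),
            nrow %% 3L == 0L, ncol %% 3L == 0L)
  max_cells <- max(buffers_km) * 1000 / cell_size_m
  if ((ncol %/% 3L) + max_cells + 2 > ncol) {
    stop("generation error: largest buffer does not fit east of the center ",
         "county on this grid", call. = FALSE)
  }
  structure(list(
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    cell_size_m = cell_size_m, buffers_km = buffers_km,
    center_share = center_share,
    target_rows = as.integer(target_rows), target_cols = as.integer(target_cols),
    soil_depth_min_cm = soil_depth_min_cm, allowed_textures = allowed_textures,
    yield_kg_ha = yield_kg_ha, farm_loss = farm_loss,
    retail_loss = retail_loss, consumer_loss = consumer_loss,
    cups_per_kg = cups_per_kg, population = population
  ), class = "truth_design")
}

#' Generate a complete input bundle with known expected results
#'
#' Builds every input layer and table the pipeline needs, plus the expected
#' suitable mask, suitable area (ha) and per-capita availability
#' (cups/person/day) for every buffer scenario. All expected values are
#' computed in closed form from the construction (rectangle cell counts
#' times cell area; the yield/loss/cup chain applied by hand), never by
#' running the pipeline.
#'
#' @param design a [truth_design()].
#' @param seed integer seed; drives the climate perturbation, acreage year
#'   factors, annulus rectangle sizes and (when not pinned in the design)
#'   the economic parameters.
#' @return A `truth_case` list: `inputs` (ready for [run_pipeline()]),
#'   `params`, `expected` (tibble `buffer_km`, `area_ha`, `cups`),
#'   `expected_masks` (one boolean raster per buffer), `seed`, `design`.
#' @export
gen_truth_case <- function(design = truth_design(), seed = 1L) {
  stopifnot(inherits(design, "truth_design"))
  spec <- grid_spec(design$nrow, design$ncol, design$cell_size_m)
  cellsz <- design$cell_size_m
  th <- design$nrow %/% 3L; tw <- design$ncol %/% 3L  # tile height/width
  # center county: tile (2, 1) -> rows th+1 .. 2*th, cols 1 .. tw
  c_r0 <- th + 1L; c_r1 <- 2L * th; c_c0 <- 1L; c_c1 <- tw

  # --- counties & acreage (center tile gets the dominant share) -----------
  n_tiles <- 9L
  others <- (1 - design$center_share) / (n_tiles - 1L)
  shares <- rep(others, n_tiles); shares[4L] <- design$center_share
  cty <- gen_counties(spec, seed, tiles = c(3L, 3L), shares = shares,
                      crop_id = "crop_a")
  center_id <- "county_04"

  # --- climate (row-only fields; center rows bracket every in-band cell) ---
  climate <- gen_climate(spec, seed)

  # --- geometry of suitable rectangles ------------------------------------
  rect <- function(r0, nr_, c0, nc_) {
    list(rows = r0:(r0 + nr_ - 1L), cols = c0:(c0 + nc_ - 1L),
         n = nr_ * nc_)
  }
  target <- rect(c_r0 + 34L, design$target_rows, 40L, design$target_cols)
  stopifnot(max(target$rows) <= c_r1, max(target$cols) <= c_c1)

  buffers <- design$buffers_km
  ring_rects <- list()
  if (length(buffers) > 1L) {
    dims <- .with_seed(.sub_seed(seed, 3L), {
      list(h = sample(8:18, length(buffers) - 1L, replace = TRUE),
           w = sample(5:15, length(buffers) - 1L, replace = TRUE))
    })
    for (i in seq_len(length(buffers) - 1L)) {
      inner_k <- floor(buffers[i] * 1000 / cellsz) + 2L      # > previous front
      outer_k <- floor(buffers[i + 1L] * 1000 / cellsz) - 1L # <= this front
      w <- min(dims$w[i], outer_k - inner_k + 1L)
      r0 <- c_r0 + 4L + (i - 1L) * 22L
      stopifnot(w >= 1L, r0 + dims$h[i] - 1L <= c_r1)
      ring_rects[[i]] <- rect(r0, dims$h[i], c_c1 + inner_k, w)
    }
  }

  # distractors: fallow but each failing exactly one condition
  d_soil <- rect(c_r1 - 14L, 10L, 40L, 10L)      # depth below the minimum
  d_text <- rect(c_r0 + 49L, 10L, 5L, 10L)       # disallowed texture class
  d_clim <- rect(c_r1 + 5L, 5L, 40L, 10L)        # rows outside center band
  d_far <- rect(1L, 10L, design$ncol - 19L, 10L) # beyond the largest buffer
  paint <- function(m, r, val) { m[r$rows, r$cols] <- val; m }

  # --- soil ----------------------------------------------------------------
  depth <- matrix(100, design$nrow, design$ncol)
  depth <- paint(depth, d_soil, design$soil_depth_min_cm / 5)
  texture <- matrix(design$allowed_textures[1L], design$nrow, design$ncol)
  texture <- paint(texture, d_text, max(design$allowed_textures) + 6)
  soil <- soil_layers(
    grid_raster(depth, cellsz, kind = "continuous"),
    grid_raster(texture, cellsz, kind = "categorical")
  )

  # --- land use ------------------------------------------------------------
  code_table <- c(other = 0L, crop_a = 10L, fallow_cropland = 61L)
  lu <- matrix(0, design$nrow, design$ncol)
  lu <- paint(lu, rect(c_r0 + 9L, 10L, 10L, 20L), 10L)  # current cultivation
  for (r in c(list(target), ring_rects, list(d_soil, d_text, d_clim, d_far))) {
    lu <- paint(lu, r, 61L)
  }
  landuse <- landuse_layer(
    grid_raster(lu, cellsz, kind = "categorical"), code_table
  )

  # --- economics (seeded unless pinned in the design) ----------------------
  econ <- .with_seed(.sub_seed(seed, 4L), list(
    yield = stats::runif(1, 8000, 16000),
    farm = stats::runif(1, 0.02, 0.25),
    retail = stats::runif(1, 0.02, 0.25),
    consumer = stats::runif(1, 0.05, 0.40),
    cups = stats::runif(1, 0.5, 5)
  ))
  yield_kg_ha <- design$yield_kg_ha %||% econ$yield
  chain <- loss_chain(
    "crop_a",
    farm_loss = design$farm_loss %||% econ$farm,
    retail_loss = design$retail_loss %||% econ$retail,
    consumer_loss = design$consumer_loss %||% econ$consumer,
    cups_per_kg = design$cups_per_kg %||% econ$cups
  )

  # --- expected results, in closed form ------------------------------------
  cell_ha <- cellsz^2 / 1e4
  ring_cells <- vapply(ring_rects, function(r) r$n, numeric(1))
  cum_cells <- cumsum(c(target$n, ring_cells))
  area_ha <- cum_cells * cell_ha
  kg_to_cups <- (1 - chain$farm_loss) * (1 - chain$retail_loss) *
    (1 - chain$consumer_loss) * chain$cups_per_kg
  cups <- area_ha * yield_kg_ha * kg_to_cups / design$population / 365
  expected <- tibble::tibble(buffer_km = buffers, area_ha = area_ha,
                             cups = cups)
  expected_masks <- lapply(seq_along(buffers), function(i) {
    m <- matrix(FALSE, design$nrow, design$ncol)
    for (r in c(list(target), ring_rects[seq_len(i - 1L)])) {
      m <- paint(m, r, TRUE)
    }
    as_mask(m, cell_size_m = cellsz)
  })
  names(expected_masks) <- paste0("km_", buffers)

  requirement <- list(
    crop_id = "crop_a",
    derive_climate = TRUE,    # climate bounds from the center's own range
    soil_depth_min_cm = design$soil_depth_min_cm,
    allowed_textures = design$allowed_textures,
    require_fallow = TRUE
  )
  inputs <- list(
    climate = climate, soil = soil, landuse = landuse,
    county_raster = cty$county_raster, county_codes = cty$county_codes,
    acreage = cty$acreage,
    yields = tibble::tibble(crop_id = "crop_a",
                            state = sprintf("state_%02d", 4L),
                            yield_kg_ha = yield_kg_ha),
    losses = list(crop_a = chain),
    population = design$population,
    requirements = list(crop_a = requirement)
  )
  params <- list(threshold = 0.10, buffers_km = buffers,
                 year_range = 2002:2012)
  structure(list(inputs = inputs, params = params, expected = expected,
                 expected_masks = expected_masks, seed = seed,
                 design = design, center_id = center_id),
            class = "truth_case")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
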