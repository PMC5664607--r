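#' Run the full site-suitability and availability pipeline
#'
#' Executes the end-to-end sequence for every crop in the inputs: national
#' acreage shares -> production centers (abutting eligible counties merged)
#' -> per-scenario buffer regions -> boolean suitability overlay ->
#' loss-adjusted per-capita availability -> report tables. Results are
#' cumulative in buffer distance by construction (regions are nested).
#'
#' When one crop has several centers, each center's suitable cells are
#' attributed to that center (and its state's yield); cells claimed by a
#' higher-share center are not double counted when expanded regions overlap.
#'
#' @param inputs list with components: `climate` ([climate_stack()]), `soil`
#'   ([soil_layers()]), `landuse` ([landuse_layer()]), `county_raster`
#'   (categorical `grid_raster`), `county_codes` (named map county_id ->
#'   code), `acreage` (tibble `crop_id`, `county_id`, `state`, `year`,
#'   `acreage`), `yields` (tibble `crop_id`, `state`, `yield_kg_ha`),
#'   `losses` (named list of [loss_chain()] per crop), `population`,
#'   `requirements` (named list per crop: either a [crop_requirement()] or a
#'   list with `derive_climate = TRUE` plus soil/texture/fallow fields, in
#'   which case monthly climate bounds are derived from each center's own
#'   range).
#' @param params list: `threshold` (default 0.10), `buffers_km` (default
#'   `c(0, 5, 10, 15, 20)`), `year_range` (default all years present),
#'   `clip` (optional mask), `keep_masks` (default `FALSE`).
#' @return List: `results` (long tibble `crop_id`, `buffer_km`,
#'   `suitable_area_ha`, `production_kg_farm`, `cups_per_capita_day`,
#'   cumulative in buffer), `area_table` and `cups_table`
#'   ([scenario_table()] layouts, full precision), `centers` (per crop),
#'   `log` (per crop x center x buffer filter cascades and config echo), and
#'   `masks` when requested.
#' @export
run_pipeline <- function(inputs, params = list()) {
  threshold <- params$threshold %||% 0.10
  buffers_km <- params$buffers_km %||% c(0, 5, 10, 15, 20)
  year_range <- params$year_range %||% sort(unique(inputs$acreage$year))
  keep_masks <- isTRUE(params$keep_masks)
  stopifnot(!is.unsorted(buffers_km, strictly = TRUE), buffers_km[1L] == 0)

  adjacency <- county_adjacency(inputs$county_raster, inputs$county_codes)
  crops <- unique(inputs$acreage$crop_id)
  all_rows <- list(); all_centers <- list(); logs <- list(); masks <- list()

  for (crop in crops) {
    acr <- inputs$acreage[inputs$acreage$crop_id == crop, ]
    shares <- mean_national_share(acr, year_range)
    centers <- identify_centers(shares, adjacency, threshold)
    all_centers[[crop]] <- centers
    if (nrow(centers) == 0L) {
      stop("pipeline error at stage 'centers': no production center reaches ",
           "threshold ", threshold, " for crop '", crop, "'", call. = FALSE)
    }
    state_of <- stats::setNames(acr$state, acr$county_id)
    chain <- inputs$losses[[crop]]
    if (is.null(chain)) {
      stop("pipeline error at stage 'availability': no loss chain for crop '",
           crop, "'", call. = FALSE)
    }

    center_info <- lapply(seq_len(nrow(centers)), function(i) {
      cmask <- center_mask(centers$county_ids[[i]], inputs$county_raster,
                           inputs$county_codes)
      list(mask = cmask, sq = .sq_dist_to_true(cmask$values),
           state = unname(state_of[centers$county_ids[[i]][1L]]),
           req = .resolve_requirement(inputs$requirements[[crop]], crop,
                                      inputs$climate, cmask))
    })

    area_by_buffer <- numeric(length(buffers_km))
    prod_by_buffer <- numeric(length(buffers_km))
    for (bi in seq_along(buffers_km)) {
      b <- buffers_km[bi]
      claimed <- NULL
      area_b <- 0; prod_b <- 0
      for (ci in seq_along(center_info)) {
        info <- center_info[[ci]]
        region <- expand_center(info$mask, b, sq_cell_dist = info$sq,
                                clip = params$clip)
        suit <- evaluate_suitability(inputs$climate, inputs$soil,
                                     inputs$landuse, info$req, region)
        sv <- suit$values
        if (!is.null(claimed)) sv <- sv & !claimed
        claimed <- if (is.null(claimed)) sv else claimed | sv
        a <- sum(sv) * cell_area_ha(suit)
        yld <- .lookup_yield(inputs$yields, crop, info$state)
        area_b <- area_b + a
        prod_b <- prod_b + production_from_area(a, yld)
        logs[[sprintf("%s|%s|km_%g", crop, centers$center_id[ci], b)]] <-
          attr(suit, "cascade")
      }
      area_by_buffer[bi] <- area_b
      prod_by_buffer[bi] <- prod_b
      if (keep_masks) {
        masks[[sprintf("%s|km_%g", crop, b)]] <-
          as_mask(claimed, template = inputs$county_raster)
      }
    }
    cups <- per_capita_cups(loss_adjust(prod_by_buffer, chain), chain,
                            inputs$population)
    all_rows[[crop]] <- tibble::tibble(
      crop_id = crop, buffer_km = buffers_km,
      suitable_area_ha = area_by_buffer,
      production_kg_farm = prod_by_buffer,
      cups_per_capita_day = cups
    )
  }
  results <- dplyr::bind_rows(all_rows)
  out <- list(
    results = results,
    area_table = scenario_table(
      dplyr::rename(results[, c("crop_id", "buffer_km", "suitable_area_ha")],
                    value = "suitable_area_ha")),
    cups_table = scenario_table(
    dplyr::rename(results[, c("crop_id", "buffer_km", "cups_per_capita_day")],
                  value = "cups_per_capita_day")),
    centers = all_centers,
    log = list(cascades = logs,
               config = list(threshold = threshold, buffers_km = buffers_km,
                             year_range = year_range))
  )
  if (keep_masks) out$masks <- masks
  out
}

.lookup_yield <- function(yields, crop, state) {
  hit <- yields[yields$crop_id == crop & yields$state == state, ]
  if (nrow(hit) == 0L) hit <- yields[yields$crop_id == crop, ]
  if (nrow(hit) == 0L) {
    stop("pipeline error at stage 'availability': no yield for crop '",
         crop, "'", call. = FALSE)
  }
  hit$yield_kg_ha[1L]
}

# A requirement may be a finished crop_requirement, or a recipe asking for
# climate bounds derived from the center's own range (the fallback when
# published reports lack resolution).
.resolve_requirement <- function(req, crop, climate, center_mask_) {
  if (inherits(req, "crop_requirement")) return(req)
  if (is.null(req)) {
    stop("pipeline error at stage 'suitability': no requirement for crop '",
         crop, "'", call. = FALSE)
  }
  if (isTRUE(req$derive_climate)) {
    b <- derive_bounds(climate, center_mask_, provenance = "whole_center")
    crop_requirement(
      crop_id = crop, precip_bounds = b$precip, tmin_bounds = b$tmin,
      tmax_bounds = b$tmax,
      soil_depth_min_cm = req$soil_depth_min_cm,
      allowed_textures = req$allowed_textures,
      require_fallow = req$require_fallow %||% TRUE
    )
  } else {
    do.call(crop_requirement,
            c(list(crop_id = crop),
              req[setdiff(names(req), c("derive_climate", "crop_id"))]))
  }
}

# ---- bundle I/O ------------------------------------------------------------

#' Write a synthetic input bundle to disk
#'
#' Emits the plain-text formats the pipeline reads: ESRI ASCII grids for
#' every raster layer, CSV tables for acreage, yields, losses and
#' population, a YAML run config, and the expected results as JSON. The
#' output of one seed is byte-identical across runs.
#'
#' @param case a [gen_truth_case()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(case, dir) {
  stopifnot(inherits(case, "truth_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  inp <- case$inputs
  for (m in 1:12) {
    write_ascii_grid(inp$climate$precip[[m]], p(sprintf("precip_%02d.asc", m)))
    write_ascii_grid(inp$climate$tmin[[m]], p(sprintf("tmin_%02d.asc", m)))
    write_ascii_grid(inp$climate$tmax[[m]], p(sprintf("tmax_%02d.asc", m)))
  }
  write_ascii_grid(inp$soil$depth, p("soil_depth.asc"))
  write_ascii_grid(inp$soil$texture, p("soil_texture.asc"))
  write_ascii_grid(inp$landuse$raster, p("landuse.asc"))
  write_ascii_grid(inp$county_raster, p("counties.asc"))
  utils::write.csv(inp$acreage, p("acreage.csv"), row.names = FALSE)
  utils::write.csv(inp$yields, p("yields.csv"), row.names = FALSE)
  losses <- dplyr::bind_rows(lapply(inp$losses, function(ch) {
    tibble::tibble(crop_id = ch$crop_id, farm_loss = ch$farm_loss,
                   retail_loss = ch$retail_loss,
                   consumer_loss = ch$consumer_loss,
                   cups_per_kg = ch$cups_per_kg)
  }))
  utils::write.csv(losses, p("losses.csv"), row.names = FALSE)
  reqs <- lapply(inp$requirements, function(r) {
    if (inherits(r, "crop_requirement")) r <- unclass(r)
    lapply(r, function(x) if (is.matrix(x)) apply(x, 1L, as.numeric,
                                                  simplify = FALSE) else x)
  })
  cfg <- list(
    crop_codes = as.list(inp$landuse$code_table),
    county_codes = as.list(inp$county_codes),
    population = inp$population,
    threshold = case$params$threshold,
    buffers_km = case$params$buffers_km,
    year_range = range(case$params$year_range),
    seed = case$seed,
    requirements = reqs
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  jsonlite::write_json(case$expected, p("expected.json"), digits = NA)
  invisible(dir)
}

#' Read an input bundle from disk
#'
#' Inverse of [write_bundle()]: reconstructs the `inputs` and `params` lists
#' that [run_pipeline()] consumes.
#'
#' @param dir bundle directory.
#' @return List with `inputs` and `params`.
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  cfg <- yaml::read_yaml(p("config.yaml"))
  rd12 <- function(stem) lapply(1:12, function(m)
    read_ascii_grid(p(sprintf("%s_%02d.asc", stem, m)), "continuous"))
  climate <- climate_stack(rd12("precip"), rd12("tmin"), rd12("tmax"))
  soil <- soil_layers(read_ascii_grid(p("soil_depth.asc"), "continuous"),
                      read_ascii_grid(p("soil_texture.asc"), "categorical"))
  landuse <- landuse_layer(read_ascii_grid(p("landuse.asc"), "categorical"),
                           unlist(cfg$crop_codes))
  losses_df <- utils::read.csv(p("losses.csv"))
  losses <- lapply(split(losses_df, losses_df$crop_id), function(r)
    loss_chain(r$crop_id, r$farm_loss, r$retail_loss, r$consumer_loss,
               r$cups_per_kg))
  reqs <- lapply(cfg$requirements, function(r) {
    for (f in c("precip_bounds", "tmin_bounds", "tmax_bounds")) {
      if (!is.null(r[[f]])) {
        r[[f]] <- do.call(rbind, r[[f]])
      }
    }
    r
  })
  inputs <- list(
    climate = climate, soil = soil, landuse = landuse,
    county_raster = read_ascii_grid(p("counties.asc"), "categorical"),
    county_codes = unlist(cfg$county_codes),
    acreage = tibble::as_tibble(utils::read.csv(p("acreage.csv"))),
    yields = tibble::as_tibble(utils::read.csv(p("yields.csv"))),
    losses = losses,
    population = cfg$population,
    requirements = reqs
  )
  params <- list(threshold = cfg$threshold,
                 buffers_km = as.numeric(cfg$buffers_km),
                 year_range = seq(cfg$year_range[[1]], cfg$year_range[[2]]))
  list(inputs = inputs, params = params)
}
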