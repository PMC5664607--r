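#' Crop growing-requirement parameterization
#'
#' Bundles the growing conditions of one crop. Only the conditions named in
#' `active_conditions` participate in the overlay ("only the growing
#' conditions relevant to a given crop" enter its model); bounds supplied for
#' inactive conditions trigger a configuration warning. All bound
#' comparisons downstream are inclusive: derived bounds come from observed
#' extrema, which must themselves remain suitable.
#'
#' @param crop_id crop identifier.
#' @param precip_bounds,tmin_bounds,tmax_bounds optional 12 x 2 matrices of
#'   monthly (low, high) bounds — precipitation in mm, temperatures in
#'   degrees C; rows are months January..December.
#' @param soil_depth_min_cm optional minimum soil depth (cm).
#' @param allowed_textures optional vector of allowed texture-class codes.
#' @param require_fallow must the cell be fallow cropland? Default `TRUE`.
#' @param active_conditions character subset of
#'   `c("precip", "tmin", "tmax", "soil_depth", "texture", "landuse")`; at
#'   least one. Defaults to every condition for which a parameter was
#'   supplied (plus `"landuse"` when `require_fallow`).
#' @return An object of class `crop_requirement`.
#' @export
crop_requirement <- function(crop_id, precip_bounds = NULL, tmin_bounds = NULL,
                             tmax_bounds = NULL, soil_depth_min_cm = NULL,
                             allowed_textures = NULL, require_fallow = TRUE,
                             active_conditions = NULL) {
  chk_bounds <- function(b, what) {
    if (is.null(b)) return(NULL)
    b <- as.matrix(b)
    if (!all(dim(b) == c(12L, 2L))) {
      stop(what, " bounds must be a 12 x 2 (low, high) matrix", call. = FALSE)
    }
    if (any(b[, 1L] > b[, 2L], na.rm = TRUE)) {
      stop(what, " bounds have low > high", call. = FALSE)
    }
    colnames(b) <- c("low", "high")
    b
  }
  precip_bounds <- chk_bounds(precip_bounds, "precip")
  tmin_bounds <- chk_bounds(tmin_bounds, "tmin")
  tmax_bounds <- chk_bounds(tmax_bounds, "tmax")
  supplied <- c(
    precip = !is.null(precip_bounds), tmin = !is.null(tmin_bounds),
    tmax = !is.null(tmax_bounds), soil_depth = !is.null(soil_depth_min_cm),
    texture = !is.null(allowed_textures), landuse = isTRUE(require_fallow)
  )
  all_conditions <- names(supplied)
  if (is.null(active_conditions)) {
    active_conditions <- all_conditions[supplied]
  }
  if (!all(active_conditions %in% all_conditions)) {
    stop("unknown condition(s): ",
         paste(setdiff(active_conditions, all_conditions), collapse = ", "),
         call. = FALSE)
  }
  if (length(active_conditions) == 0L) {
    stop("at least one condition must be active", call. = FALSE)
  }
  idle <- all_conditions[supplied & !all_conditions %in% active_conditions]
  idle <- setdiff(idle, "landuse")
  if (length(idle)) {
    warning("parameters supplied for inactive condition(s): ",
            paste(idle, collapse = ", "))
  }
  missing_par <- setdiff(active_conditions, all_conditions[supplied])
  if (length(missing_par)) {
    stop("active condition(s) without parameters: ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  structure(
    list(crop_id = crop_id, precip_bounds = precip_bounds,
         tmin_bounds = tmin_bounds, tmax_bounds = tmax_bounds,
         soil_depth_min_cm = soil_depth_min_cm,
         allowed_textures = allowed_textures,
         require_fallow = isTRUE(require_fallow),
         active_conditions = active_conditions),
    class = "crop_requirement"
  )
}

#' Derive climate bounds from a reference zone
#'
#' When published reports lack the resolution to parameterize a condition,
#' the range of values observed in the crop's own production center (or its
#' 95%-cultivation clusters) stands in: per variable and month, low/high are
#' the zonal minimum/maximum. Every cell inside the zone therefore satisfies
#' its own derived bounds.
#'
#' @param stack a [climate_stack()].
#' @param zone boolean `grid_raster` reference zone (non-empty).
#' @param provenance `"whole_center"` or `"crop_clusters"`, recorded for the
#'   run log.
#' @return List with 12 x 2 matrices `precip`, `tmin`, `tmax` and the
#'   `provenance` tag; ready to splice into [crop_requirement()].
#' @export
derive_bounds <- function(stack, zone,
                          provenance = c("whole_center", "crop_clusters")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(stack, "climate_stack"))
  one_var <- function(layers) {
    b <- t(vapply(layers, function(r) zonal_min_max(r, zone), numeric(2)))
    colnames(b) <- c("low", "high")
    b
  }
  list(precip = one_var(stack$precip), tmin = one_var(stack$tmin),
       tmax = one_var(stack$tmax), provenance = provenance)
}

#' Clusters covering at least a fraction of a crop's cultivated cells
#'
#' Labels the connected clusters of cells cultivating `crop_code`, sorts them
#' by size (descending; ties broken by smaller label, i.e. scan order) and
#' returns the union of the smallest prefix whose cumulative cell count
#' reaches `coverage` of all the crop's cells. Used to focus derived climate
#' bounds on where at least 95% of a crop is actually grown.
#'
#' @param landuse a [landuse_layer()].
#' @param crop_code land-use code (or code-table name) of the crop's
#'   cultivation class.
#' @param coverage required fraction of crop cells, default 0.95.
#' @param connectivity passed to [connected_components()].
#' @return Boolean `grid_raster` of the selected clusters.
#' @export
crop_clusters <- function(landuse, crop_code, coverage = 0.95,
                          connectivity = "edge") {
  stopifnot(inherits(landuse, "landuse_layer"), coverage > 0, coverage <= 1)
  if (is.character(crop_code)) {
    if (!crop_code %in% names(landuse$code_table)) {
      stop("crop code '", crop_code, "' not in the land-use code table",
           call. = FALSE)
    }
    crop_code <- landuse$code_table[[crop_code]]
  }
  crop_cells <- as_mask(!is.na(landuse$raster$values) &
                          landuse$raster$values == crop_code,
                        template = landuse$raster)
  total <- sum(crop_cells$values)
  if (total == 0L) {
    stop("empty-crop error: no cells cultivate code ", crop_code,
         call. = FALSE)
  }
  lab <- connected_components(crop_cells, connectivity)
  sizes <- tabulate(lab$values[lab$values > 0])
  ord <- order(-sizes, seq_along(sizes))   # size desc, then scan-order label
  cum <- cumsum(sizes[ord])
  need <- which(cum >= coverage * total)[1L]
  keep <- ord[seq_len(need)]
  as_mask(matrix(lab$values %in% keep, nrow(lab$values), ncol(lab$values)) &
            lab$values > 0,
          template = crop_cells)
}

#' Boolean site-suitability overlay for one crop
#'
#' A cell is suitable iff every active condition holds simultaneously: it
#' lies in the analysis region; its land use is fallow cropland (when
#' required); for every month its precipitation, minimum temperature and
#' maximum temperature fall inclusively within the crop's bounds (for the
#' active climate variables); its soil is at least the minimum depth; and
#' its texture class is allowed. A `NA` (nodata) cell in any active layer is
#' unsuitable — a conservative reading of "all growing conditions
#' satisfied".
#'
#' The returned mask carries a `"cascade"` attribute: the number of cells
#' surviving after each condition is applied in turn, an audit trail showing
#' which constraint binds.
#'
#' @param climate a [climate_stack()] (may be `NULL` if no climate condition
#'   is active).
#' @param soil a [soil_layers()] (may be `NULL` if no soil condition is
#'   active).
#' @param landuse a [landuse_layer()] (may be `NULL` if land use inactive).
#' @param req a [crop_requirement()].
#' @param region boolean `grid_raster`, the analysis region.
#' @return Boolean `grid_raster` of suitable cells, with attribute
#'   `"cascade"` (named integer vector).
#' @export
evaluate_suitability <- function(climate, soil, landuse, req, region) {
  stopifnot(inherits(req, "crop_requirement"), is_grid_raster(region),
            region$kind == "boolean")
  active <- req$active_conditions
  layers <- list(region)
  if (any(c("precip", "tmin", "tmax") %in% active)) {
    stopifnot(inherits(climate, "climate_stack"))
    layers <- c(layers, climate$precip[1L])
  }
  if (any(c("soil_depth", "texture") %in% active)) {
    stopifnot(inherits(soil, "soil_layers"))
    layers <- c(layers, list(soil$depth))
  }
  if ("landuse" %in% active) {
    stopifnot(inherits(landuse, "landuse_layer"))
    layers <- c(layers, list(landuse$raster))
  }
  if (length(layers) > 1L) do.call(.stop_misaligned, layers)

  ok <- region$values
  cascade <- c(region = sum(ok))
  monthly_ok <- function(ok, layers, bounds) {
    for (m in 1:12) {
      v <- layers[[m]]$values
      ok <- ok & !is.na(v) & v >= bounds[m, 1L] & v <= bounds[m, 2L]
    }
    ok
  }
  if ("landuse" %in% active) {
    v <- landuse$raster$values
    fallow <- landuse$code_table[["fallow_cropland"]]
    ok <- ok & !is.na(v) & v == fallow
    cascade <- c(cascade, landuse = sum(ok))
  }
  if ("precip" %in% active) {
    ok <- monthly_ok(ok, climate$precip, req$precip_bounds)
    cascade <- c(cascade, precip = sum(ok))
  }
  if ("tmin" %in% active) {
    ok <- monthly_ok(ok, climate$tmin, req$tmin_bounds)
    cascade <- c(cascade, tmin = sum(ok))
  }
  if ("tmax" %in% active) {
    ok <- monthly_ok(ok, climate$tmax, req$tmax_bounds)
    cascade <- c(cascade, tmax = sum(ok))
  }
  if ("soil_depth" %in% active) {
    v <- soil$depth$values
    ok <- ok & !is.na(v) & v >= req$soil_depth_min_cm
    cascade <- c(cascade, soil_depth = sum(ok))
  }
  if ("texture" %in% active) {
    v <- soil$texture$values
    ok <- ok & !is.na(v) &
      matrix(v %in% req$allowed_textures, nrow(v), ncol(v))
    cascade <- c(cascade, texture = sum(ok))
  }
  out <- as_mask(ok, template = region)
  attr(out, "cascade") <- cascade
  out
}
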