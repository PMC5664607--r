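#' Mean national acreage shares by county
#'
#' For one crop, each county's share of mean national harvested acreage over
#' a year range: (mean county acreage over the years) / (mean national total
#' over the years). Years absent from a county's records count as zero
#' acreage for that county. Shares over all counties sum to 1.
#'
#' @param acreage long data frame for one crop: columns `county_id`, `state`,
#'   `year`, `acreage` (ha, non-negative).
#' @param year_range integer vector of years to average over (e.g.
#'   `2002:2012`); defaults to all years present.
#' @return Tibble `county_id`, `state`, `mean_acreage_ha`, `share`, sorted by
#'   descending share.
#' @export
mean_national_share <- function(acreage, year_range = NULL) {
  stopifnot(all(c("county_id", "state", "year", "acreage") %in% names(acreage)))
  if (any(acreage$acreage < 0, na.rm = TRUE)) {
    stop("acreage must be non-negative", call. = FALSE)
  }
  if (is.null(year_range)) year_range <- sort(unique(acreage$year))
  if (length(year_range) == 0L) stop("empty year range", call. = FALSE)
  a <- acreage[acreage$year %in% year_range, ]
  out <- a |>
    dplyr::group_by(.data$county_id, .data$state) |>
    dplyr::summarise(mean_acreage_ha = sum(.data$acreage) / length(year_range),
                     .groups = "drop")
  national <- sum(out$mean_acreage_ha)
  if (!is.finite(national) || national <= 0) {
    stop("degenerate-data error: national mean acreage is zero", call. = FALSE)
  }
  out$share <- out$mean_acreage_ha / national
  dplyr::arrange(out, dplyr::desc(.data$share))
}

#' Derive county adjacency from a county-label raster
#'
#' Two counties abut when any cell of one shares an edge (rook rule) with a
#' cell of the other; corner-only contact does not count.
#'
#' @param county_raster categorical `grid_raster` of county ids (numeric
#'   codes; `NA` outside counties) or a named code table attached via
#'   `county_ids` mapping id -> code.
#' @param county_ids optional named vector mapping county_id name -> raster
#'   code; when supplied the result uses the names.
#' @return Tibble of unordered adjacent pairs, columns `a`, `b`.
#' @export
county_adjacency <- function(county_raster, county_ids = NULL) {
  stopifnot(is_grid_raster(county_raster))
  m <- county_raster$values
  nr <- nrow(m); nc <- ncol(m)
  pairs <- rbind(
    cbind(as.vector(m[-nr, , drop = FALSE]), as.vector(m[-1L, , drop = FALSE])),
    cbind(as.vector(m[, -nc, drop = FALSE]), as.vector(m[, -1L, drop = FALSE]))
  )
  pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1L] != pairs[, 2L], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(a = character(0), b = character(0)))
  }
  pairs <- unique(cbind(pmin(pairs[, 1L], pairs[, 2L]),
                        pmax(pairs[, 1L], pairs[, 2L])))
  if (!is.null(county_ids)) {
    lab <- function(code) names(county_ids)[match(code, county_ids)]
    tibble::tibble(a = lab(pairs[, 1L]), b = lab(pairs[, 2L]))
  } else {
    tibble::tibble(a = as.character(pairs[, 1L]), b = as.character(pairs[, 2L]))
  }
}

#' Identify production centers
#'
#' Counties whose share of mean national acreage reaches the threshold are
#' eligible; eligible counties that abut one another (directly or through a
#' chain of abutting eligible counties) merge into a single production
#' center. Centers are returned sorted by descending combined share.
#'
#' @param shares output of [mean_national_share()] (columns `county_id`,
#'   `share`; `state` carried through if present).
#' @param adjacency data frame of abutting county pairs (columns `a`, `b`),
#'   e.g. from [county_adjacency()]; may be empty.
#' @param threshold eligibility threshold on the share (default 0.10).
#' @return Tibble with one row per center: `center_id`, `county_ids` (list
#'   column), `share` (combined), `n_counties`. Zero rows when no county is
#'   eligible.
#' @export
identify_centers <- function(shares, adjacency = NULL, threshold = 0.10) {
  stopifnot(all(c("county_id", "share") %in% names(shares)))
  elig <- shares[shares$share >= threshold, ]
  if (nrow(elig) == 0L) {
    return(tibble::tibble(center_id = character(0), county_ids = list(),
                          share = numeric(0), n_counties = integer(0)))
  }
  ids <- as.character(elig$county_id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(adjacency) && nrow(adjacency) > 0L) {
    keep <- adjacency$a %in% ids & adjacency$b %in% ids
    adj <- adjacency[keep, , drop = FALSE]
    if (nrow(adj) > 0L) {
      g <- igraph::add_edges(g, t(cbind(match(adj$a, ids), match(adj$b, ids))))
    }
  }
  memb <- igraph::components(g)$membership
  groups <- split(ids, memb)
  share_of <- stats::setNames(elig$share, ids)
  out <- tibble::tibble(
    county_ids = unname(groups),
    share = unname(vapply(groups, function(cc) sum(share_of[cc]), numeric(1))),
    n_counties = lengths(groups)
  )
  out <- out[order(-out$share, vapply(out$county_ids, min, character(1))), ]
  out$center_id <- vapply(out$county_ids,
                          function(cc) paste(sort(cc), collapse = "+"),
                          character(1))
  out[, c("center_id", "county_ids", "share", "n_counties")]
}

#' Mask of a production center
#'
#' Union of the member counties' footprints on the common grid.
#'
#' @param county_ids character vector of member county ids.
#' @param county_raster categorical `grid_raster` of county codes.
#' @param county_codes named vector mapping county_id -> raster code; if
#'   `NULL` the ids themselves are taken as codes.
#' @return A boolean `grid_raster`.
#' @export
center_mask <- function(county_ids, county_raster, county_codes = NULL) {
  stopifnot(is_grid_raster(county_raster))
  codes <- if (is.null(county_codes)) {
    suppressWarnings(as.numeric(county_ids))
  } else {
    unname(county_codes[county_ids])
  }
  if (anyNA(codes)) stop("unknown county id(s)", call. = FALSE)
  v <- county_raster$values
  as_mask(!is.na(v) & matrix(v %in% codes, nrow(v), ncol(v)),
          template = county_raster)
}

#' Expand a production center into a buffer scenario region
#'
#' Dilates the center footprint by `buffer_km` from all sides (Euclidean,
#' maintaining the shape). The canonical scenario set is 0, 5, 10, 15 and
#' 20 km; other distances work but draw a warning. Buffers are not clipped at
#' administrative borders unless a `clip` mask is supplied.
#'
#' @param mask the center's boolean `grid_raster`.
#' @param buffer_km non-negative buffer distance in kilometers.
#' @param sq_cell_dist optional precomputed squared cell-distance matrix (see
#'   [dilate_mask()]); pass it when expanding one center at several
#'   distances.
#' @param clip optional boolean `grid_raster`; the region is intersected with
#'   it after dilation.
#' @return A boolean `grid_raster`, the scenario region.
#' @export
expand_center <- function(mask, buffer_km, sq_cell_dist = NULL, clip = NULL) {
  if (!is.numeric(buffer_km) || length(buffer_km) != 1L || is.na(buffer_km) ||
      buffer_km < 0) {
    stop("`buffer_km` must be a single non-negative number", call. = FALSE)
  }
  if (!buffer_km %in% c(0, 5, 10, 15, 20)) {
    warning("buffer_km outside the canonical scenario set {0, 5, 10, 15, 20}")
  }
  region <- dilate_mask(mask, buffer_km * 1000, sq_cell_dist = sq_cell_dist)
  if (!is.null(clip)) {
    .stop_misaligned(region, clip)
    region <- as_mask(region$values & clip$values, template = region)
  }
  region
}
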