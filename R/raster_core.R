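#' Planar grid raster
#'
#' The common container for every layer in an analysis: a 2-D matrix of values
#' on a square-celled planar grid in projected meters. Row 1 is the northern
#' (top) edge; `origin_xy` is the outer corner of cell `[1, 1]` (the upper-left
#' corner of the grid). Missing measurements are stored as `NA`; the `nodata`
#' field only records the sentinel used when the raster is written to or read
#' from disk.
#'
#' All layers combined in one analysis must share shape, cell size and origin
#' (see [grids_aligned()]); reprojection and resampling are an I/O concern,
#' not handled here.
#'
#' @param values numeric, integer or logical matrix. For `kind = "boolean"` a
#'   logical matrix; `NA` is coerced to `FALSE` (a cell with no data cannot be
#'   asserted true).
#' @param cell_size_m positive cell side length in meters (cells are square).
#' @param origin_xy numeric length-2, planar coordinates (m) of the upper-left
#'   outer corner of the grid.
#' @param nodata sentinel value used on disk for `NA`, or `NULL`.
#' @param kind one of `"continuous"`, `"categorical"`, `"boolean"`.
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(runif(25), 5, 5), cell_size_m = 30)
#' cell_area_ha(r)
#' @export
grid_raster <- function(values, cell_size_m, origin_xy = c(0, 0), nodata = NULL,
                        kind = c("continuous", "categorical", "boolean")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L ||
      !is.finite(cell_size_m) || cell_size_m <= 0) {
    stop("invalid raster: `cell_size_m` must be a single positive number",
         call. = FALSE)
  }
  if (length(origin_xy) != 2L || !is.numeric(origin_xy)) {
    stop("`origin_xy` must be two planar coordinates in meters", call. = FALSE)
  }
  if (kind == "boolean") {
    storage.mode(values) <- "logical"
    values[is.na(values)] <- FALSE
  } else {
    storage.mode(values) <- "double"
  }
  structure(
    list(values = values, cell_size_m = as.numeric(cell_size_m),
         origin_xy = as.numeric(origin_xy), nodata = nodata, kind = kind),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster [%s]> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$kind, nrow(x$values), ncol(x$values), x$cell_size_m,
              x$origin_xy[1], x$origin_xy[2]))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Test for the grid_raster class
#' @param x object to test.
#' @export
is_grid_raster <- function(x) inherits(x, "grid_raster")

#' Build a boolean mask on a grid
#'
#' A mask is simply a boolean [grid_raster()]; `NA` cells become `FALSE`.
#'
#' @param values logical (or coercible) matrix, or a `grid_raster` whose
#'   values are reinterpreted as logical.
#' @param template optional `grid_raster` supplying cell size and origin.
#' @inheritParams grid_raster
#' @export
as_mask <- function(values, cell_size_m = NULL, origin_xy = NULL,
                    template = NULL) {
  if (is_grid_raster(values)) {
    template <- values
    values <- values$values != 0 & !is.na(values$values)
  }
  if (!is.null(template)) {
    if (is.null(cell_size_m)) cell_size_m <- template$cell_size_m
    if (is.null(origin_xy)) origin_xy <- template$origin_xy
  }
  if (is.null(origin_xy)) origin_xy <- c(0, 0)
  grid_raster(values, cell_size_m, origin_xy, nodata = NULL, kind = "boolean")
}

#' Check that rasters share one grid
#'
#' Layers combined cell-by-cell must agree in shape, cell size and origin;
#' anything else is a configuration error upstream, never silently resampled.
#'
#' @param ... two or more `grid_raster` objects.
#' @param tol tolerance (m) on cell size and origin comparison.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(..., tol = 1e-6) {
  rs <- list(...)
  stopifnot(length(rs) >= 2L)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!identical(dim(r$values), dim(ref$values))) return(FALSE)
    if (abs(r$cell_size_m - ref$cell_size_m) > tol) return(FALSE)
    if (any(abs(r$origin_xy - ref$origin_xy) > tol)) return(FALSE)
  }
  TRUE
}

.stop_misaligned <- function(...) {
  if (!grids_aligned(...)) {
    stop("alignment error: all layers must share shape, cell size and origin",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Area of one grid cell in hectares
#'
#' @param raster a `grid_raster`.
#' @return `cell_size_m^2 / 1e4`, e.g. 0.09 ha for 30 m cells.
#' @export
cell_area_ha <- function(raster) {
  stopifnot(is_grid_raster(raster))
  raster$cell_size_m^2 / 1e4
}

#' Area covered by a mask in hectares
#'
#' Exact cell counting (true cells times cell area); no sub-cell
#' interpolation.
#'
#' @param mask a boolean `grid_raster`.
#' @export
mask_area_ha <- function(mask) {
  stopifnot(is_grid_raster(mask), mask$kind == "boolean")
  sum(mask$values) * cell_area_ha(mask)
}

# Squared distance (cell units) from every cell to the nearest TRUE cell,
# measured center to center. Exact two-pass algorithm: per-column 1-D
# distances, then the lower envelope of parabolas along each row
# (Felzenszwalb & Huttenlocher). Cells in columns/rows with no reachable
# TRUE cell get Inf.
.sq_dist_to_true <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  idx <- seq_len(nr)
  d <- matrix(Inf, nr, nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    if (!any(col)) next
    lastT <- cummax(ifelse(col, idx, -Inf))
    nxtT <- -rev(cummax(rev(ifelse(col, -idx, -Inf))))
    d[, j] <- pmin(idx - lastT, nxtT - idx)^2
  }
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) out[i, ] <- .lower_envelope_sq(d[i, ])
  out
}

# 1-D squared distance transform with per-position additive costs f
# (Inf = no source there). Returns min_p (q - p)^2 + f[p] for every q.
.lower_envelope_sq <- function(f) {
  n <- length(f)
  src <- which(is.finite(f))
  if (length(src) == 0L) return(rep(Inf, n))
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- src[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(src) > 1L) {
    for (q in src[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
        if (s > z[k]) break
        k <- k - 1L
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

#' Euclidean distance to the nearest true cell
#'
#' Exact center-to-center Euclidean distance, in meters, from every cell to
#' the nearest true cell of `mask`. True cells get 0; if the mask is empty
#' every cell gets `Inf`.
#'
#' @param mask a boolean `grid_raster`.
#' @return A continuous `grid_raster` of distances (m).
#' @export
distance_map_m <- function(mask) {
  stopifnot(is_grid_raster(mask), mask$kind == "boolean")
  d <- sqrt(.sq_dist_to_true(mask$values)) * mask$cell_size_m
  grid_raster(d, mask$cell_size_m, mask$origin_xy, kind = "continuous")
}

#' Dilate a mask by a Euclidean distance
#'
#' The output is true at every cell whose center lies within `distance_m`
#' (Euclidean, center to center) of the center of some true input cell, so the
#' output always contains the input and `distance_m = 0` is the identity.
#' This is the buffer-expansion primitive: enlarging a footprint by a fixed
#' distance from all sides while maintaining its shape.
#'
#' @param mask a boolean `grid_raster`.
#' @param distance_m non-negative buffer distance in meters.
#' @param sq_cell_dist optional precomputed squared cell-distance matrix from
#'   an earlier call (an optimization when thresholding one mask at several
#'   distances); leave `NULL` normally.
#' @return A boolean `grid_raster`.
#' @examples
#' m <- as_mask(matrix(FALSE, 7, 7), cell_size_m = 30)
#' m$values[4, 4] <- TRUE
#' sum(dilate_mask(m, 60)$values)  # discrete disk of radius 2 cells: 13
#' @export
dilate_mask <- function(mask, distance_m, sq_cell_dist = NULL) {
  stopifnot(is_grid_raster(mask), mask$kind == "boolean")
  if (!is.numeric(distance_m) || length(distance_m) != 1L ||
      is.na(distance_m) || distance_m < 0) {
    stop("`distance_m` must be a single non-negative number", call. = FALSE)
  }
  if (distance_m == 0) return(mask)
  if (is.null(sq_cell_dist)) sq_cell_dist <- .sq_dist_to_true(mask$values)
  r2 <- (distance_m / mask$cell_size_m)^2
  # squared cell distances are integers; the epsilon only absorbs FP error in
  # r2 at exact ties (e.g. distance an integer multiple of the cell size)
  out <- sq_cell_dist <= r2 + 1e-9
  as_mask(out, template = mask)
}

#' Label connected components of a mask
#'
#' Partitions the true cells into connected clusters. Under `"edge"`
#' connectivity (rook) two cells are neighbors when they share an edge; under
#' `"edge+corner"` (queen) corner contact also connects. Labels are assigned
#' 1, 2, ... in row-major scan order of each component's first cell, so
#' labeling is deterministic.
#'
#' @param mask a boolean `grid_raster`.
#' @param connectivity `"edge"` or `"edge+corner"`.
#' @return A categorical `grid_raster` of integer labels; cells outside the
#'   mask are 0. The number of components is in attribute `"n_components"`.
#' @export
connected_components <- function(mask, connectivity = c("edge", "edge+corner")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is_grid_raster(mask), mask$kind == "boolean")
  m <- mask$values
  nr <- nrow(m); nc <- ncol(m)
  true_idx <- which(m)
  lab <- matrix(0, nr, nc)
  if (length(true_idx) == 0L) {
    out <- grid_raster(lab, mask$cell_size_m, mask$origin_xy, kind = "categorical")
    attr(out, "n_components") <- 0L
    return(out)
  }
  # linear-index pairs of adjacent true cells (column-major indices)
  edges <- list()
  if (nr > 1L) {
    a <- which(m[-nr, , drop = FALSE] & m[-1L, , drop = FALSE])
    p <- a + (a - 1L) %/% (nr - 1L)  # re-index into full matrix
    edges[["v"]] <- cbind(p, p + 1L)
  }
  if (nc > 1L) {
    a <- which(m[, -nc, drop = FALSE] & m[, -1L, drop = FALSE])
    edges[["h"]] <- cbind(a, a + nr)
  }
  if (connectivity == "edge+corner" && nr > 1L && nc > 1L) {
    a <- which(m[-nr, -nc, drop = FALSE] & m[-1L, -1L, drop = FALSE])
    p <- a + (a - 1L) %/% (nr - 1L)
    edges[["d1"]] <- cbind(p, p + nr + 1L)
    a <- which(m[-1L, -nc, drop = FALSE] & m[-nr, -1L, drop = FALSE])
    p <- a + (a - 1L) %/% (nr - 1L) + 1L
    edges[["d2"]] <- cbind(p, p + nr - 1L)
  }
  el <- do.call(rbind, edges)
  vid <- match(seq_len(nr * nc), true_idx)  # linear index -> vertex id
  g <- igraph::make_empty_graph(n = length(true_idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) {
    g <- igraph::add_edges(g, t(cbind(vid[el[, 1L]], vid[el[, 2L]])))
  }
  memb <- igraph::components(g)$membership
  # relabel components by row-major order of their first cell
  rows <- ((true_idx - 1L) %% nr) + 1L
  cols <- ((true_idx - 1L) %/% nr) + 1L
  scan_key <- (rows - 1L) * nc + cols
  first_key <- tapply(scan_key, memb, min)
  new_of_old <- rank(first_key)  # 1..K by scan order
  lab[true_idx] <- new_of_old[as.character(memb)]
  out <- grid_raster(lab, mask$cell_size_m, mask$origin_xy, kind = "categorical")
  attr(out, "n_components") <- length(first_key)
  out
}

#' Zonal minimum and maximum
#'
#' Extrema of a continuous raster over the cells of a zone mask, ignoring
#' `NA` cells. Used to derive climate bounds from a reference zone.
#'
#' @param raster a continuous `grid_raster`.
#' @param zone a boolean `grid_raster` aligned with `raster`.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
zonal_min_max <- function(raster, zone) {
  stopifnot(is_grid_raster(raster), is_grid_raster(zone),
            zone$kind == "boolean")
  .stop_misaligned(raster, zone)
  vals <- raster$values[zone$values]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("empty-zone error: zone has no cells with data", call. = FALSE)
  }
  c(min = min(vals), max = max(vals))
}

# ---- layer bundles ---------------------------------------------------------

#' Monthly climate stack
#'
#' Twelve monthly precipitation (mm) and surface temperature (degrees C,
#' minimum and maximum) layers on one grid, the climate inputs of the
#' suitability overlay.
#'
#' @param precip,tmin,tmax lists of 12 continuous `grid_raster` layers
#'   (January..December).
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(precip, tmin, tmax) {
  for (lst in list(precip, tmin, tmax)) {
    if (length(lst) != 12L || !all(vapply(lst, is_grid_raster, logical(1)))) {
      stop("each climate variable needs exactly 12 monthly grid_raster layers",
           call. = FALSE)
    }
  }
  do.call(.stop_misaligned, c(precip, tmin, tmax))
  for (m in 1:12) {
    bad <- tmin[[m]]$values > tmax[[m]]$values
    if (any(bad, na.rm = TRUE)) {
      stop(sprintf("tmin exceeds tmax in month %d", m), call. = FALSE)
    }
  }
  structure(list(precip = precip, tmin = tmin, tmax = tmax),
            class = "climate_stack")
}

#' Soil layers
#'
#' Soil depth (cm, continuous) and texture class (categorical codes; the
#' 12-class particle-size triangle coding by default) on one grid.
#'
#' @param depth continuous `grid_raster`, depth in cm (non-negative).
#' @param texture categorical `grid_raster` of texture-class codes.
#' @export
soil_layers <- function(depth, texture) {
  stopifnot(is_grid_raster(depth), is_grid_raster(texture))
  .stop_misaligned(depth, texture)
  if (any(depth$values < 0, na.rm = TRUE)) {
    stop("soil depth must be non-negative", call. = FALSE)
  }
  structure(list(depth = depth, texture = texture), class = "soil_layers")
}

#' Land-use layer
#'
#' A categorical land-cover raster plus its code table. The code table must
#' name at least a fallow-cropland class; per-crop cultivation classes let
#' the overlay locate where a crop is currently grown.
#'
#' @param raster categorical `grid_raster` of land-use codes.
#' @param code_table named integer vector mapping class name -> code; must
#'   include `"fallow_cropland"`.
#' @export
landuse_layer <- function(raster, code_table) {
  stopifnot(is_grid_raster(raster))
  if (is.null(names(code_table)) || !"fallow_cropland" %in% names(code_table)) {
    stop("code_table must be a named vector including 'fallow_cropland'",
         call. = FALSE)
  }
  codes <- unique(raster$values[!is.na(raster$values)])
  if (!all(codes %in% code_table)) {
    stop("land-use raster contains codes absent from the code table",
         call. = FALSE)
  }
  structure(list(raster = raster, code_table = code_table),
            class = "landuse_layer")
}

# ---- ESRI ASCII grid I/O ---------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Plain-text raster interchange. Header keys (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) are case-insensitive; the first data row
#' is the northern edge. Cells equal to the nodata sentinel become `NA`
#' (`FALSE` for boolean rasters).
#'
#' @param path file path.
#' @param kind value kind of the resulting raster.
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical", "boolean")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k,
                                call. = FALSE)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid body does not match declared dimensions", call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  grid_raster(m, hdr$cellsize, origin, nodata = hdr$nodata_value, kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' @param raster a `grid_raster`; `NA` cells are written as the nodata
#'   sentinel (the raster's own, or -9999; 255 for boolean masks).
#' @param path output file path.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(is_grid_raster(raster))
  nodata <- raster$nodata
  if (is.null(nodata)) nodata <- if (raster$kind == "boolean") 255 else -9999
  m <- raster$values
  storage.mode(m) <- "double"
  m[is.na(m)] <- nodata
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", raster$origin_xy[1]),
    sprintf("yllcorner %.10g", raster$origin_xy[2] - nr * raster$cell_size_m),
    sprintf("cellsize %.10g", raster$cell_size_m),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
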