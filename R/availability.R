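#' Farm-weight production from suitable area
#'
#' Applies a state-level yield to a suitable land area. Linear in both
#' arguments; per-center products for a multi-center crop sum to the crop
#' total.
#'
#' @param area_ha suitable land area (ha, non-negative).
#' @param yield_kg_ha farm-weight yield (kg/ha, positive).
#' @return Farm-weight production (kg/yr).
#' @export
production_from_area <- function(area_ha, yield_kg_ha) {
  if (any(area_ha < 0)) stop("area must be non-negative", call. = FALSE)
  if (any(yield_kg_ha <= 0)) stop("yield must be positive", call. = FALSE)
  area_ha * yield_kg_ha
}

#' Loss chain for one crop
#'
#' Supply-chain loss accounting collapsed into three multiplicative stages
#' (farm, retail, consumer) plus one mass-to-volume factor converting
#' consumer-weight kilograms into cup-equivalents. The structure mirrors
#' loss-adjusted food availability accounting; the factors are inputs.
#'
#' @param crop_id crop identifier.
#' @param farm_loss,retail_loss,consumer_loss loss fractions, each in
#'   `[0, 1)`.
#' @param cups_per_kg cup-equivalents per kg of consumer-weight food
#'   (positive).
#' @return An object of class `loss_chain`.
#' @export
loss_chain <- function(crop_id, farm_loss, retail_loss, consumer_loss,
                       cups_per_kg) {
  fr <- c(farm = farm_loss, retail = retail_loss, consumer = consumer_loss)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr >= 1)) {
    stop("configuration error: loss fractions must lie in [0, 1)",
         call. = FALSE)
  }
  if (!is.finite(cups_per_kg) || cups_per_kg <= 0) {
    stop("cups_per_kg must be positive", call. = FALSE)
  }
  structure(list(crop_id = crop_id, farm_loss = farm_loss,
                 retail_loss = retail_loss, consumer_loss = consumer_loss,
                 cups_per_kg = cups_per_kg),
            class = "loss_chain")
}

#' Adjust farm-weight mass for supply-chain losses
#'
#' `mass * (1 - farm) * (1 - retail) * (1 - consumer)`; the order of the
#' stages is immaterial.
#'
#' @param mass_kg farm-weight mass (kg/yr).
#' @param chain a [loss_chain()].
#' @return Consumer-available mass (kg/yr).
#' @export
loss_adjust <- function(mass_kg, chain) {
  stopifnot(inherits(chain, "loss_chain"))
  mass_kg * (1 - chain$farm_loss) * (1 - chain$retail_loss) *
    (1 - chain$consumer_loss)
}

#' Per-capita daily cup-equivalents
#'
#' Converts annual consumer-available mass into cup-equivalents per person
#' per day, assuming availability is spread evenly over the population and a
#' 365-day year.
#'
#' @param consumer_kg_per_year consumer-available mass (kg/yr).
#' @param chain a [loss_chain()] supplying `cups_per_kg`.
#' @param population total population (positive).
#' @return Cup-equivalents per person per day.
#' @export
per_capita_cups <- function(consumer_kg_per_year, chain, population) {
  stopifnot(inherits(chain, "loss_chain"))
  if (!is.finite(population) || population <= 0) {
    stop("population must be positive", call. = FALSE)
  }
  consumer_kg_per_year * chain$cups_per_kg / population / 365
}

#' Full area-to-availability chain for one crop
#'
#' Convenience composition: area -> farm-weight production -> loss-adjusted
#' mass -> per-capita daily cup-equivalents.
#'
#' @inheritParams production_from_area
#' @inheritParams per_capita_cups
#' @export
area_to_cups <- function(area_ha, yield_kg_ha, chain, population) {
  per_capita_cups(loss_adjust(production_from_area(area_ha, yield_kg_ha),
                              chain),
                  chain, population)
}

#' Scenario report table
#'
#' Pivots per-crop, per-buffer values (cumulative suitable area or
#' availability) into the report layout: one row per crop, one column per
#' buffer distance, plus a Total row that is the exact column-wise sum of
#' the crop rows. Values stay at full precision; rounding is presentation
#' only (see `digits`).
#'
#' @param results long data frame with columns `crop_id`, `buffer_km`,
#'   `value`; every crop must have a value for every buffer.
#' @param digits optional number of decimals for presentation rounding;
#'   `NULL` (default) leaves full precision. The Total row is summed before
#'   rounding.
#' @return Tibble with a `crop` column ("Total" first) and one `km_<d>`
#'   column per buffer.
#' @export
scenario_table <- function(results, digits = NULL) {
  stopifnot(all(c("crop_id", "buffer_km", "value") %in% names(results)))
  buffers <- sort(unique(results$buffer_km))
  crops <- unique(results$crop_id)
  full <- tidyr::expand_grid(crop_id = crops, buffer_km = buffers)
  merged <- dplyr::left_join(full, results, by = c("crop_id", "buffer_km"))
  if (anyNA(merged$value)) {
    miss <- merged[is.na(merged$value), ]
    stop("report error: missing value for ",
         paste(sprintf("%s @ %g km", miss$crop_id, miss$buffer_km),
               collapse = "; "),
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(merged, names_from = "buffer_km",
                             values_from = "value",
                             names_prefix = "km_")
  total <- dplyr::summarise(wide,
                            dplyr::across(dplyr::starts_with("km_"), sum))
  out <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(crop = "Total"), total),
    dplyr::rename(wide, crop = "crop_id")
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out,
                         dplyr::across(dplyr::starts_with("km_"),
                                       \(x) round(x, digits)))
  }
  out
}

#' Percent increase over a baseline
#'
#' @param added additional availability (same units as `baseline`).
#' @param baseline current availability (positive).
#' @return `added / baseline * 100`.
#' @examples
#' percent_increase(43.6e-3, 2.6)  # ~1.68, printing as 1.7 at one decimal
#' @export
percent_increase <- function(added, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline must be positive", call. = FALSE)
  }
  added / baseline * 100
}

#' Sensitivity of the Total row to omitting one crop
#'
#' Per scenario column, the percent of the Total contributed by one crop —
#' equivalently, the percent reduction in the Total if that crop were
#' omitted. Used to check how much an atypical crop (e.g. one grown indoors,
#' for which few geospatial conditions apply) drives the totals.
#'
#' @param table a [scenario_table()] output (crop rows plus a Total row).
#' @param crop_id the crop to omit.
#' @return Named numeric vector of percent reductions, one per `km_` column.
#' @export
omit_crop_sensitivity <- function(table, crop_id) {
  stopifnot("crop" %in% names(table))
  cols <- grep("^km_", names(table), value = TRUE)
  if (!crop_id %in% table$crop) {
    stop("unknown crop '", crop_id, "'", call. = FALSE)
  }
  crop_row <- as.numeric(table[table$crop == crop_id, cols])
  total_row <- as.numeric(table[table$crop == "Total", cols])
  stats::setNames(crop_row / total_row * 100, cols)
}

#' Published scenario tables
#'
#' Loads the report tables shipped with the package: per-crop cumulative
#' suitable land area (10^3 ha) and per-capita availability (10^-3
#' cup-equivalents per person per day) under the five production-center
#' expansion scenarios, the production-center roster, and headline
#' constants (the 2.6 cups/person/day baseline availability of all fruits
#' and vegetables). These are inputs for consistency checks and worked
#' examples, not outputs of this package.
#'
#' @return List with tibbles `centers`, `area_kha`, `cups_mcups` (columns
#'   `crop`, `current`, `km_0`, `km_5`, `km_10`, `km_15`, `km_20`; a crop
#'   with an unprinted current value carries `NA`) and the scalar
#'   `baseline_cups` (cups/person/day, all fruits and vegetables).
#' @export
published_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "fvcapacity",
                                  mustWork = TRUE)
  rd <- function(f) tibble::as_tibble(utils::read.csv(path(f),
                                                      check.names = FALSE))
  list(
    centers = rd("production_centers.csv"),
    area_kha = rd("scenario_area_kha.csv"),
    cups_mcups = rd("scenario_availability_mcups.csv"),
    baseline_cups = 2.6
  )
}
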