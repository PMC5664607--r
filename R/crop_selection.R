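#' Default daily reference intakes
#'
#' Reference daily amounts used to normalize per-serving nutrient contents
#' into percent-of-reference contributions. Defaults are the current FDA
#' Daily Values for the four nutrients of public health concern the screen
#' uses: fiber 28 g, calcium 1300 mg, magnesium 420 mg, potassium 4700 mg.
#' All values must be strictly positive; override any subset.
#'
#' @param fiber_g,calcium_mg,magnesium_mg,potassium_mg daily reference
#'   amounts in the units of the nutrient columns.
#' @return Named numeric vector of reference intakes.
#' @export
reference_intakes <- function(fiber_g = 28, calcium_mg = 1300,
                              magnesium_mg = 420, potassium_mg = 4700) {
  refs <- c(fiber_g = fiber_g, calcium_mg = calcium_mg,
            magnesium_mg = magnesium_mg, potassium_mg = potassium_mg)
  if (any(!is.finite(refs)) || any(refs <= 0)) {
    stop("reference intakes must all be strictly positive", call. = FALSE)
  }
  refs
}

#' Nutrient density score
#'
#' Scores each food by summing (default) or averaging its per-serving
#' percent-of-reference contributions over a configurable nutrient set.
#' With the default sum aggregator, a food supplying exactly the reference
#' amount of each of the four nutrients scores 400.
#'
#' @param foods data frame with one row per food and a numeric column per
#'   nutrient named in `names(refs)` (default columns `fiber_g`,
#'   `calcium_mg`, `magnesium_mg`, `potassium_mg`).
#' @param refs named positive vector of daily reference amounts, see
#'   [reference_intakes()]; its names choose the nutrient set.
#' @param aggregate `"sum"` (default) or `"mean"` of the percent
#'   contributions.
#' @return Numeric vector of scores, one per row of `foods`.
#' @examples
#' foods <- data.frame(fiber_g = 5, calcium_mg = 60,
#'                     magnesium_mg = 30, potassium_mg = 500)
#' nutrient_density_score(foods,
#'   refs = reference_intakes(25, 1000, 300, 3500))  # 50.29
#' @export
nutrient_density_score <- function(foods, refs = reference_intakes(),
                                   aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  missing_cols <- setdiff(names(refs), names(foods))
  if (length(missing_cols)) {
    stop("scoring error: missing nutrient column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  amounts <- as.matrix(foods[, names(refs), drop = FALSE])
  if (anyNA(amounts)) {
    bad <- which(rowSums(is.na(amounts)) > 0)
    stop("scoring error: missing nutrient value in row(s) ",
         paste(bad, collapse = ", "), " (no silent zero-fill)", call. = FALSE)
  }
  if (any(amounts < 0)) {
    stop("scoring error: nutrient amounts must be non-negative", call. = FALSE)
  }
  pct <- sweep(amounts, 2L, refs, "/") * 100
  if (aggregate == "sum") rowSums(pct) else rowMeans(pct)
}

#' Ordinary least-squares trend slope of an annual series
#'
#' Slope of value regressed on year, in value units per year. Used to screen
#' foods for rising consumption and production.
#'
#' @param years strictly increasing integer years (at least 2 distinct).
#' @param values non-negative amounts, same length as `years`.
#' @return The OLS slope (a single number).
#' @export
trend_slope <- function(years, values) {
  if (length(years) != length(values)) {
    stop("`years` and `values` must have equal length", call. = FALSE)
  }
  if (length(unique(years)) < 2L) {
    stop("degenerate-series error: need at least 2 distinct years",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(values ~ years))[["years"]])
}

#' Select nutrient-dense crops with rising consumption and production
#'
#' A food is selected iff (a) its nutrient density score reaches the cutoff
#' and (b) the OLS trend slope is strictly positive for both its consumption
#' and its production series restricted to the most recent `window_years`
#' calendar years present in each series.
#'
#' @param foods data frame with columns `food_id`, `name`,
#'   `myplate_subgroup` and the nutrient columns used by
#'   [nutrient_density_score()].
#' @param series long-format data frame of annual series with columns
#'   `food_id`, `series_type` (`"consumption"` or `"production"`), `year`,
#'   `value`. Every scored food needs both series.
#' @param refs reference intakes (see [reference_intakes()]).
#' @param window_years width of the recency window (default 5).
#' @param score_cutoff absolute score cutoff; if `NULL` (default) the cutoff
#'   is the `score_quantile` quantile of the candidate scores.
#' @param score_quantile quantile defining "nutrient dense" when
#'   `score_cutoff` is `NULL`; default 0.9 (top decile).
#' @param aggregate score aggregator passed through.
#' @return Tibble of selected foods with their MyPlate subgroup tag, score,
#'   and both window slopes, ordered by descending score.
#' @export
select_crops <- function(foods, series, refs = reference_intakes(),
                         window_years = 5L, score_cutoff = NULL,
                         score_quantile = 0.9,
                         aggregate = c("sum", "mean")) {
  stopifnot(window_years >= 2L)
  scores <- nutrient_density_score(foods, refs, aggregate)
  if (is.null(score_cutoff)) {
    score_cutoff <- stats::quantile(scores, score_quantile, names = FALSE)
  }
  slope_in_window <- function(fid, type) {
    s <- series[series$food_id == fid & series$series_type == type, ]
    if (nrow(s) == 0L) {
      stop("selection error: no ", type, " series for food '", fid, "'",
           call. = FALSE)
    }
    yrs <- sort(unique(s$year))
    keep <- yrs[yrs > max(yrs) - window_years]
    s <- s[s$year %in% keep, ]
    trend_slope(s$year, s$value)
  }
  out <- tibble::tibble(
    food_id = foods$food_id,
    name = foods$name,
    myplate_subgroup = foods$myplate_subgroup,
    score = scores
  )
  out$consumption_slope <- vapply(out$food_id, slope_in_window,
                                  numeric(1), type = "consumption")
  out$production_slope <- vapply(out$food_id, slope_in_window,
                                 numeric(1), type = "production")
  out <- out[out$score >= score_cutoff &
               out$consumption_slope > 0 & out$production_slope > 0, ]
  out[order(-out$score), ]
}
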