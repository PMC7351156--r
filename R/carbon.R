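# Carbon-sequestration scenario engine: adoption-trend fitting on
# historical crop-area series and the 12-scenario projection grid.
#
# Sequestration accounting is linear: new adoption area (Mha) times a
# constant per-hectare rate (MgC/ha/yr) times the C-to-CO2 mass ratio
# 44/12 gives MMT CO2-eq/yr. Woody perennials sequester far more than
# vines and herbs, so the woody share of new adoption is a scenario axis.

# Validate an area series tibble (year, area).
check_series <- function(series, min_points = 3) {
  series <- tibble::as_tibble(series)
  missing_cols <- setdiff(c("year", "area"), names(series))
  if (length(missing_cols) > 0) {
    abort(sprintf("`series` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pvcrops_schema_error")
  }
  if (nrow(series) < min_points) {
    abort(sprintf("Need at least %d points to fit a trend (have %d).",
                  min_points, nrow(series)),
          class = "pvcrops_insufficient_data_error")
  }
  if (any(diff(series$year) <= 0)) {
    abort("Years must be strictly increasing.",
          class = "pvcrops_validation_error")
  }
  if (any(series$area < 0)) {
    abort("Areas must be non-negative.", class = "pvcrops_validation_error")
  }
  series
}

new_trend <- function(curve, params, project, series) {
  structure(list(curve = curve, params = params, project = project,
                 series = series),
            class = "pv_trend")
}

#' @export
print.pv_trend <- function(x, ...) {
  cat(sprintf("<%s adoption trend: %s>\n", x$curve,
              paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a linear adoption trend
#'
#' Ordinary least squares of area on calendar year. Projections clamp
#' negative fitted areas to zero.
#'
#' @param series tibble with columns `year` (strictly increasing) and
#'   `area` (Mha, non-negative); at least 3 points.
#' @return a `pv_trend` object with elements `curve`, `params`
#'   (`intercept`, `slope`), and `project(year)`.
#' @export
fit_linear_trend <- function(series) {
  series <- check_series(series)
  fit <- lm(area ~ year, data = series)
  b <- coef(fit)
  new_trend(
    "linear",
    c(intercept = unname(b[1]), slope = unname(b[2])),
    function(year) pmax(0, unname(b[1] + b[2] * year)),
    series)
}

#' Fit an exponential adoption trend
#'
#' Log-linear least squares: `log(area) ~ year`, so the slope is the
#' per-year continuous growth rate. All areas must be positive.
#'
#' @inheritParams fit_linear_trend
#' @return a `pv_trend` object with `params` (`base` at year 0 on the log
#'   scale's intercept, `rate`) and `project(year)`.
#' @export
fit_exponential_trend <- function(series) {
  series <- check_series(series)
  if (any(series$area <= 0)) {
    abort("Exponential fitting requires strictly positive areas.",
          class = "pvcrops_domain_error")
  }
  fit <- lm(log(area) ~ year, data = series)
  b <- coef(fit)
  new_trend(
    "exponential",
    c(log_base = unname(b[1]), rate = unname(b[2])),
    function(year) pmax(0, exp(unname(b[1] + b[2] * year))),
    series)
}

#' New adoption projected over a horizon
#'
#' The projected increase in area between two years under a fitted trend,
#' floored at zero.
#'
#' @param trend a `pv_trend` from [fit_linear_trend()] or
#'   [fit_exponential_trend()].
#' @param from,to horizon years (defaults 2020 and 2050).
#' @return new adoption in Mha.
#' @export
new_adoption <- function(trend, from = 2020, to = 2050) {
  stopifnot(inherits(trend, "pv_trend"))
  max(0, trend$project(to) - trend$project(from))
}

#' Rescale new adoption to a different world vegetable area
#'
#' Adoption is assumed proportional to total vegetable cropland, so the
#' base projection scales by the ratio of target to base world area (e.g.
#' a tripling of world vegetable area to meet nutritional needs).
#'
#' @param base_new_adoption new adoption at the base world area (Mha).
#' @param base_world_area,target_world_area world vegetable areas (Mha);
#'   `base_world_area > 0`.
#' @return scaled new adoption (Mha).
#' @export
#' @examples
#' scale_for_world_area(8.8, 58.2, 174.5)  # 26.4
scale_for_world_area <- function(base_new_adoption, base_world_area,
                                 target_world_area) {
  check_scalar(base_new_adoption, "base_new_adoption")
  check_scalar(base_world_area, "base_world_area")
  check_scalar(target_world_area, "target_world_area")
  if (base_world_area <= 0) {
    abort("`base_world_area` must be positive.",
          class = "pvcrops_domain_error")
  }
  base_new_adoption * target_world_area / base_world_area
}

#' Split new adoption between woody and non-woody PVs
#'
#' @param total_new total new adoption (Mha, `>= 0`).
#' @param woody_fraction fraction of new adoption that is woody, in
#'   `[0, 1]`.
#' @return named numeric `c(woody, nonwoody)` summing exactly to
#'   `total_new`.
#' @export
allocate_adoption <- function(total_new, woody_fraction) {
  check_scalar(total_new, "total_new")
  check_scalar(woody_fraction, "woody_fraction")
  if (total_new < 0) {
    abort("`total_new` must be non-negative.",
          class = "pvcrops_domain_error")
  }
  if (woody_fraction < 0 || woody_fraction > 1) {
    abort("`woody_fraction` must lie in [0, 1].",
          class = "pvcrops_domain_error")
  }
  c(woody = total_new * woody_fraction,
    nonwoody = total_new * (1 - woody_fraction))
}

#' Annual CO2-equivalent sequestration of an area
#'
#' `area * rate * co2_per_c`: Mha times MgC/ha/yr gives MMT C/yr, and the
#' molar mass ratio CO2/C = 44/12 converts to MMT CO2-eq/yr.
#'
#' @param area area in Mha (`>= 0`).
#' @param rate sequestration rate in MgC/ha/yr (`>= 0`).
#' @param co2_per_c CO2-to-C mass conversion factor (default `44/12`).
#' @return sequestration in MMT CO2-eq/yr.
#' @export
#' @examples
#' sequestration(11.1, 0.43)  # ~17.5
sequestration <- function(area, rate, co2_per_c = 44 / 12) {
  if (any(area < 0) || any(rate < 0)) {
    abort("`area` and `rate` must be non-negative.",
          class = "pvcrops_domain_error")
  }
  area * rate * co2_per_c
}

#' Average a set of sequestration-rate entries
#'
#' Literature rates come as single values or ranges; ranges are resolved
#' per `policy` (midpoint, low end, or high end) before taking the
#' unweighted mean. The scenario engine accepts rate overrides directly
#' via [seq_rates()], so published category averages can be injected
#' as-is.
#'
#' @param entries list of numeric vectors, each of length 1 (a point rate)
#'   or 2 (a range, low then high), in MgC/ha/yr.
#' @param policy how to resolve ranges: `"midpoint"`, `"low"`, or
#'   `"high"`.
#' @return mean rate in MgC/ha/yr.
#' @export
#' @examples
#' average_rate(list(c(0.3, 0.8), 1, c(0.3, 0.5), c(0, 0.1)))  # 0.5
average_rate <- function(entries, policy = c("midpoint", "low", "high")) {
  policy <- match.arg(policy)
  if (!is.list(entries) || length(entries) == 0) {
    abort("`entries` must be a non-empty list.",
          class = "pvcrops_domain_error")
  }
  resolved <- vapply(entries, function(e) {
    if (!is.numeric(e) || !length(e) %in% 1:2 || any(e < 0)) {
      abort("Each entry must be a non-negative rate or (low, high) range.",
            class = "pvcrops_domain_error")
    }
    switch(policy,
           midpoint = mean(range(e)),
           low = min(e),
           high = max(e))
  }, numeric(1))
  mean(resolved)
}

#' Sequestration-rate configuration
#'
#' Category rates for the scenario engine. Defaults are the published
#' category averages: 3.71 MgC/ha/yr for woody perennials and 0.43 for
#' perennial vines and herbs.
#'
#' @param woody,herbaceous rates in MgC/ha/yr.
#' @param co2_per_c CO2/C mass factor.
#' @return named list.
#' @export
seq_rates <- function(woody = 3.71, herbaceous = 0.43,
                      co2_per_c = 44 / 12) {
  if (woody < 0 || herbaceous < 0 || co2_per_c <= 0) {
    abort("Rates must be non-negative and the CO2 factor positive.",
          class = "pvcrops_domain_error")
  }
  list(woody = woody, herbaceous = herbaceous, co2_per_c = co2_per_c)
}

#' Build the 12-scenario sequestration grid
#'
#' Crosses adoption curve (linear, exponential), world vegetable area
#' (current 58.2 Mha vs tripled 174.5 Mha) and woody share of new
#' adoption (25/50/75%) into 12 scenarios labelled `1a`–`4c`: scenario
#' families 1 (current area, linear), 2 (current, exponential), 3
#' (tripled, linear), 4 (tripled, exponential); letters a/b/c are the
#' woody fractions in increasing order. Tripled-area totals scale the
#' base-area totals by the world-area ratio.
#'
#' Woody and non-woody allocations are rounded to the grid's reporting
#' resolution (`round_area_digits` decimals, default 0.1 Mha) before
#' sequestration is computed, so the CO2 columns are consistent with the
#' printed areas.
#'
#' @param trends named list with elements `linear` and `exponential`, each
#'   a `pv_trend` fitted to the historical base-area series; ignored when
#'   `totals_override` is given.
#' @param totals_override optional named numeric of new-adoption totals in
#'   Mha for scenario families `"1"`–`"4"`, bypassing trend projection and
#'   world-area scaling.
#' @param rates a [seq_rates()] list.
#' @param woody_fractions woody shares (ascending; mapped to letters).
#' @param world_areas world vegetable areas in Mha, base first.
#' @param horizon projection horizon `c(from, to)` passed to
#'   [new_adoption()].
#' @param round_area_digits decimals at which allocations are fixed before
#'   computing CO2; `NULL` keeps full precision.
#' @return tibble with one row per scenario: `id`, `world_veg_area`,
#'   `curve`, `woody_fraction`, `woody_Mha`, `nonwoody_Mha`, `total_Mha`,
#'   `woody_co2`, `nonwoody_co2`, `total_co2`.
#' @export
build_scenario_grid <- function(trends = NULL, totals_override = NULL,
                                rates = seq_rates(),
                                woody_fractions = c(0.25, 0.5, 0.75),
                                world_areas = c(58.2, 174.5),
                                horizon = c(2020, 2050),
                                round_area_digits = 1) {
  if (length(world_areas) != 2 || length(woody_fractions) != 3) {
    abort("Need 2 world areas and 3 woody fractions.",
          class = "pvcrops_usage_error")
  }
  woody_fractions <- sort(woody_fractions)
  curves <- c("linear", "exponential")
  families <- tibble::tibble(
    family = as.character(1:4),
    world_veg_area = rep(world_areas, each = 2),
    curve = rep(curves, times = 2)
  )

  if (is.null(totals_override)) {
    if (is.null(trends) || !all(curves %in% names(trends))) {
      abort("Provide `trends` (linear and exponential) or `totals_override`.",
            class = "pvcrops_usage_error")
    }
    base_new <- vapply(trends[curves], new_adoption, numeric(1),
                       from = horizon[1], to = horizon[2])
    families$total_new <- vapply(seq_len(4), function(i) {
      scale_for_world_area(base_new[[families$curve[i]]], world_areas[1],
                           families$world_veg_area[i])
    }, numeric(1))
  } else {
    if (!all(families$family %in% names(totals_override))) {
      abort("`totals_override` must name totals for families 1-4.",
            class = "pvcrops_usage_error")
    }
    families$total_new <- unname(totals_override[families$family])
  }

  grid <- tidyr::crossing(families,
                          woody_fraction = woody_fractions) |>
    dplyr::arrange(.data$family, .data$woody_fraction) |>
    dplyr::mutate(
      id = paste0(.data$family,
                  letters[match(.data$woody_fraction, woody_fractions)]))

  alloc <- purrr::map2(grid$total_new, grid$woody_fraction,
                       allocate_adoption)
  grid$woody_Mha <- vapply(alloc, `[[`, numeric(1), "woody")
  grid$nonwoody_Mha <- vapply(alloc, `[[`, numeric(1), "nonwoody")
  if (!is.null(round_area_digits)) {
    grid$woody_Mha <- round_half_up(grid$woody_Mha, round_area_digits)
    grid$nonwoody_Mha <- round_half_up(grid$nonwoody_Mha,
                                       round_area_digits)
  }
  grid |>
    dplyr::mutate(
      woody_co2 = sequestration(.data$woody_Mha, rates$woody,
                                rates$co2_per_c),
      nonwoody_co2 = sequestration(.data$nonwoody_Mha, rates$herbaceous,
                                   rates$co2_per_c),
      total_co2 = .data$woody_co2 + .data$nonwoody_co2,
      total_Mha = .data$total_new) |>
    dplyr::select("id", "world_veg_area", "curve", "woody_fraction",
                  "woody_Mha", "nonwoody_Mha", "total_Mha",
                  "woody_co2", "nonwoody_co2", "total_co2")
}
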