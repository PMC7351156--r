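# Report renderers: deterministic CSV/JSON-ready tables mirroring the
# published layouts. Display rounding happens here and only here — one
# decimal for Mha and MMT CO2-eq, two decimals for nutrient bounds,
# integer or one-decimal percentages for breakdowns.

fmt_num <- function(x, digits) {
  ifelse(is.finite(x),
         formatC(round_half_up(x, digits), format = "f", digits = digits),
         NA_character_)
}

#' Render a module result as a display table
#'
#' Dispatches on `layout`:
#' * `"bounds"`: six class rows by one column per nutrient, each cell a
#'   2-decimal `lower-upper` interval (`x+` for the open top class, empty
#'   where a class is disabled).
#' * `"scenarios"`: the 12-scenario grid with areas and CO2 columns at
#'   one decimal.
#' * `"multinutrient"`: species scores with XH/VH/H class labels.
#' * `"topten"`: a ranked concentration list.
#' * `"breakdown"`: category counts with one-decimal percentages.
#'
#' @param result the matching module output: a `pv_bounds` set, a
#'   [build_scenario_grid()] tibble, a [classify_profiles()] tibble, a
#'   [top_n_species()] tibble, or a [breakdown()] tibble.
#' @param layout one of `"bounds"`, `"scenarios"`, `"multinutrient"`,
#'   `"topten"`, `"breakdown"`.
#' @param syndrome for `"multinutrient"`: which syndrome to score.
#' @return a tibble of display-formatted character/numeric columns with
#'   deterministic column order.
#' @export
render_table <- function(result, layout = c("bounds", "scenarios",
                                            "multinutrient", "topten",
                                            "breakdown"),
                         syndrome = "traditional") {
  layout <- match.arg(layout)
  switch(layout,
         bounds = render_bounds(result),
         scenarios = render_scenarios(result),
         multinutrient = render_multinutrient(result, syndrome),
         topten = render_topten(result),
         breakdown = render_breakdown(result))
}

render_bounds <- function(bounds_set) {
  if (!inherits(bounds_set, "pv_bounds")) {
    abort("`result` must be a pv_bounds set for the bounds layout.",
          class = "pvcrops_usage_error")
  }
  # Printed style: contiguous 2-decimal intervals, the upper edge of each
  # class one display unit (0.01) below the next class's lower edge.
  cell <- function(lo, hi) paste0(fmt_num(lo, 2), "-", fmt_num(hi, 2))
  cols <- lapply(seq_len(nrow(bounds_set)), function(i) {
    b <- bounds_set[i, ]
    unname(c(
      if (b$has_very_low) cell(0, b$ref_min - 0.01) else "",
      cell(if (b$has_very_low) b$ref_min else 0, b$t1 - 0.01),
      cell(b$t1, b$t2 - 0.01),
      cell(b$t2, b$ref_max),
      cell(b$ref_max + 0.01, b$vh_upper),
      paste0(fmt_num(b$vh_upper, 2), "+")))
  })
  out <- tibble::tibble(class = concentration_classes)
  for (i in seq_along(cols)) out[[bounds_set$nutrient[i]]] <- cols[[i]]
  out
}

render_scenarios <- function(grid) {
  needed <- c("id", "world_veg_area", "curve", "woody_fraction",
              "woody_Mha", "nonwoody_Mha", "total_Mha", "woody_co2",
              "nonwoody_co2", "total_co2")
  if (!all(needed %in% names(grid))) {
    abort("`result` must be a scenario grid for the scenarios layout.",
          class = "pvcrops_usage_error")
  }
  tibble::tibble(
    scenario = grid$id,
    world_veg_Mha = fmt_num(grid$world_veg_area, 1),
    adoption_rate = ifelse(grid$curve == "linear", "Linear",
                           "Exponential"),
    pct_woody = paste0(fmt_num(100 * grid$woody_fraction, 0), "%"),
    woody_Mha = fmt_num(grid$woody_Mha, 1),
    woody_MMT_co2 = fmt_num(grid$woody_co2, 1),
    nonwoody_Mha = fmt_num(grid$nonwoody_Mha, 1),
    nonwoody_MMT_co2 = fmt_num(grid$nonwoody_co2, 1),
    total_Mha = fmt_num(grid$total_Mha, 1),
    total_MMT_co2 = fmt_num(grid$total_co2, 1))
}

render_multinutrient <- function(classified, syndrome) {
  if (!all(c("species_name", "nutrient", "class") %in%
           names(classified))) {
    abort("`result` must be a classified profile table for the multinutrient layout.",
          class = "pvcrops_usage_error")
  }
  nuts <- syndrome_nutrients[[syndrome]]
  wide <- classified |>
    tibble::as_tibble() |>
    dplyr::filter(.data$nutrient %in% nuts) |>
    dplyr::mutate(label = unname(class_labels[as.character(.data$class)])) |>
    dplyr::select("species_name", "nutrient", "label") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "label")
  for (nut in setdiff(nuts, names(wide))) wide[[nut]] <- NA_character_
  scores <- score_species(classified, syndrome)
  wide |>
    dplyr::select(dplyr::all_of(c("species_name", nuts))) |>
    dplyr::left_join(scores[c("species_name", "points", "qualifies")],
                     by = "species_name") |>
    dplyr::arrange(.data$species_name)
}

render_topten <- function(ranked) {
  if (!all(c("rank", "species_name", "mean_value") %in% names(ranked))) {
    abort("`result` must be a top-n ranking for the topten layout.",
          class = "pvcrops_usage_error")
  }
  tibble::tibble(rank = ranked$rank, species_name = ranked$species_name,
                 concentration = fmt_num(ranked$mean_value, 2))
}

render_breakdown <- function(bd) {
  if (!all(c("category", "count", "percentage") %in% names(bd))) {
    abort("`result` must be a breakdown for the breakdown layout.",
          class = "pvcrops_usage_error")
  }
  tibble::tibble(category = bd$category, count = bd$count,
                 percentage = fmt_num(bd$percentage, 1))
}

#' Write a rendered report to disk
#'
#' @param x a tibble (typically from [render_table()]).
#' @param path output path.
#' @param format `"csv"` or `"json"` (records orientation).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(x, path, progress = FALSE, na = "")
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
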