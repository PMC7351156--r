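# Meta-analysis of per-species nutrient measurements and multi-nutrient
# deficiency-syndrome scoring.
#
# Measurements from multiple literature sources are pooled to unweighted
# per-species means on a fresh-weight 100 g basis (the international
# standard for vegetable nutrient reporting); dry-basis values are
# converted first. Species are then scored against two deficiency
# syndromes: "traditional" malnutrition (iron, zinc, vitamin A, folate;
# iodine is excluded as terrestrial plants carry none) and "industrial"
# diet deficiencies (fiber, calcium, magnesium and the antioxidant
# vitamins A, C, E).

#' Nutrients scored for each deficiency syndrome
#'
#' @format Named list with elements `traditional` and `industrial`, each a
#'   character vector of nutrient codes.
#' @export
syndrome_nutrients <- list(
  traditional = c("Fe", "Zn", "vitA", "folate"),
  industrial = c("fiber", "Ca", "Mg", "vitA", "vitC", "vitE")
)

# Points per class for syndrome scoring; classes not listed score 0.
syndrome_points <- c(extremely_high = 3, very_high = 2, high = 1)

#' Convert a dry-basis concentration to fresh basis
#'
#' A dry-weight concentration per 100 g scales to fresh weight by the dry
#' matter fraction: `fresh = dry * (1 - moisture_fraction)`.
#'
#' @param value_dry concentration per 100 g dry weight (`>= 0`).
#' @param moisture_fraction fresh-weight moisture content in `[0, 1)`.
#' @return concentration per 100 g fresh weight.
#' @export
#' @examples
#' dry_to_fresh(10, 0.9)  # 1.0
dry_to_fresh <- function(value_dry, moisture_fraction) {
  if (any(!is.finite(value_dry)) || any(value_dry < 0)) {
    abort("`value_dry` must be finite and non-negative.",
          class = "pvcrops_domain_error")
  }
  if (any(!is.finite(moisture_fraction)) || any(moisture_fraction < 0) ||
      any(moisture_fraction >= 1)) {
    abort("`moisture_fraction` must lie in [0, 1).",
          class = "pvcrops_domain_error")
  }
  value_dry * (1 - moisture_fraction)
}

# Normalise a measurements table: check schema, convert dry rows to fresh.
prepare_measurements <- function(measurements) {
  measurements <- tibble::as_tibble(measurements)
  needed <- c("species_name", "nutrient", "value", "basis")
  missing_cols <- setdiff(needed, names(measurements))
  if (length(missing_cols) > 0) {
    abort(sprintf("Measurements are missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pvcrops_schema_error")
  }
  if (!"part" %in% names(measurements)) measurements$part <- "combined"
  if (!"moisture_fraction" %in% names(measurements)) {
    measurements$moisture_fraction <- NA_real_
  }
  bad <- !measurements$basis %in% c("fresh", "dry")
  if (any(bad)) {
    abort(sprintf("Unknown basis %s at row %d.",
                  encodeString(measurements$basis[which(bad)[1]],
                               quote = "\""), which(bad)[1]),
          class = "pvcrops_validation_error")
  }
  dry <- measurements$basis == "dry"
  if (any(dry & !is.finite(measurements$moisture_fraction))) {
    abort("Dry-basis rows require a moisture_fraction.",
          class = "pvcrops_validation_error")
  }
  if (any(measurements$value < 0, na.rm = TRUE)) {
    abort("Measurement values must be non-negative.",
          class = "pvcrops_validation_error")
  }
  measurements$value_fresh <- measurements$value
  measurements$value_fresh[dry] <- dry_to_fresh(
    measurements$value[dry], measurements$moisture_fraction[dry])
  measurements
}

#' Aggregate one species' measurements into a mean profile
#'
#' Pools all measurements for a single species into unweighted arithmetic
#' means per nutrient on a fresh-weight basis, recording the number of
#' source values behind each mean.
#'
#' @param measurements tibble with columns `species_name`, `nutrient`,
#'   `value`, `basis` (`"fresh"` or `"dry"`), optional `part`,
#'   `moisture_fraction` (required for dry rows) and `source_id`; all rows
#'   must share one `species_name`.
#' @param part_scope label recorded for the pooled profile (default
#'   `"combined"`).
#' @return tibble with columns `species_name`, `part_scope`, `nutrient`,
#'   `mean_value`, `n_sources`; nutrients with no measurements are absent.
#' @export
aggregate_profile <- function(measurements, part_scope = "combined") {
  measurements <- prepare_measurements(measurements)
  if (length(unique(measurements$species_name)) > 1) {
    abort("`aggregate_profile()` expects a single species; use `aggregate_profiles()` for a table.",
          class = "pvcrops_usage_error")
  }
  measurements |>
    dplyr::group_by(.data$species_name, .data$nutrient) |>
    dplyr::summarise(mean_value = mean(.data$value_fresh),
                     n_sources = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(part_scope = part_scope, .after = "species_name")
}

#' Aggregate a measurements table into per-species profiles
#'
#' Two part-handling modes: `"per_part"` keeps one profile row per
#' (species, part, nutrient); `"species_max"` first averages within each
#' part and then takes, per nutrient, the maximum across a species' parts —
#' the species-level rating used for multi-nutrient scoring, so a species
#' whose best levels are split across parts (e.g. leaves and flowerbuds)
#' is credited with each part's best.
#'
#' @inheritParams aggregate_profile
#' @param mode `"per_part"` or `"species_max"`.
#' @return tibble with columns `species_name`, `part_scope`, `nutrient`,
#'   `mean_value`, `n_sources`.
#' @export
aggregate_profiles <- function(measurements,
                               mode = c("per_part", "species_max")) {
  mode <- match.arg(mode)
  measurements <- prepare_measurements(measurements)
  per_part <- measurements |>
    dplyr::group_by(.data$species_name, part_scope = .data$part,
                    .data$nutrient) |>
    dplyr::summarise(mean_value = mean(.data$value_fresh),
                     n_sources = dplyr::n(), .groups = "drop")
  if (mode == "per_part") {
    return(per_part)
  }
  per_part |>
    dplyr::group_by(.data$species_name, .data$nutrient) |>
    dplyr::summarise(
      part_scope = if (dplyr::n() == 1) .data$part_scope[1] else "combined",
      mean_value = max(.data$mean_value),
      n_sources = sum(.data$n_sources), .groups = "drop") |>
    dplyr::relocate("part_scope", .after = "species_name")
}

#' Classify a profile table against a bounds set
#'
#' @param profiles output of [aggregate_profiles()] (needs `nutrient` and
#'   `mean_value` columns).
#' @param bounds_set `pv_bounds` tibble from [derive_bounds_set()].
#' @return `profiles` with an added ordered-factor `class` column; profile
#'   rows for nutrients absent from `bounds_set` are dropped with a
#'   warning.
#' @export
classify_profiles <- function(profiles, bounds_set) {
  profiles <- tibble::as_tibble(profiles)
  unknown <- setdiff(unique(profiles$nutrient), bounds_set$nutrient)
  if (length(unknown) > 0) {
    warn(sprintf("Dropping profile rows with no bounds for: %s.",
                 paste(unknown, collapse = ", ")))
    profiles <- profiles[profiles$nutrient %in% bounds_set$nutrient, ]
  }
  profiles$class <- factor(NA_character_, levels = concentration_classes,
                           ordered = TRUE)
  for (nut in unique(profiles$nutrient)) {
    idx <- profiles$nutrient == nut
    b <- bounds_set[bounds_set$nutrient == nut, ]
    class(b) <- unique(c("pv_bounds", class(b)))
    profiles$class[idx] <- classify(profiles$mean_value[idx], b)
  }
  profiles
}

#' Score a species' nutrient classes against a deficiency syndrome
#'
#' Points accrue over the syndrome's nutrients: 3 for `extremely_high`,
#' 2 for `very_high`, 1 for `high`, 0 otherwise. Nutrients with missing
#' data contribute 0 (a species is scored on what is known, not
#' disqualified). A species qualifies as a multi-nutrient crop at 6 or
#' more points.
#'
#' @param classes named character (or factor) vector mapping nutrient code
#'   to concentration class; nutrients not named are treated as missing.
#' @param syndrome `"traditional"` or `"industrial"`.
#' @return list of class `pv_syndrome_score` with elements `syndrome`,
#'   `points`, `qualifies`, and `contributing` (named class vector over the
#'   syndrome nutrients, `NA` where missing).
#' @export
#' @examples
#' score_syndrome(c(Fe = "extremely_high", Zn = "very_high",
#'                  vitA = "very_high"), "traditional")  # 7 points
score_syndrome <- function(classes, syndrome = c("traditional",
                                                 "industrial")) {
  syndrome <- match.arg(syndrome)
  nuts <- syndrome_nutrients[[syndrome]]
  classes <- setNames(as.character(classes), names(classes))
  bad <- !is.na(classes) & !classes %in% concentration_classes
  if (any(bad)) {
    abort(sprintf("Unknown concentration class %s.",
                  encodeString(classes[bad][1], quote = "\"")),
          class = "pvcrops_usage_error")
  }
  contributing <- setNames(classes[nuts], nuts)
  pts <- syndrome_points[contributing]
  pts[is.na(pts)] <- 0
  points <- as.integer(sum(pts))
  structure(
    list(syndrome = syndrome, points = points, qualifies = points >= 6L,
         contributing = contributing),
    class = "pv_syndrome_score")
}

#' @export
print.pv_syndrome_score <- function(x, ...) {
  cat(sprintf("<%s syndrome score: %d point%s, %squalifying>\n",
              x$syndrome, x$points, if (x$points == 1) "" else "s",
              if (x$qualifies) "" else "non-"))
  shown <- x$contributing[!is.na(x$contributing)]
  if (length(shown) > 0) {
    cat(paste(sprintf("  %s: %s", names(shown),
                      class_labels[shown]), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Score every species in a classified profile table
#'
#' @param classified output of [classify_profiles()].
#' @inheritParams score_syndrome
#' @return tibble with one row per species: `species_name`, `syndrome`,
#'   `points`, `qualifies`.
#' @export
score_species <- function(classified, syndrome = c("traditional",
                                                   "industrial")) {
  syndrome <- match.arg(syndrome)
  classified |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$species_name) |>
    dplyr::summarise(
      points = score_syndrome(
        setNames(as.character(.data$class), .data$nutrient),
        syndrome)$points,
      .groups = "drop") |>
    dplyr::mutate(syndrome = syndrome, qualifies = .data$points >= 6L,
                  .after = "species_name") |>
    dplyr::relocate("points", .after = "syndrome")
}

#' Top-n species by nutrient concentration
#'
#' Ranks species by mean concentration of one nutrient, highest first,
#' ties broken alphabetically by species name; species without data for
#' the nutrient are excluded.
#'
#' @param profiles profile tibble (`species_name`, `nutrient`,
#'   `mean_value`).
#' @param nutrient nutrient code.
#' @param n number of species to return (fewer if the list is shorter).
#' @return tibble with columns `rank`, `species_name`, `mean_value`.
#' @export
top_n_species <- function(profiles, nutrient, n = 10) {
  if (!is.numeric(n) || n < 1) {
    abort("`n` must be at least 1.", class = "pvcrops_usage_error")
  }
  nut <- nutrient
  profiles |>
    tibble::as_tibble() |>
    dplyr::filter(.data$nutrient == nut, !is.na(.data$mean_value)) |>
    dplyr::arrange(dplyr::desc(.data$mean_value), .data$species_name) |>
    dplyr::slice_head(n = n) |>
    dplyr::transmute(rank = dplyr::row_number(), .data$species_name,
                     .data$mean_value)
}

#' Superabundance proportions by form and part
#'
#' For each (growth form, part) cell, the number of crops with any
#' nutrient data, the proportion showing at least one superabundant
#' nutrient (class very high or extremely high) and the proportion with
#' four or more. Profiles are matched to species records by
#' `species_name`; unmatched profiles are dropped with a warning.
#'
#' @param profiles per-part profile tibble from
#'   `aggregate_profiles(mode = "per_part")`.
#' @param species `pv_species` tibble supplying each species' form.
#' @param bounds_set `pv_bounds` tibble.
#' @return tibble with columns `form`, `part`, `n_crops`, `prop_any`,
#'   `prop_four_plus` (proportions in \[0, 1\]).
#' @export
superabundance_by_category <- function(profiles, species, bounds_set) {
  species <- as_species_table(species)
  classified <- classify_profiles(profiles, bounds_set)
  unmatched <- setdiff(unique(classified$species_name),
                       species$species_name)
  if (length(unmatched) > 0) {
    warn(sprintf("Excluding %d profile species with no inventory record: %s.",
                 length(unmatched), paste(unmatched, collapse = ", ")))
    classified <- classified[!classified$species_name %in% unmatched, ]
  }
  forms <- tibble::tibble(species_name = species$species_name,
                          form = species$form)
  classified |>
    dplyr::inner_join(forms, by = "species_name") |>
    dplyr::group_by(.data$form, part = .data$part_scope,
                    .data$species_name) |>
    dplyr::summarise(
      n_super = sum(is_superabundant(.data$class)), .groups = "drop") |>
    dplyr::group_by(.data$form, .data$part) |>
    dplyr::summarise(
      n_crops = dplyr::n(),
      prop_any = mean(.data$n_super >= 1),
      prop_four_plus = mean(.data$n_super >= 4),
      .groups = "drop")
}
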