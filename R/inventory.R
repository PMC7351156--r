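# Species-inventory module: loading, validation and categorical breakdowns
# of cultivated perennial-vegetable (PV) species tables.

#' Categorical levels for species-inventory fields
#'
#' The controlled vocabularies used by the species table. Growth forms fold
#' trees, shrubs, bamboos, palms, cacti, mangroves and woody succulents into
#' `woody`; lianas and herbaceous climbers are `vine`; forbs, ferns, grasses
#' and aquatics are `herb`. Thermal climates follow the USDA-zone based
#' scheme (tropical lowland/highland split at 1500 m elevation within zones
#' 10–11, subtropical = zone 9, warm temperate = 7–8, cold temperate = 4–6,
#' boreal = 2–3, arctic = 1). Domestication status ranges from `global`
#' (traded worldwide, > $1bn sales) down to `historic` (abandoned) and
#' `new_experimental`.
#'
#' @format A named list of character vectors, one per categorical field:
#'   `form`, `parts`, `thermal_climates`, `moisture`, `shade`,
#'   `domestication`, `lifecycle`.
#' @export
pv_levels <- list(
  form = c("woody", "vine", "herb"),
  parts = c("leaf", "shoot", "other_vegetative", "flowerbud", "flower",
            "unripe_fruit", "ripe_fruit", "unripe_seed", "stem"),
  thermal_climates = c("tropical_lowland", "tropical_highland", "subtropical",
                       "warm_temperate", "cold_temperate", "boreal", "arctic"),
  moisture = c("humid", "semi_arid", "arid", "aquatic"),
  shade = c("full_shade", "partial_shade", "sun_only"),
  domestication = c("global", "minor_global", "regional", "historic",
                    "new_experimental"),
  lifecycle = c("perennial", "perennial_grown_as_annual")
)

# Columns holding semicolon-delimited sets in the CSV representation.
pv_set_fields <- c("parts", "thermal_climates", "moisture")

pv_species_cols <- c("species_name", "family", "form", "parts",
                     "thermal_climates", "moisture", "shade",
                     "domestication", "lifecycle")

# Reporting roll-up of the seven thermal climates into three broad belts.
pv_climate_rollup <- c(
  tropical_lowland = "tropical", tropical_highland = "tropical",
  subtropical = "tropical", warm_temperate = "temperate",
  cold_temperate = "temperate", boreal = "boreal_arctic",
  arctic = "boreal_arctic"
)

#' Validate an in-memory species table
#'
#' Checks column presence, enum membership (with row numbers in messages),
#' non-empty set fields, and uniqueness of `species_name`, then returns the
#' table with set-valued columns (`parts`, `thermal_climates`, `moisture`)
#' as list-columns of character vectors.
#'
#' @param df data frame with the columns listed under
#'   [load_species_table()]; set-valued columns may be semicolon-delimited
#'   strings or list-columns.
#' @param set_delim delimiter separating values inside a set-valued cell.
#' @return a `pv_species` tibble (row order preserved).
#' @export
as_species_table <- function(df, set_delim = ";") {
  missing_cols <- setdiff(pv_species_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Species table is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pvcrops_schema_error")
  }
  df <- tibble::as_tibble(df)[pv_species_cols]
  for (fld in pv_set_fields) {
    if (!is.list(df[[fld]])) {
      df[[fld]] <- lapply(strsplit(as.character(df[[fld]]), set_delim,
                                   fixed = TRUE),
                          function(v) trimws(v[nzchar(trimws(v))]))
    }
  }
  validate_species(df)
  class(df) <- c("pv_species", class(df))
  df
}

validate_species <- function(df) {
  dup <- duplicated(df$species_name)
  if (any(dup)) {
    abort(sprintf("Duplicate species_name at row(s): %s.",
                  paste(which(dup), collapse = ", ")),
          class = "pvcrops_validation_error")
  }
  for (fld in c("form", "shade", "domestication", "lifecycle")) {
    bad <- which(!(df[[fld]] %in% pv_levels[[fld]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "Invalid %s value %s at row %d (allowed: %s).",
        fld, encodeString(df[[fld]][bad[1]], quote = "\""), bad[1],
        paste(pv_levels[[fld]], collapse = ", ")),
        class = "pvcrops_validation_error")
    }
  }
  for (fld in pv_set_fields) {
    lens <- lengths(df[[fld]])
    if (any(lens == 0)) {
      abort(sprintf("Column %s must be non-empty (row %d).",
                    fld, which(lens == 0)[1]),
            class = "pvcrops_validation_error")
    }
    ok <- vapply(df[[fld]], function(v) all(v %in% pv_levels[[fld]]),
                 logical(1))
    if (any(!ok)) {
      row <- which(!ok)[1]
      bad_tok <- setdiff(df[[fld]][[row]], pv_levels[[fld]])[1]
      abort(sprintf("Invalid %s value %s at row %d (allowed: %s).",
                    fld, encodeString(bad_tok, quote = "\""), row,
                    paste(pv_levels[[fld]], collapse = ", ")),
            class = "pvcrops_validation_error")
    }
  }
  invisible(df)
}

#' Read a species-inventory CSV
#'
#' Reads a UTF-8 CSV with one row per cultivated species and columns
#' `species_name, family, form, parts, thermal_climates, moisture, shade,
#' domestication, lifecycle`. Set-valued columns hold one or more tokens
#' separated by `set_delim` inside the cell. Every row is validated against
#' [pv_levels]; note that shrubs, trees, bamboos, palms and cacti are all
#' encoded as form `woody`.
#'
#' @param path path to the CSV file.
#' @param set_delim delimiter inside set-valued cells (default `";"`).
#' @return a validated `pv_species` tibble, row order preserved.
#' @export
load_species_table <- function(path, set_delim = ";") {
  if (!file.exists(path)) {
    abort(sprintf("Species file not found: %s", path),
          class = "pvcrops_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  as_species_table(df, set_delim = set_delim)
}

#' Write a species-inventory CSV
#'
#' Inverse of [load_species_table()]: set-valued list-columns are collapsed
#' with `set_delim` and the table is written as UTF-8 CSV, so that a
#' load/write cycle is field-equivalent.
#'
#' @param species a `pv_species` tibble (or coercible data frame).
#' @param path output path.
#' @inheritParams load_species_table
#' @return `path`, invisibly.
#' @export
write_species_table <- function(species, path, set_delim = ";") {
  species <- as_species_table(species, set_delim = set_delim)
  flat <- species
  for (fld in pv_set_fields) {
    flat[[fld]] <- vapply(flat[[fld]], paste, character(1),
                          collapse = set_delim)
  }
  class(flat) <- setdiff(class(flat), "pv_species")
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Categorical breakdown of a species table
#'
#' Counts and percentages of species over one categorical field. For
#' single-valued fields (`form`, `shade`, `domestication`, `lifecycle`) the
#' denominator is the number of species and percentages sum to 100. For
#' set-valued fields (`parts`, `thermal_climates`, `moisture`) species are
#' multi-counted — once per value they carry, as in the published
#' form-by-part figure — and the denominator is the number of field values;
#' `single_count = TRUE` instead counts each species once by its first
#' listed value.
#'
#' @param species a `pv_species` tibble.
#' @param field one of the categorical fields; the aliases `"part"` and
#'   `"climate"` are accepted for `parts` / `thermal_climates`.
#' @param single_count count each species once (first value) instead of
#'   multi-counting set-valued fields.
#' @param climate_rollup for `thermal_climates`, report the three broad
#'   belts (`tropical`, `temperate`, `boreal_arctic`); a species is counted
#'   once per distinct belt it reaches.
#' @return tibble with columns `category`, `count`, `percentage`
#'   (full-precision), carrying attributes `field`, `denominator` and
#'   `multi_count`.
#' @export
breakdown <- function(species, field, single_count = FALSE,
                      climate_rollup = FALSE) {
  aliases <- c(part = "parts", climate = "thermal_climates")
  if (field %in% names(aliases)) field <- aliases[[field]]
  if (!field %in% names(pv_levels)) {
    abort(sprintf("Unknown breakdown field %s.",
                  encodeString(field, quote = "\"")),
          class = "pvcrops_usage_error")
  }
  species <- as_species_table(species)
  is_set <- field %in% pv_set_fields
  levels <- pv_levels[[field]]

  if (is_set) {
    vals <- species[[field]]
    if (climate_rollup && field == "thermal_climates") {
      vals <- lapply(vals, function(v) unique(unname(pv_climate_rollup[v])))
      levels <- unique(unname(pv_climate_rollup))
    }
    vals <- if (single_count) {
      vapply(vals, `[`, character(1), 1)
    } else {
      unlist(vals, use.names = FALSE)
    }
  } else {
    vals <- species[[field]]
  }

  counts <- table(factor(vals, levels = levels))
  denom <- length(vals)
  out <- tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    percentage = if (denom > 0) 100 * as.integer(counts) / denom else
      rep(NA_real_, length(counts))
  )
  attr(out, "field") <- field
  attr(out, "denominator") <- denom
  attr(out, "multi_count") <- is_set && !single_count
  out
}

#' Bounds on the perennial share of vegetable crop species
#'
#' Given counts of fully perennial crops, perennials sometimes grown as
#' annuals, and total vegetable crops in a source, returns the lower and
#' upper percentage bounds of the perennial share: the lower bound counts
#' only fully perennial crops, the upper bound adds the
#' perennial-grown-as-annual crops.
#'
#' @param n_fully_perennial,n_perennial_as_annual,n_total_vegetables counts.
#' @return named numeric `c(lower, upper)` in percent, reported to one
#'   decimal.
#' @export
#' @examples
#' perennial_share(63, 37, 180)  # 35.0, 55.6
perennial_share <- function(n_fully_perennial, n_perennial_as_annual,
                            n_total_vegetables) {
  check_scalar(n_fully_perennial, "n_fully_perennial")
  check_scalar(n_perennial_as_annual, "n_perennial_as_annual")
  check_scalar(n_total_vegetables, "n_total_vegetables")
  if (n_total_vegetables <= 0) {
    abort("`n_total_vegetables` must be positive.",
          class = "pvcrops_domain_error")
  }
  if (n_fully_perennial < 0 || n_perennial_as_annual < 0 ||
      n_fully_perennial + n_perennial_as_annual > n_total_vegetables) {
    abort("Counts must be non-negative and sum to at most the total.",
          class = "pvcrops_domain_error")
  }
  c(lower = round_half_up(100 * n_fully_perennial / n_total_vegetables, 1),
    upper = round_half_up(
      100 * (n_fully_perennial + n_perennial_as_annual) / n_total_vegetables,
      1))
}

#' Share of species in a domestication class
#'
#' @param n_in_class,n_total counts with `0 <= n_in_class <= n_total`.
#' @return percentage, reported to one decimal.
#' @export
#' @examples
#' domestication_share(18, 613)  # 2.9
domestication_share <- function(n_in_class, n_total) {
  check_scalar(n_in_class, "n_in_class")
  check_scalar(n_total, "n_total")
  if (n_total <= 0) {
    abort("`n_total` must be positive.", class = "pvcrops_domain_error")
  }
  if (n_in_class < 0 || n_in_class > n_total) {
    abort("`n_in_class` must lie in [0, n_total].",
          class = "pvcrops_domain_error")
  }
  round_half_up(100 * n_in_class / n_total, 1)
}

#' Current cultivated vegetable-use area
#'
#' Sums vegetable-use areas over crop components, each contributing its
#' production area times the fraction of that area used as a vegetable
#' (e.g. 10% of the olive area is in table olives).
#'
#' @param components data frame with columns `crop`, `production_area_Mha`
#'   (non-negative) and `vegetable_use_fraction` (in `[0, 1]`).
#' @return total vegetable-use area in Mha, reported to one decimal.
#' @export
current_area <- function(components) {
  components <- tibble::as_tibble(components)
  needed <- c("crop", "production_area_Mha", "vegetable_use_fraction")
  missing_cols <- setdiff(needed, names(components))
  if (length(missing_cols) > 0) {
    abort(sprintf("`components` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pvcrops_schema_error")
  }
  if (nrow(components) == 0) {
    abort("`components` must be non-empty.", class = "pvcrops_usage_error")
  }
  if (any(components$production_area_Mha < 0)) {
    abort("Production areas must be non-negative.",
          class = "pvcrops_validation_error")
  }
  if (any(components$vegetable_use_fraction < 0 |
          components$vegetable_use_fraction > 1)) {
    abort("`vegetable_use_fraction` must lie in [0, 1].",
          class = "pvcrops_validation_error")
  }
  round_half_up(sum(components$production_area_Mha *
                      components$vegetable_use_fraction), 1)
}
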