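# Nutrient concentration classes anchored to a reference crop set.
#
# The reference set is a panel of widely grown and marketed vegetables; the
# range of each nutrient across the panel is split into tertiles (low /
# medium / high), values below the panel minimum are "very low", values
# above the panel maximum up to twice the maximum are "very high", and
# anything beyond twice the maximum is "extremely high" ("superabundant"
# covers the last two).

#' Nutrient codes and units
#'
#' The nine nutrients assessed, with their per-100 g fresh-weight units:
#' fiber in g, minerals (Ca, Fe, Mg, Zn) and vitamins C and E in mg,
#' vitamin A in mg retinol activity equivalents (RAE), folate in mcg.
#' Iodine is not assessed: terrestrial plants carry no useful levels.
#'
#' @format Named character vector mapping nutrient code to unit.
#' @export
nutrient_units <- c(
  fiber = "g/100g", Ca = "mg/100g", Fe = "mg/100g", Mg = "mg/100g",
  Zn = "mg/100g", vitA = "mg RAE/100g", folate = "mcg/100g",
  vitC = "mg/100g", vitE = "mg/100g"
)

#' Ordered concentration classes
#'
#' @format Character vector of the six classes, ordered from `very_low` to
#'   `extremely_high`.
#' @export
concentration_classes <- c("very_low", "low", "medium", "high",
                           "very_high", "extremely_high")

#' Short display labels for concentration classes
#'
#' `XH` marks extremely high levels (over twice the reference maximum),
#' `VH` very high (between the reference maximum and twice it), `H` high
#' (top tertile of the reference range), and so on.
#'
#' @format Named character vector mapping class to label.
#' @export
class_labels <- c(very_low = "VL", low = "L", medium = "M", high = "H",
                  very_high = "VH", extremely_high = "XH")

#' Construct concentration-class bounds from a reference range
#'
#' Builds the six-class boundary set for one nutrient from the minimum and
#' maximum concentration observed across the reference crops. The reference
#' range is split into equal tertiles at `t1` and `t2`; `vh_upper` is twice
#' `ref_max` (the very-high / extremely-high edge). When `ref_min` is 0 the
#' very-low class is disabled (`has_very_low = FALSE`), as for vitamin A in
#' the reference panel.
#'
#' @param nutrient nutrient code (a name of [nutrient_units]).
#' @param ref_min,ref_max reference-set minimum and maximum concentration.
#' @return one-row `pv_bounds` tibble with columns `nutrient`, `ref_min`,
#'   `t1`, `t2`, `ref_max`, `vh_upper`, `has_very_low`.
#' @export
#' @examples
#' class_bounds("Ca", 11.85, 238.70)  # vh_upper = 477.40
class_bounds <- function(nutrient, ref_min, ref_max) {
  if (!nutrient %in% names(nutrient_units)) {
    abort(sprintf("Unknown nutrient code %s.",
                  encodeString(nutrient, quote = "\"")),
          class = "pvcrops_usage_error")
  }
  check_scalar(ref_min, "ref_min")
  check_scalar(ref_max, "ref_max")
  if (ref_min < 0 || ref_max < ref_min) {
    abort("Need 0 <= ref_min <= ref_max.", class = "pvcrops_domain_error")
  }
  if (ref_max == ref_min) {
    abort(sprintf("Degenerate reference range for %s (all values equal).",
                  nutrient),
          class = "pvcrops_degenerate_range_error")
  }
  span <- ref_max - ref_min
  out <- tibble::tibble(
    nutrient = nutrient,
    ref_min = ref_min,
    t1 = ref_min + span / 3,
    t2 = ref_min + 2 * span / 3,
    ref_max = ref_max,
    vh_upper = 2 * ref_max,
    has_very_low = ref_min > 0
  )
  class(out) <- c("pv_bounds", class(out))
  out
}

#' Derive class bounds from a reference crop table
#'
#' Computes the per-nutrient min/max over the reference crops (missing
#' cells excluded) and calls [class_bounds()]. Cassava leaf, an extreme
#' outlier among the tracked crops, is excluded by default.
#'
#' @param reference data frame with a `crop_name` column and one numeric
#'   column per nutrient code; empty/`NA` cells mean no data.
#' @param nutrient nutrient code to derive bounds for.
#' @param include_cassava keep cassava-leaf rows (crop names matching
#'   "cassava" or "Manihot esculenta") in the reference set.
#' @return one-row `pv_bounds` tibble.
#' @export
derive_class_bounds <- function(reference, nutrient, include_cassava = FALSE) {
  reference <- tibble::as_tibble(reference)
  if (!"crop_name" %in% names(reference)) {
    abort("`reference` must have a `crop_name` column.",
          class = "pvcrops_schema_error")
  }
  if (!nutrient %in% names(reference)) {
    abort(sprintf("Reference table has no column for nutrient %s.",
                  encodeString(nutrient, quote = "\"")),
          class = "pvcrops_schema_error")
  }
  if (!include_cassava) {
    drop <- grepl("cassava|Manihot esculenta", reference$crop_name,
                  ignore.case = TRUE)
    reference <- reference[!drop, ]
  }
  vals <- na.omit(as.numeric(reference[[nutrient]]))
  if (length(vals) < 2) {
    abort(sprintf(
      "Need at least 2 reference values for %s (have %d).",
      nutrient, length(vals)),
      class = "pvcrops_insufficient_reference_error")
  }
  class_bounds(nutrient, min(vals), max(vals))
}

#' Derive a full bounds set
#'
#' @inheritParams derive_class_bounds
#' @param nutrients nutrient codes to include (default: all columns of
#'   `reference` that are known nutrient codes).
#' @return `pv_bounds` tibble with one row per nutrient.
#' @export
derive_bounds_set <- function(reference, nutrients = NULL,
                              include_cassava = FALSE) {
  if (is.null(nutrients)) {
    nutrients <- intersect(names(reference), names(nutrient_units))
  }
  out <- dplyr::bind_rows(lapply(
    nutrients, derive_class_bounds, reference = reference,
    include_cassava = include_cassava))
  class(out) <- c("pv_bounds", class(out))
  out
}

#' Classify concentrations against class bounds
#'
#' Maps concentrations to the six ordered classes using half-open
#' intervals: `very_low = [0, ref_min)`, `low = [ref_min, t1)`,
#' `medium = [t1, t2)`, `high = [t2, ref_max]`,
#' `very_high = (ref_max, 2*ref_max]`, `extremely_high = (2*ref_max, Inf)`.
#' When the very-low class is disabled (reference minimum 0), `[0, t1)`
#' maps to `low`. Every finite non-negative value falls in exactly one
#' class.
#'
#' @param value numeric vector of concentrations (finite, `>= 0`).
#' @param bounds one-row `pv_bounds` tibble (see [class_bounds()]).
#' @return ordered factor over [concentration_classes].
#' @export
#' @examples
#' b <- class_bounds("Fe", 0.47, 2.11)
#' classify(c(0.2, 1.2, 5), b)  # very_low, medium, extremely_high
classify <- function(value, bounds) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    abort("`value` must be finite and non-negative.",
          class = "pvcrops_domain_error")
  }
  stopifnot(inherits(bounds, "pv_bounds"), nrow(bounds) == 1)
  cls <- character(length(value))
  cls[value > bounds$vh_upper] <- "extremely_high"
  cls[value > bounds$ref_max & value <= bounds$vh_upper] <- "very_high"
  cls[value >= bounds$t2 & value <= bounds$ref_max] <- "high"
  cls[value >= bounds$t1 & value < bounds$t2] <- "medium"
  cls[value < bounds$t1] <- "low"
  if (bounds$has_very_low) {
    cls[value < bounds$ref_min] <- "very_low"
  }
  factor(cls, levels = concentration_classes, ordered = TRUE)
}

#' Is a concentration class superabundant?
#'
#' Superabundant means above the reference-set maximum, i.e. rated
#' `very_high` or `extremely_high`.
#'
#' @param cls character/factor vector of class values.
#' @return logical vector.
#' @export
is_superabundant <- function(cls) {
  as.character(cls) %in% c("very_high", "extremely_high")
}
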