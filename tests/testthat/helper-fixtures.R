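# Shared helpers: a bounds set built from the back-derived reference
# ranges, and a small in-code species table.

fixture_bounds_set <- function(nutrients = NULL) {
  ranges <- pv_fixtures()$class_ranges
  if (!is.null(nutrients)) ranges <- ranges[ranges$nutrient %in% nutrients, ]
  out <- dplyr::bind_rows(lapply(seq_len(nrow(ranges)), function(i) {
    class_bounds(ranges$nutrient[i], ranges$ref_min[i], ranges$ref_max[i])
  }))
  class(out) <- c("pv_bounds", class(out))
  out
}

tiny_species <- function() {
  as_species_table(tibble::tibble(
    species_name = c("Alpha one", "Beta two", "Gamma three"),
    family = c("Fam1", "Fam1", "Fam2"),
    form = c("woody", "herb", "vine"),
    parts = c("leaf", "leaf;shoot", "ripe_fruit"),
    thermal_climates = c("tropical_lowland", "warm_temperate;cold_temperate",
                         "subtropical"),
    moisture = c("humid", "humid;semi_arid", "humid"),
    shade = c("partial_shade", "sun_only", "full_shade"),
    domestication = c("regional", "global", "historic"),
    lifecycle = c("perennial", "perennial_grown_as_annual", "perennial")
  ))
}

# One-row pv_bounds extractor that keeps the class attribute.
bounds_row <- function(bounds_set, nutrient) {
  b <- bounds_set[bounds_set$nutrient == nutrient, ]
  class(b) <- unique(c("pv_bounds", class(b)))
  b
}
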