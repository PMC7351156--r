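# Machine-readable encodings of the published summary tables: rate
# compilations, concentration-class boundaries, the 12-scenario grid,
# the two multi-nutrient species lists, the printed area components and
# the reference-crop panel. Values are carried verbatim from the printed
# tables; each element tags its provenance in a `source` column or
# attribute.

#' Published summary tables as fixtures
#'
#' Returns the printed summary tables in machine-readable form:
#'
#' * `sequestration_rates`: the literature rate compilation (point rates
#'   and ranges in MgC/ha/yr) for the woody and herbaceous categories,
#'   with the printed category averages as an attribute
#'   `printed_averages` (3.71 woody, 0.43 herbaceous).
#' * `class_ranges`: per-nutrient reference-set minima and maxima,
#'   back-derived from the printed class table (the low class's lower
#'   edge and high class's upper edge).
#' * `class_table_printed`: the printed six-class intervals per nutrient
#'   (upper edge `Inf` for the open top class). The printed fiber row is
#'   internally inconsistent and the printed interior edges of some
#'   nutrients differ slightly from exact tertiles; both are carried
#'   as printed.
#' * `scenario_table`: the printed 12-scenario grid (areas in Mha, CO2
#'   columns in MMT CO2-eq/yr). Row `1a`'s woody cells are inconsistent
#'   as printed (flagged in column `consistent`).
#' * `traditional_table` / `industrial_table`: the 16- and 24-species
#'   multi-nutrient lists with their printed XH/VH/H class labels (`NA`
#'   where no label is printed), growth form and parts.
#' * `area_components`: the five printed crop-area components behind the
#'   current cultivated-area figure.
#' * `reference_crops`: the 22 reference vegetable crops (cassava leaf,
#'   excluded as an outlier, is not among them).
#'
#' @return named list of tibbles (and a character vector for
#'   `reference_crops`).
#' @export
pv_fixtures <- function() {
  rates <- tibble::tibble(
    category = c(rep("woody", 9), rep("herbaceous", 4)),
    system = c("cropland to orchard", "Olea europaea", "Bactris gasipaes",
               "Dacryodes edulis", "temperate tree crops",
               "tropical tree crops", "bamboo plantation",
               "fodder tree block", "short-rotation coppice",
               "Vitis vinifera", "giant biomass grasses",
               "perennial grains", "residential herbaceous perennials"),
    rate_low = c(3.5, 2.6, 5.1, 7.8, 2.1, 1.8, 6.0, 0.1, 1.18,
                 0.3, 1.0, 0.3, 0.0),
    rate_high = c(3.5, 2.6, 5.1, 7.8, 2.1, 10.0, 13.0, 0.5, 1.18,
                  0.8, 1.0, 0.5, 0.1),
    source = "published sequestration-rate table"
  )
  attr(rates, "printed_averages") <- c(woody = 3.71, herbaceous = 0.43)

  class_ranges <- tibble::tibble(
    nutrient = c("fiber", "Ca", "Fe", "Mg", "Zn", "vitA", "folate",
                 "vitC", "vitE"),
    ref_min = c(0.40, 11.85, 0.47, 11.25, 0.16, 0.00, 13.50, 5.65, 0.05),
    ref_max = c(3.85, 238.70, 2.11, 85.50, 0.56, 0.55, 194.00, 116.80,
                2.54),
    source = "published concentration-class table (back-derived range)"
  )

  printed <- tibble::tribble(
    ~nutrient, ~class, ~lower, ~upper,
    "fiber", "very_low", 0.00, 0.39, "fiber", "low", 0.40, 1.45,
    "fiber", "medium", 1.46, 2.50, "fiber", "high", 2.51, 3.85,
    "fiber", "very_high", 3.59, 7.15, "fiber", "extremely_high", 7.16, Inf,
    "Ca", "very_low", 0.00, 11.84, "Ca", "low", 11.85, 86.71,
    "Ca", "medium", 86.72, 161.57, "Ca", "high", 161.58, 238.70,
    "Ca", "very_high", 238.71, 477.40, "Ca", "extremely_high", 477.41, Inf,
    "Fe", "very_low", 0.00, 0.46, "Fe", "low", 0.47, 1.01,
    "Fe", "medium", 1.02, 1.55, "Fe", "high", 1.56, 2.11,
    "Fe", "very_high", 2.12, 4.21, "Fe", "extremely_high", 4.22, Inf,
    "Mg", "very_low", 0.00, 11.24, "Mg", "low", 11.25, 35.75,
    "Mg", "medium", 35.76, 60.26, "Mg", "high", 60.27, 85.50,
    "Mg", "very_high", 85.51, 171.00, "Mg", "extremely_high", 171.01, Inf,
    "Zn", "very_low", 0.00, 0.15, "Zn", "low", 0.16, 0.29,
    "Zn", "medium", 0.30, 0.42, "Zn", "high", 0.43, 0.56,
    "Zn", "very_high", 0.57, 1.12, "Zn", "extremely_high", 1.13, Inf,
    "vitA", "very_low", 0.00, 0.00, "vitA", "low", 0.00, 0.18,
    "vitA", "medium", 0.19, 0.37, "vitA", "high", 0.38, 0.55,
    "vitA", "very_high", 0.56, 1.11, "vitA", "extremely_high", 1.12, Inf,
    "folate", "very_low", 0.00, 13.49, "folate", "low", 13.50, 73.07,
    "folate", "medium", 73.08, 132.63, "folate", "high", 132.64, 194.00,
    "folate", "very_high", 194.01, 388.00,
    "folate", "extremely_high", 388.01, Inf,
    "vitC", "very_low", 0.00, 5.64, "vitC", "low", 5.65, 42.33,
    "vitC", "medium", 42.34, 79.01, "vitC", "high", 79.02, 116.80,
    "vitC", "very_high", 116.81, 233.59,
    "vitC", "extremely_high", 233.60, Inf,
    "vitE", "very_low", 0.00, 0.04, "vitE", "low", 0.05, 0.73,
    "vitE", "medium", 0.74, 1.42, "vitE", "high", 1.43, 2.54,
    "vitE", "very_high", 2.55, 5.08, "vitE", "extremely_high", 5.09, Inf
  )
  printed$source <- "published concentration-class table (as printed)"

  scenarios <- tibble::tribble(
    ~id, ~world_veg_area, ~curve, ~woody_fraction, ~woody_Mha,
    ~woody_co2, ~nonwoody_Mha, ~nonwoody_co2, ~total_Mha, ~total_co2,
    "1a", 58.2, "linear", 0.25, 1.2, 4.6, 3.7, 5.8, 4.9, 22.7,
    "1b", 58.2, "linear", 0.50, 2.5, 33.8, 2.5, 3.9, 4.9, 37.7,
    "1c", 58.2, "linear", 0.75, 3.7, 50.7, 1.2, 1.9, 4.9, 52.6,
    "2a", 58.2, "exponential", 0.25, 2.2, 30.0, 6.6, 10.4, 8.8, 40.4,
    "2b", 58.2, "exponential", 0.50, 4.4, 60.0, 4.4, 6.9, 8.8, 67.0,
    "2c", 58.2, "exponential", 0.75, 6.6, 90.1, 2.2, 3.5, 8.8, 93.5,
    "3a", 174.5, "linear", 0.25, 3.7, 50.7, 11.1, 17.5, 14.8, 68.2,
    "3b", 174.5, "linear", 0.50, 7.4, 101.3, 7.4, 11.7, 14.8, 113.0,
    "3c", 174.5, "linear", 0.75, 11.1, 152.0, 3.7, 5.8, 14.8, 157.8,
    "4a", 174.5, "exponential", 0.25, 6.6, 90.1, 19.8, 31.2, 26.4, 121.2,
    "4b", 174.5, "exponential", 0.50, 13.2, 180.1, 13.2, 20.8, 26.4, 200.9,
    "4c", 174.5, "exponential", 0.75, 19.8, 270.2, 6.6, 10.4, 26.4, 280.6
  )
  scenarios$consistent <- scenarios$id != "1a"
  scenarios$source <- "published scenario table"

  traditional <- tibble::tribble(
    ~species_name, ~form, ~parts, ~Fe, ~Zn, ~vitA, ~folate,
    "Cnidoscolus aconitifolius", "woody", "leaf", "XH", NA, "XH", NA,
    "Malva sylvestris", "herb", "leaf", "XH", "XH", NA, NA,
    "Manihot esculenta", "woody", "leaf", "XH", "XH", "VH", NA,
    "Momordica cochinchinensis", "vine", "leaf;unripe_fruit;ripe_fruit",
    "VH", "VH", "VH", "H",
    "Monochoria vaginalis", "herb", "leaf", "VH", "VH", "VH", NA,
    "Moringa oleifera", "woody", "leaf;unripe_fruit;flowerbud",
    "XH", "VH", "VH", NA,
    "Morus alba", "woody", "leaf", "XH", "XH", "VH", NA,
    "Persicaria barbata", "herb", "leaf", "XH", "VH", NA, "VH",
    "Pterocarpus mildbraedii", "woody", "leaf", "XH", "XH", NA, NA,
    "Salix reticulata", "woody", "leaf", "XH", "XH", NA, NA,
    "Senna obtusifolia", "woody", "leaf", "XH", NA, "XH", NA,
    "Senna sophera", "woody", "leaf", "VH", "VH", "VH", "H",
    "Solanum aethiopicum", "herb", "leaf", "XH", "VH", "VH", NA,
    "Toona sinensis", "woody", "leaf", "XH", "XH", "XH", NA,
    "Ulmus pumila", "woody", "ripe_fruit", "XH", "XH", NA, NA,
    "Vitis vinifera", "vine", "leaf", "VH", "VH", "VH", NA
  )
  traditional$source <-
    "published multi-nutrient table, traditional syndrome"

  industrial <- tibble::tribble(
    ~species_name, ~form, ~parts, ~fiber, ~Ca, ~Mg, ~vitA, ~vitC, ~vitE,
    "Asclepias syriaca", "herb", "leaf", NA, "VH", NA, "VH", "XH", NA,
    "Atriplex halimus", "woody", "leaf", "VH", "XH", "XH", NA, NA, NA,
    "Bambusa polymorpha", "woody", "shoot", "VH", "VH", "VH", NA, NA, NA,
    "Cnidoscolus aconitifolius", "woody", "leaf",
    NA, "VH", "VH", "XH", "VH", NA,
    "Coccinia grandis", "vine", "leaf;unripe_fruit",
    "VH", NA, NA, "H", NA, "XH",
    "Dicliptera chinensis", "herb", "leaf", NA, "VH", NA, "VH", NA, "XH",
    "Epilobium angustifolium", "herb", "shoot",
    "H", "H", "VH", NA, "VH", NA,
    "Gnetum gnemon", "woody", "leaf", "VH", NA, "H", "H", "VH", "H",
    "Limnocharis flava", "herb", "leaf;stem;flowerbud",
    "VH", "XH", "XH", "H", NA, NA,
    "Manihot esculenta", "woody", "leaf", "H", "VH", NA, "VH", "XH", "XH",
    "Momordica cochinchinensis", "vine", "leaf;unripe_fruit;ripe_fruit",
    "H", "VH", NA, "VH", "XH", "XH",
    "Moringa oleifera", "woody", "leaf;unripe_fruit;flowerbud",
    "H", "VH", "VH", "VH", "VH", "H",
    "Morus alba", "woody", "leaf", "VH", "VH", "VH", "VH", "VH", NA,
    "Pisonia umbellifera", "woody", "leaf", "VH", "VH", "VH", NA, NA, NA,
    "Sauropus androgynus", "woody", "leaf", NA, NA, NA, "VH", "VH", "XH",
    "Senna obtusifolia", "woody", "leaf", NA, "VH", NA, "XH", "VH", NA,
    "Senna sophera", "woody", "leaf", NA, "H", NA, "VH", "VH", "VH",
    "Sesbania grandiflora", "woody", "leaf",
    "XH", "VH", "VH", NA, "H", "H",
    "Silene vulgaris", "herb", "leaf", "VH", NA, NA, "VH", NA, "XH",
    "Solanum aethiopicum", "herb", "leaf", NA, "VH", NA, "VH", NA, "XH",
    "Toona sinensis", "woody", "leaf", NA, "VH", NA, "XH", "VH", "XH",
    "Trichanthera gigantea", "woody", "leaf",
    NA, "XH", "XH", NA, NA, NA,
    "Urtica dioica", "herb", "leaf", "H", "VH", "H", NA, "VH", "XH",
    "Vitis vinifera", "vine", "leaf", "XH", "VH", "VH", "VH", NA, "H"
  )
  industrial$source <-
    "published multi-nutrient table, industrial syndrome"

  areas <- tibble::tibble(
    crop = c("olive", "asparagus", "avocado", "artichoke", "moringa"),
    production_area_Mha = c(10.6, 1.5, 0.6, 0.1, 0.038),
    vegetable_use_fraction = c(0.10, 1, 1, 1, 1),
    source = "published cultivated-area components"
  )

  reference_crops <- c(
    "Abelmoschus esculentus", "Allium ampeloprasum", "Allium fistulosum",
    "Asparagus officinalis", "Brassica oleracea (Italica)",
    "Brassica oleracea (Capitata)", "Brassica oleracea (Botrytis)",
    "Brassica oleracea (Acephala)", "Brassica rapa", "Capsicum annuum",
    "Cucumis sativus", "Cucurbita spp. (summer)",
    "Cucurbita spp. (winter)", "Cynara scolymus", "Lactuca sativa",
    "Persea americana", "Phaseolus vulgaris", "Pisum sativum",
    "Solanum lycopersicum", "Solanum melongena", "Spinacea oleracea",
    "Zea mays"
  )

  list(sequestration_rates = rates,
       class_ranges = class_ranges,
       class_table_printed = printed,
       scenario_table = scenarios,
       traditional_table = traditional,
       industrial_table = industrial,
       area_components = areas,
       reference_crops = reference_crops)
}

#' Class-label columns of a multi-nutrient fixture as named class vectors
#'
#' Converts one row of the `traditional_table` / `industrial_table`
#' fixtures (XH/VH/H labels) into the named class vector accepted by
#' [score_syndrome()].
#'
#' @param row one-row tibble from a multi-nutrient fixture.
#' @param nutrients nutrient codes to extract (the table's label
#'   columns).
#' @return named character vector of class values (missing labels
#'   dropped).
#' @export
fixture_row_classes <- function(row, nutrients) {
  label_to_class <- setNames(names(class_labels), class_labels)
  labels <- unlist(row[nutrients])
  out <- label_to_class[labels]
  names(out) <- nutrients
  out[!is.na(out)]
}
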