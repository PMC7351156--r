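# Seeded synthetic-data generators for every pipeline input: species
# inventories, multi-source nutrient measurement tables, and crop-area
# time series with known ground truth.
#
# Defaults emulate the study conditions of the compiled datasets: a
# 613-species inventory with the published category shares, a 240-species
# composition table calibrated to a 64% superabundance frequency, and a
# 1967-2017 area series.

check_probs <- function(p, field, levels) {
  if (is.null(names(p)) || !all(names(p) %in% levels)) {
    abort(sprintf("`%s` must be named with levels among: %s.",
                  field, paste(levels, collapse = ", ")),
          class = "pvcrops_spec_error")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must be non-negative and sum to 1.", field),
          class = "pvcrops_spec_error")
  }
  invisible(p)
}

#' Specification for a synthetic species inventory
#'
#' Category probabilities default to the published shares of the
#' 613-species inventory where those are stated (growth form 36.5 / 11.7
#' / 50.9% for woody / vine / herb; domestication 2.9 / 30.7 / 61.0 / 1.5
#' / 2.6%; shade 9% full, 46% partial; lifecycle 18.5%
#' perennial-grown-as-annual), normalised to sum to one. Parts and
#' climates, for which only figure-level information exists, default to a
#' leaf-dominant and tropics-dominant mix.
#'
#' @param n_species number of species to generate.
#' @param form_probs,part_probs,climate_probs,moisture_probs,shade_probs,domestication_probs,lifecycle_probs
#'   named probability vectors over the corresponding [pv_levels].
#' @param extra_value_prob probability that a set-valued field (parts,
#'   climates, moisture) carries a second distinct value.
#' @param seed integer RNG seed.
#' @return list of class `pv_inventory_spec`.
#' @export
inventory_spec <- function(
    n_species = 613,
    form_probs = c(woody = 0.365, vine = 0.117, herb = 0.509) / 0.991,
    part_probs = c(leaf = 0.45, shoot = 0.12, other_vegetative = 0.08,
                   flowerbud = 0.05, flower = 0.05, unripe_fruit = 0.08,
                   ripe_fruit = 0.10, unripe_seed = 0.04, stem = 0.03),
    climate_probs = c(tropical_lowland = 0.30, tropical_highland = 0.10,
                      subtropical = 0.15, warm_temperate = 0.18,
                      cold_temperate = 0.20, boreal = 0.05, arctic = 0.02),
    moisture_probs = c(humid = 0.65, semi_arid = 0.25, arid = 0.05,
                       aquatic = 0.05),
    shade_probs = c(full_shade = 0.09, partial_shade = 0.46,
                    sun_only = 0.45),
    domestication_probs = c(global = 0.029, minor_global = 0.307,
                            regional = 0.610, historic = 0.015,
                            new_experimental = 0.026) / 0.987,
    lifecycle_probs = c(perennial = 0.815, perennial_grown_as_annual = 0.185),
    extra_value_prob = 0.15,
    seed = 1L) {
  if (!is.numeric(n_species) || n_species < 0) {
    abort("`n_species` must be a non-negative count.",
          class = "pvcrops_spec_error")
  }
  probs <- list(form = form_probs, parts = part_probs,
                thermal_climates = climate_probs, moisture = moisture_probs,
                shade = shade_probs, domestication = domestication_probs,
                lifecycle = lifecycle_probs)
  for (fld in names(probs)) check_probs(probs[[fld]], fld, pv_levels[[fld]])
  if (extra_value_prob < 0 || extra_value_prob > 1) {
    abort("`extra_value_prob` must lie in [0, 1].",
          class = "pvcrops_spec_error")
  }
  structure(list(n_species = as.integer(n_species), probs = probs,
                 extra_value_prob = extra_value_prob,
                 seed = as.integer(seed)),
            class = "pv_inventory_spec")
}

sample_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Draw a primary value plus, with prob p, a second distinct value.
sample_set <- function(n, probs, p_extra) {
  primary <- sample_level(n, probs)
  lapply(seq_len(n), function(i) {
    v <- primary[i]
    if (length(probs) > 1 && runif(1) < p_extra) {
      rest <- probs[setdiff(names(probs), v)]
      v <- c(v, sample(names(rest), 1, prob = rest))
    }
    v
  })
}

#' Generate a synthetic species inventory
#'
#' Draws each categorical field independently from the spec's probability
#' maps; set-valued fields get one primary value and occasionally a
#' second. Identical spec and seed give identical output.
#'
#' @param spec an [inventory_spec()].
#' @return a validated `pv_species` tibble with `spec$n_species` rows.
#' @export
gen_inventory <- function(spec) {
  stopifnot(inherits(spec, "pv_inventory_spec"))
  n <- spec$n_species
  if (n == 0) {
    empty <- tibble::tibble(
      species_name = character(), family = character(), form = character(),
      parts = list(), thermal_climates = list(), moisture = list(),
      shade = character(), domestication = character(),
      lifecycle = character())
    return(as_species_table(empty))
  }
  with_seed(spec$seed, {
    df <- tibble::tibble(
      species_name = sprintf("Simulatia specios%04d", seq_len(n)),
      family = sprintf("Simfamily%02d",
                       sample.int(40, n, replace = TRUE)),
      form = sample_level(n, spec$probs$form),
      parts = sample_set(n, spec$probs$parts, spec$extra_value_prob),
      thermal_climates = sample_set(n, spec$probs$thermal_climates,
                                    spec$extra_value_prob),
      moisture = sample_set(n, spec$probs$moisture, spec$extra_value_prob),
      shade = sample_level(n, spec$probs$shade),
      domestication = sample_level(n, spec$probs$domestication),
      lifecycle = sample_level(n, spec$probs$lifecycle)
    )
    as_species_table(df)
  })
}

#' Specification for a synthetic composition table
#'
#' Latent per-species "true" concentrations are log-normal per nutrient
#' (concentrations are positive and right-skewed), with the log-location
#' calibrated against a bounds set so that the expected fraction of
#' species with at least one superabundant nutrient equals
#' `superabundance_target`. Observed source values jitter
#' multiplicatively around the latent value; a fraction of rows are
#' reported on a dry basis with a consistent moisture fraction, so
#' fresh-weight conversion recovers the latent value.
#'
#' The defaults emulate the compiled composition dataset: 240 species, a
#' 64% superabundance frequency, one to three literature sources per
#' species-nutrient, and a quarter of values reported dry.
#'
#' @param n_species number of species.
#' @param superabundance_target target fraction of species with >= 1
#'   superabundant nutrient, in `[0, 1)`.
#' @param nutrient_coverage probability a species has data for a given
#'   nutrient (at least one nutrient is always covered).
#' @param sources_min,sources_max range of sources per species-nutrient.
#' @param dry_basis_fraction probability a source value is dry-basis.
#' @param jitter_sd log-scale SD of per-source observation noise.
#' @param sigma_log log-scale SD of the latent concentration distribution.
#' @param seed integer RNG seed.
#' @return list of class `pv_composition_spec`.
#' @export
composition_spec <- function(n_species = 240,
                             superabundance_target = 0.64,
                             nutrient_coverage = 0.8,
                             sources_min = 1, sources_max = 3,
                             dry_basis_fraction = 0.25,
                             jitter_sd = 0.1,
                             sigma_log = 0.6,
                             seed = 1L) {
  if (!is.numeric(n_species) || n_species < 0) {
    abort("`n_species` must be a non-negative count.",
          class = "pvcrops_spec_error")
  }
  for (frac in c(superabundance_target = superabundance_target,
                 nutrient_coverage = nutrient_coverage,
                 dry_basis_fraction = dry_basis_fraction)) {
    if (frac < 0 || frac > 1) {
      abort("Fractions in the composition spec must lie in [0, 1].",
            class = "pvcrops_spec_error")
    }
  }
  if (superabundance_target >= 1) {
    abort("`superabundance_target` must be below 1.",
          class = "pvcrops_spec_error")
  }
  if (nutrient_coverage <= 0) {
    abort("`nutrient_coverage` must be positive.",
          class = "pvcrops_spec_error")
  }
  if (sigma_log <= 0 || jitter_sd < 0) {
    abort("`sigma_log` must be positive and `jitter_sd` non-negative.",
          class = "pvcrops_spec_error")
  }
  if (sources_min < 1 || sources_max < sources_min) {
    abort("Need 1 <= sources_min <= sources_max.",
          class = "pvcrops_spec_error")
  }
  structure(list(n_species = as.integer(n_species),
                 superabundance_target = superabundance_target,
                 nutrient_coverage = nutrient_coverage,
                 sources_min = as.integer(sources_min),
                 sources_max = as.integer(sources_max),
                 dry_basis_fraction = dry_basis_fraction,
                 jitter_sd = jitter_sd, sigma_log = sigma_log,
                 seed = as.integer(seed)),
            class = "pv_composition_spec")
}

#' Generate a synthetic multi-source composition table
#'
#' Calibration is analytic: with `k` nutrients each covered with
#' probability `c`, the per-nutrient tail probability `p` solves
#' `1 - (1 - c * p)^k = target`, and the log-normal location is then
#' `mu = log(ref_max) - sigma * qnorm(1 - p)` so that
#' `P(latent > ref_max) = p` per nutrient (superabundant means above the
#' reference maximum).
#'
#' @param spec a [composition_spec()].
#' @param bounds_set `pv_bounds` tibble supplying per-nutrient `ref_max`
#'   for calibration.
#' @return measurements tibble (`species_name`, `part`, `nutrient`,
#'   `value`, `basis`, `moisture_fraction`, `source_id`) with attribute
#'   `"latent"`: the species-by-nutrient latent fresh-weight values.
#' @export
gen_composition <- function(spec, bounds_set) {
  stopifnot(inherits(spec, "pv_composition_spec"),
            inherits(bounds_set, "pv_bounds"))
  k <- nrow(bounds_set)
  target <- spec$superabundance_target
  p_tail <- (1 - (1 - target)^(1 / k)) / spec$nutrient_coverage
  if (p_tail > 1) {
    abort("Superabundance target unattainable at this nutrient coverage.",
          class = "pvcrops_spec_error")
  }
  mu <- log(bounds_set$ref_max) - spec$sigma_log * qnorm(1 - p_tail)

  with_seed(spec$seed, {
    n <- spec$n_species
    if (n == 0) {
      out <- tibble::tibble(species_name = character(), part = character(),
                            nutrient = character(), value = numeric(),
                            basis = character(),
                            moisture_fraction = numeric(),
                            source_id = character())
      attr(out, "latent") <- tibble::tibble(species_name = character(),
                                            nutrient = character(),
                                            latent = numeric())
      return(out)
    }
    species <- sprintf("Simulatia nutriens%04d", seq_len(n))
    covered <- matrix(runif(n * k) < spec$nutrient_coverage, nrow = n)
    none <- which(rowSums(covered) == 0)
    for (i in none) covered[i, sample.int(k, 1)] <- TRUE

    rows <- vector("list", n)
    latent_rows <- vector("list", n)
    for (i in seq_len(n)) {
      nut_idx <- which(covered[i, ])
      latent <- exp(rnorm(length(nut_idx), mu[nut_idx], spec$sigma_log))
      latent_rows[[i]] <- tibble::tibble(
        species_name = species[i],
        nutrient = bounds_set$nutrient[nut_idx],
        latent = latent)
      n_src <- sample(seq(spec$sources_min, spec$sources_max),
                      length(nut_idx), replace = TRUE)
      per_nut <- lapply(seq_along(nut_idx), function(j) {
        obs_fresh <- latent[j] * exp(
          rnorm(n_src[j], 0, spec$jitter_sd) - spec$jitter_sd^2 / 2)
        dry <- runif(n_src[j]) < spec$dry_basis_fraction
        moisture <- ifelse(dry, runif(n_src[j], 0.70, 0.95), NA_real_)
        tibble::tibble(
          species_name = species[i],
          part = "leaf",
          nutrient = bounds_set$nutrient[nut_idx[j]],
          value = ifelse(dry, obs_fresh / (1 - moisture), obs_fresh),
          basis = ifelse(dry, "dry", "fresh"),
          moisture_fraction = moisture,
          source_id = sprintf("src%02d", seq_len(n_src[j])))
      })
      rows[[i]] <- dplyr::bind_rows(per_nut)
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "latent") <- dplyr::bind_rows(latent_rows)
    out
  })
}

#' Specification for a synthetic crop-area series
#'
#' @param start_year,end_year series span (defaults 1967–2017, one point
#'   per year).
#' @param curve `"linear"` (`area = base + slope * (year - start_year)`)
#'   or `"exponential"`
#'   (`area = base * exp(rate * (year - start_year))`).
#' @param base area at `start_year` (Mha, positive).
#' @param slope linear trend in Mha/yr (used when `curve = "linear"`).
#' @param rate continuous growth rate per year (when
#'   `curve = "exponential"`).
#' @param noise_sd SD of additive Gaussian noise (Mha); 0 gives a
#'   noiseless series.
#' @param seed integer RNG seed.
#' @return list of class `pv_series_spec`.
#' @export
series_spec <- function(start_year = 1967, end_year = 2017,
                        curve = c("linear", "exponential"),
                        base = 2, slope = 0.1, rate = 0.02,
                        noise_sd = 0, seed = 1L) {
  curve <- match.arg(curve)
  if (end_year <= start_year) {
    abort("`end_year` must exceed `start_year`.",
          class = "pvcrops_spec_error")
  }
  if (base <= 0 || noise_sd < 0) {
    abort("`base` must be positive and `noise_sd` non-negative.",
          class = "pvcrops_spec_error")
  }
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year), curve = curve,
                 base = base, slope = slope, rate = rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "pv_series_spec")
}

#' Generate a synthetic crop-area series
#'
#' Deterministic trend plus seeded Gaussian noise; negative noisy areas
#' are clamped to zero with a warning.
#'
#' @param spec a [series_spec()].
#' @return tibble with columns `year`, `area` (Mha).
#' @export
gen_series <- function(spec) {
  stopifnot(inherits(spec, "pv_series_spec"))
  years <- seq(spec$start_year, spec$end_year)
  trend <- switch(spec$curve,
                  linear = spec$base + spec$slope * (years - spec$start_year),
                  exponential = spec$base *
                    exp(spec$rate * (years - spec$start_year)))
  area <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, trend + rnorm(length(years), 0, spec$noise_sd))
  } else {
    trend
  }
  if (any(area < 0)) {
    warn(sprintf("Clamping %d negative generated area(s) to 0.",
                 sum(area < 0)))
    area <- pmax(0, area)
  }
  tibble::tibble(year = years, area = area)
}
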