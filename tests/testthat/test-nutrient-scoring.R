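# Meta-analytic profiles, syndrome scoring, rankings and superabundance
# breakdowns.

test_that("dry-to-fresh conversion scales by the dry-matter fraction", {
  expect_equal(dry_to_fresh(10, 0.9), 1.0)
  expect_equal(dry_to_fresh(5, 0), 5)
  expect_equal(dry_to_fresh(8, 0.75), 2.0)
  expect_error(dry_to_fresh(1, 1), class = "pvcrops_domain_error")
  expect_error(dry_to_fresh(-1, 0.5), class = "pvcrops_domain_error")
})

test_that("profile aggregation pools fresh-converted means per nutrient", {
  m <- tibble::tibble(
    species_name = "Testus plantus",
    nutrient = c("Fe", "Fe", "Ca"),
    value = c(2.0, 6.0, 100),
    basis = c("fresh", "dry", "fresh"),
    moisture_fraction = c(NA, 0.5, NA),
    source_id = c("a", "b", "c"))
  prof <- aggregate_profile(m)
  fe <- prof[prof$nutrient == "Fe", ]
  expect_equal(fe$mean_value, 2.5)  # mean of 2.0 and 6.0*(1-0.5)=3.0
  expect_equal(fe$n_sources, 2L)
  ca <- prof[prof$nutrient == "Ca", ]
  expect_equal(ca$mean_value, 100)
  expect_equal(ca$n_sources, 1L)
  expect_false("Zn" %in% prof$nutrient)

  mixed <- m
  mixed$species_name[1] <- "Other species"
  expect_error(aggregate_profile(mixed), class = "pvcrops_usage_error")
  nodry <- m
  nodry$moisture_fraction[2] <- NA
  expect_error(aggregate_profile(nodry),
               class = "pvcrops_validation_error")
})

test_that("aggregation is permutation-invariant and scale-consistent", {
  set.seed(5)
  m <- tibble::tibble(
    species_name = "Testus plantus",
    nutrient = sample(c("Fe", "Ca", "Zn"), 30, replace = TRUE),
    value = runif(30, 0, 50),
    basis = sample(c("fresh", "dry"), 30, replace = TRUE),
    source_id = as.character(1:30))
  m$moisture_fraction <- ifelse(m$basis == "dry", runif(30, 0.5, 0.9), NA)
  base <- aggregate_profile(m)
  perm <- aggregate_profile(m[sample.int(30), ])
  expect_equal(dplyr::arrange(base, nutrient),
               dplyr::arrange(perm, nutrient))
  scaled <- m
  scaled$value <- scaled$value * 3
  expect_equal(aggregate_profile(scaled)$mean_value,
               base$mean_value * 3)
})

test_that("species-max mode credits each nutrient's best part", {
  m <- tibble::tibble(
    species_name = "Testus plantus",
    part = c("leaf", "leaf", "flowerbud", "flowerbud"),
    nutrient = c("Fe", "Ca", "Fe", "Ca"),
    value = c(5, 10, 2, 40),
    basis = "fresh", source_id = "a")
  per_part <- aggregate_profiles(m, mode = "per_part")
  expect_equal(nrow(per_part), 4L)
  best <- aggregate_profiles(m, mode = "species_max")
  expect_equal(best$mean_value[best$nutrient == "Fe"], 5)
  expect_equal(best$mean_value[best$nutrient == "Ca"], 40)
})

test_that("syndrome scoring matches the published multi-nutrient rows", {
  s <- score_syndrome(c(Fe = "extremely_high", Zn = "very_high",
                        vitA = "very_high"), "traditional")
  expect_equal(s$points, 7L)
  expect_true(s$qualifies)

  s2 <- score_syndrome(c(Ca = "very_high", vitA = "extremely_high",
                         vitC = "very_high", vitE = "extremely_high"),
                       "industrial")
  expect_equal(s2$points, 10L)
  expect_true(s2$qualifies)

  s3 <- score_syndrome(c(Fe = "medium", Zn = "medium", vitA = "medium",
                         folate = "medium"), "traditional")
  expect_equal(s3$points, 0L)
  expect_false(s3$qualifies)

  # missing nutrients contribute zero but stay visible as NA
  s4 <- score_syndrome(c(Fe = "extremely_high"), "traditional")
  expect_equal(s4$points, 3L)
  expect_true(is.na(s4$contributing[["folate"]]))
})

test_that("scoring agrees with exhaustive enumeration and is monotone", {
  nuts <- syndrome_nutrients$traditional
  pts <- c(very_low = 0, low = 0, medium = 0, high = 1, very_high = 2,
           extremely_high = 3)
  combos <- expand.grid(rep(list(concentration_classes), length(nuts)),
                        stringsAsFactors = FALSE)
  oracle <- rowSums(matrix(pts[as.matrix(combos)], nrow = nrow(combos)))
  got <- vapply(seq_len(nrow(combos)), function(i) {
    score_syndrome(setNames(unlist(combos[i, ]), nuts),
                   "traditional")$points
  }, integer(1))
  expect_equal(got, as.integer(oracle))
  expect_lte(max(got), 12L)  # 4 nutrients x 3 points
  expect_equal(unique(got >= 6), unique(vapply(seq_len(nrow(combos)),
    function(i) score_syndrome(setNames(unlist(combos[i, ]), nuts),
                               "traditional")$qualifies, logical(1))))

  # upgrading one nutrient's class never lowers the score
  set.seed(9)
  for (i in 1:100) {
    cls <- setNames(sample(concentration_classes, 4, replace = TRUE),
                    nuts)
    j <- sample(4, 1)
    k <- match(cls[j], concentration_classes)
    if (k < 6) {
      up <- cls
      up[j] <- concentration_classes[k + 1]
      expect_gte(score_syndrome(up, "traditional")$points,
                 score_syndrome(cls, "traditional")$points)
    }
  }
})

test_that("industrial score is bounded by 18", {
  all_xh <- setNames(rep("extremely_high", 6),
                     syndrome_nutrients$industrial)
  expect_equal(score_syndrome(all_xh, "industrial")$points, 18L)
})

test_that("top-n ranking sorts descending with alphabetical ties", {
  prof <- tibble::tibble(
    species_name = c("Cspec", "Aspec", "Bspec", "Dspec"),
    nutrient = "Ca",
    mean_value = c(100, 300, 200, NA))
  top2 <- top_n_species(prof, "Ca", 2)
  expect_equal(top2$species_name, c("Aspec", "Bspec"))
  expect_equal(top2$rank, 1:2)

  tie <- tibble::tibble(species_name = c("Bspec", "Aspec"),
                        nutrient = "Ca", mean_value = c(100, 100))
  expect_equal(top_n_species(tie, "Ca", 2)$species_name,
               c("Aspec", "Bspec"))
  # n beyond the list returns the full sorted list
  expect_equal(nrow(top_n_species(prof, "Ca", 10)), 3L)
  expect_error(top_n_species(prof, "Ca", 0), class = "pvcrops_usage_error")
})

test_that("superabundance breakdown isolates the constructed cell", {
  bounds <- fixture_bounds_set(c("Fe", "Ca"))
  sp <- tiny_species()  # Alpha one: woody leaf; Beta two: herb; Gamma: vine
  fe_max <- bounds$ref_max[bounds$nutrient == "Fe"]
  prof <- tibble::tibble(
    species_name = c("Alpha one", "Beta two", "Gamma three"),
    part_scope = c("leaf", "leaf", "ripe_fruit"),
    nutrient = "Fe",
    mean_value = c(2.5 * fe_max, 0.5 * fe_max, 0.5 * fe_max),
    n_sources = 1L)
  out <- superabundance_by_category(prof, sp, bounds)
  woody_leaf <- out[out$form == "woody" & out$part == "leaf", ]
  expect_equal(woody_leaf$prop_any, 1)
  expect_equal(sum(out$prop_any > 0), 1L)
  expect_equal(out$prop_four_plus, rep(0, nrow(out)))

  # all-superabundant cohort: every cell at 100%
  prof_all <- prof
  prof_all$mean_value <- 3 * fe_max
  out_all <- superabundance_by_category(prof_all, sp, bounds)
  expect_true(all(out_all$prop_any == 1))

  # unmatched profile species are excluded with a warning
  extra <- rbind(prof, tibble::tibble(
    species_name = "Ghost species", part_scope = "leaf", nutrient = "Fe",
    mean_value = 1, n_sources = 1L))
  expect_warning(superabundance_by_category(extra, sp, bounds),
                 "no inventory record")
})
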