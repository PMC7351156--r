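# Species-inventory loading, validation and breakdown statistics.

test_that("species CSV round-trips through write/load field-equivalently", {
  sp <- tiny_species()
  path <- withr::local_tempfile(fileext = ".csv")
  write_species_table(sp, path)
  back <- load_species_table(path)
  expect_equal(back$species_name, sp$species_name)
  expect_equal(back$form, sp$form)
  expect_equal(back$parts, sp$parts)
  expect_equal(back$thermal_climates, sp$thermal_climates)
  expect_equal(back$moisture, sp$moisture)
  expect_equal(nrow(back), 3L)

  # header-only file gives an empty, valid table
  empty <- sp[0, ]
  write_species_table(empty, path)
  expect_equal(nrow(load_species_table(path)), 0L)
})

test_that("validation rejects bad enums, duplicates, and missing columns", {
  sp <- tiny_species()
  # shrubs are encoded as woody; a literal "shrub" token is rejected
  bad <- sp
  bad$form[2] <- "shrub"
  expect_error(as_species_table(bad), class = "pvcrops_validation_error")
  expect_error(as_species_table(bad), "row 2")

  dup <- sp
  dup$species_name[3] <- dup$species_name[1]
  expect_error(as_species_table(dup), class = "pvcrops_validation_error")

  expect_error(as_species_table(sp[, -3]), class = "pvcrops_schema_error")
  expect_error(as_species_table(sp[, -3]), "form")

  noparts <- sp
  noparts$parts[[1]] <- character(0)
  expect_error(as_species_table(noparts), class = "pvcrops_validation_error")
})

test_that("breakdown counts single- and set-valued fields correctly", {
  sp <- tiny_species()
  bd <- breakdown(sp, "form")
  expect_equal(sum(bd$count), 3L)
  expect_equal(sum(bd$percentage), 100)
  expect_false(attr(bd, "multi_count"))

  all_woody <- sp
  all_woody$form <- "woody"
  bdw <- breakdown(all_woody, "form")
  expect_equal(bdw$percentage[bdw$category == "woody"], 100)

  # parts multi-counts: 4 values over 3 species
  bp <- breakdown(sp, "part")
  expect_true(attr(bp, "multi_count"))
  expect_equal(attr(bp, "denominator"), 4L)
  expect_equal(sum(bp$count), 4L)
  expect_equal(sum(bp$percentage), 100)

  # single-count mode falls back to the primary value
  bp1 <- breakdown(sp, "part", single_count = TRUE)
  expect_equal(sum(bp1$count), 3L)

  expect_error(breakdown(sp, "flavour"), class = "pvcrops_usage_error")
})

test_that("climate roll-up maps seven climates onto three belts", {
  sp <- tiny_species()
  bc <- breakdown(sp, "climate", climate_rollup = TRUE)
  expect_setequal(bc$category, c("tropical", "temperate", "boreal_arctic"))
  # species 2 spans warm+cold temperate but counts once in the belt
  expect_equal(bc$count[bc$category == "temperate"], 1L)
  expect_equal(bc$count[bc$category == "tropical"], 2L)
  expect_equal(sum(bc$count), 3L)
})

test_that("breakdown recovers known generator proportions at n = 613", {
  probs <- c(woody = 0.365, vine = 0.117, herb = 0.509) / 0.991
  sp <- gen_inventory(inventory_spec(n_species = 613, form_probs = probs,
                                     seed = 42))
  bd <- breakdown(sp, "form")
  for (cat in names(probs)) {
    got <- bd$percentage[bd$category == cat]
    expect_lt(abs(got - 100 * probs[[cat]]), 2)
    # exact-binomial 99% acceptance region
    n <- 613
    cnt <- bd$count[bd$category == cat]
    expect_gte(cnt, qbinom(0.005, n, probs[[cat]]))
    expect_lte(cnt, qbinom(0.995, n, probs[[cat]]))
  }
})

test_that("perennial share bounds match published arithmetic and are monotone", {
  expect_equal(perennial_share(63, 37, 180), c(lower = 35.0, upper = 55.6))
  expect_equal(perennial_share(0, 0, 180), c(lower = 0, upper = 0))
  expect_equal(perennial_share(180, 0, 180), c(lower = 100, upper = 100))
  expect_error(perennial_share(1, 0, 0), class = "pvcrops_domain_error")
  expect_error(perennial_share(100, 100, 180),
               class = "pvcrops_domain_error")

  # monotone non-decreasing in each count argument
  set.seed(11)
  for (i in 1:50) {
    tot <- sample(50:500, 1)
    f <- sample.int(tot, 1) - 1
    a <- sample.int(tot - f, 1) - 1
    base <- perennial_share(f, a, tot)
    if (f + a + 1 <= tot) {
      up_f <- perennial_share(f + 1, a, tot)
      up_a <- perennial_share(f, a + 1, tot)
      expect_gte(up_f["lower"], base["lower"])
      expect_gte(up_f["upper"], base["upper"])
      expect_gte(up_a["upper"], base["upper"])
      expect_equal(up_a["lower"], base["lower"])
    }
    expect_lte(base["lower"], base["upper"])
  }
})

test_that("domestication share reproduces printed one-decimal values", {
  expect_equal(domestication_share(18, 613), 2.9)
  expect_equal(domestication_share(613, 613), 100.0)
  expect_error(domestication_share(1, 0), class = "pvcrops_domain_error")
  # brute-force: 374 is the integer count whose share rounds to 61.0
  shares <- vapply(0:613, domestication_share, numeric(1), n_total = 613)
  expect_true(374 %in% (which(shares == 61.0) - 1))
  expect_equal(domestication_share(374, 613), 61.0)
})

test_that("current cultivated area sums component vegetable-use areas", {
  comps <- pv_fixtures()$area_components
  expect_equal(current_area(comps), 3.3)
  expect_equal(current_area(comps[comps$crop == "olive", ]), 1.1)
  zero <- tibble::tibble(crop = "none", production_area_Mha = 0,
                         vegetable_use_fraction = 1)
  expect_equal(current_area(rbind(comps[, 1:3], zero)), 3.3)
  neg <- tibble::tibble(crop = "x", production_area_Mha = -1,
                        vegetable_use_fraction = 1)
  expect_error(current_area(neg), class = "pvcrops_validation_error")
})
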