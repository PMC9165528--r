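test_that("per-item nitrogen intake follows the annualized protein formula", {
  expect_equal(n_intake(0, 0.16, 0), 0)
  expect_equal(n_intake(100, 0.16, 0), 5.84)
  expect_equal(n_intake(100, 0.16, 1), 0)
  expect_error(n_intake(-1, 0.16, 0), "non-negative")
  expect_error(n_intake(10, 0.16, 1.2), "\\[0, 1\\]")
})

test_that("item production and consumption footprints are simple products", {
  expect_equal(production_nf_item(1.6, 2), 3.2)
  expect_equal(production_nf_item(0, 2), 0)
  expect_equal(production_nf_item(5.84, 6.23), 36.3832)
  expect_error(production_nf_item(1, -2), "positive")
  expect_equal(consumption_nf_item(1.6, 0), 1.6)
  expect_equal(consumption_nf_item(1.6, 1), 0)
  expect_equal(consumption_nf_item(1.6, 0.5), 0.8)
  expect_error(consumption_nf_item(1.6, 2), "\\[0, 1\\]")
})

test_that("religious category permissions follow the dietary profiles", {
  expect_false(religion_filter("meat and offal", "Hindu"))
  expect_true(religion_filter("milk and dairy products", "Hindu"))
  expect_false(religion_filter("milk and dairy products", "Buddhist"))
  expect_false(religion_filter("eggs", "Buddhist"))
  expect_true(religion_filter("fish and seafood", "Muslim"))
  expect_true(all(religion_filter(food_categories(), "Christian")))
  expect_error(religion_filter("sweets", "Muslim"), "unknown food category")
})

test_that("a one-item, one-community country collapses to the item terms", {
  sup <- tibble::tibble(country = "A", year = 2000L, item_id = "cer_1",
    category = "cereals", protein_supply = 50, food_waste = 0.1,
    self_sufficiency = 1)
  vnf <- tibble::tibble(country = "A", category = "cereals", year = 2000L,
    trade_vnf = 2.5)
  wts <- tibble::tibble(country = "A", religion = religions(),
    weight = c(1, 0, 0, 0, 0))
  fp <- country_footprint(sup, vnf, wts, nf_config())
  intake <- n_intake(50, 0.16, 0.1)
  want <- production_nf_item(intake, 2.5) + consumption_nf_item(intake, 0)
  expect_equal(fp$total_nf[fp$religion == "Muslim"], want, tolerance = 1e-12)
  expect_equal(fp$total_nf[fp$religion == "all"], want, tolerance = 1e-12)
})

test_that("identical unrestricted diets make the total weight-invariant", {
  # plant-only supply is permitted by every community, so the weighted
  # total must not depend on the weight vector
  sup <- tiny_supply(countries = "A", categories = plant_categories())
  vnf <- tiny_vnf(sup)
  f1 <- country_footprint(sup, vnf, tiny_weights("A", seed = 4),
    nf_config())
  f2 <- country_footprint(sup, vnf, tiny_weights("A", seed = 5),
    nf_config())
  expect_equal(f1$total_nf[f1$religion == "all"],
    f2$total_nf[f2$religion == "all"], tolerance = 1e-12)
})

test_that("country footprints equal the independent triple-loop oracle", {
  for (seed in 1:4) {
    countries <- LETTERS[1:3]
    sup <- tiny_supply(countries = countries, seed = seed)
    vnf <- tiny_vnf(sup, seed = seed + 50)
    wts <- tiny_weights(countries, seed = seed + 100)
    got <- country_footprint(sup, vnf, wts, nf_config())
    want <- oracle_footprint(sup, vnf, wts)
    cmp <- dplyr::inner_join(got, want,
      by = c("country", "year", "religion"), suffix = c("", ".o"))
    expect_equal(nrow(cmp), nrow(got))
    expect_equal(cmp$production_nf, cmp$production_nf.o, tolerance = 1e-12)
    expect_equal(cmp$consumption_nf, cmp$consumption_nf.o,
      tolerance = 1e-12)
    expect_equal(cmp$total_nf, cmp$total_nf.o, tolerance = 1e-12)
  }
})

test_that("footprint totals decompose and the breakdown sums match", {
  sup <- tiny_supply()
  vnf <- tiny_vnf(sup)
  wts <- tiny_weights()
  fp <- country_footprint(sup, vnf, wts, nf_config())
  expect_equal(fp$total_nf, fp$production_nf + fp$consumption_nf,
    tolerance = 1e-9)
  expect_true(all(fp$production_nf >= 0 & fp$consumption_nf >= 0))
  sums <- vapply(fp$breakdown, sum, numeric(1))
  expect_equal(sums, fp$total_nf, tolerance = 1e-9, ignore_attr = TRUE)
  # with denitrification 0 the consumption footprint equals the N intake
  intake <- sum(n_intake(sup$protein_supply[sup$country == "A"], 0.16,
    sup$food_waste[sup$country == "A"]))
  expect_equal(fp$consumption_nf[fp$country == "A" &
    fp$religion == "Muslim"], intake, tolerance = 1e-12)
})

test_that("footprints are linear in supply and monotone in VNF", {
  sup <- tiny_supply()
  vnf <- tiny_vnf(sup)
  wts <- tiny_weights()
  cfg <- nf_config()
  f1 <- country_footprint(sup, vnf, wts, cfg)
  sup2 <- sup
  sup2$protein_supply <- 2 * sup2$protein_supply
  f2 <- country_footprint(sup2, vnf, wts, cfg)
  expect_equal(f2$total_nf, 2 * f1$total_nf, tolerance = 1e-12)

  vnf_up <- vnf
  vnf_up$trade_vnf <- vnf_up$trade_vnf + 0.5
  f3 <- country_footprint(sup, vnf_up, wts, cfg)
  expect_true(all(f3$total_nf >= f1$total_nf - 1e-12))

  # vegetarian communities are insensitive to animal-category VNFs
  vnf_animal <- vnf
  idx <- vnf_animal$category %in% animal_categories()
  vnf_animal$trade_vnf[idx] <- vnf_animal$trade_vnf[idx] * 10
  f4 <- country_footprint(sup, vnf_animal, wts, cfg)
  expect_equal(f4$total_nf[f4$religion == "Buddhist"],
    f1$total_nf[f1$religion == "Buddhist"], tolerance = 1e-12)
})

test_that("a consumed category without a VNF is reported by name", {
  sup <- tiny_supply(countries = "A")
  vnf <- tiny_vnf(sup)
  vnf <- vnf[vnf$category != "fruits", ]
  expect_error(
    country_footprint(sup, vnf, tiny_weights("A"), nf_config()),
    "A/fruits"
  )
})

test_that("regional footprint is the unweighted country mean", {
  res <- tibble::tibble(
    country = c("A", "B"), year = 2000L, religion = "all",
    production_nf = c(6, 7), consumption_nf = c(2, 3),
    total_nf = c(8, 10)
  )
  reg <- regional_footprint(res)
  expect_equal(reg$total_nf, 9)
  expect_equal(reg$country, "ISC average")
  expect_equal(regional_footprint(res[c(1, 1), ])$total_nf, 8)
  expect_error(regional_footprint(res[0, ]), "no country results")

  # six synthetic countries against a direct mean
  sup <- tiny_supply(countries = LETTERS[1:6], seed = 9)
  vnf <- tiny_vnf(sup, seed = 10)
  wts <- tiny_weights(LETTERS[1:6], seed = 11)
  fp <- country_footprint(sup, vnf, wts, nf_config())
  reg <- regional_footprint(fp)
  direct <- mean(fp$total_nf[fp$religion == "Hindu"])
  expect_equal(reg$total_nf[reg$religion == "Hindu"], direct,
    tolerance = 1e-12)
})

test_that("excluded-protein redistribution preserves total protein intake", {
  sup <- tiny_supply(countries = "A")
  vnf <- tiny_vnf(sup)
  wts <- tiny_weights("A")
  cfg <- nf_config(redistribute_excluded = TRUE)
  fp <- country_footprint(sup, vnf, wts, cfg)
  # consumption NF (equal to intake) becomes identical across communities
  # once excluded protein is redistributed, waste being category-uniform
  # here it is not; instead check the Buddhist consumption rose vs default
  fp0 <- country_footprint(sup, vnf, wts, nf_config())
  expect_gt(fp$consumption_nf[fp$religion == "Buddhist"],
    fp0$consumption_nf[fp0$religion == "Buddhist"])
  # and the protein totals match the national total by construction
  scale <- sum(sup$protein_supply) /
    sum(sup$protein_supply[sup$category %in% plant_categories()])
  expect_equal(fp$consumption_nf[fp$religion == "Buddhist"],
    fp0$consumption_nf[fp0$religion == "Buddhist"] * scale,
    tolerance = 1e-12)
})
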