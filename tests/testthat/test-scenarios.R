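test_that("scenario specs wire multipliers and diet flags by name", {
  expect_equal(scenario_spec("BAU")$nue_multiplier, 1)
  expect_false(scenario_spec("BAU")$diet_altered)
  expect_equal(scenario_spec("NUE")$nue_multiplier, 1.3)
  expect_true(scenario_spec("EAT_LANCET")$diet_altered)
  s <- scenario_spec("INTEGRATED")
  expect_equal(s$nue_multiplier, 1.3)
  expect_true(s$diet_altered)
  expect_error(scenario_spec("NUE", nue_multiplier = 0.9), "at least 1")
  expect_error(scenario_spec("BAU", horizon = 2000), "beyond the baseline")
})

test_that("the NUE scenario scales crop cultivation NUE, capped at one", {
  comp <- tibble::tibble(
    category = c("cereals", "fruits", "meat and offal"),
    cultivation_nue = c(0.40, 0.90, 0.30),
    processing_nue = 1, consumer_nue = 1
  )
  out <- apply_nue_scenario(comp, 1.3)
  expect_equal(out$cultivation_nue, c(0.52, 1.00, 0.30))
  expect_error(apply_nue_scenario(comp, 0.8), "at least 1")
  # the domestic VNF shrinks accordingly
  expect_equal(domestic_vnf(out$cultivation_nue[1], 1, 1), 1 / 0.52)
  expect_lt(domestic_vnf(out$cultivation_nue[1], 1, 1),
    domestic_vnf(comp$cultivation_nue[1], 1, 1))
})

test_that("diet alteration reproduces printed decrease-side deltas", {
  t2 <- isc_diet_table()
  # every printed cereal cell equals target(32) - actual
  for (co in unique(t2$country)) {
    for (rel in religions()) {
      d <- t2[t2$country == co & t2$religion == rel, ]
      act <- setNames(ifelse(is.na(d$actual), 0, d$actual), d$category)
      alt <- diet_alteration(act, religion = rel)
      expect_equal(alt$delta[alt$category == "cereals"],
        32 - act[["cereals"]],
        info = paste(co, rel))
    }
  }
  # spot values from the printed table
  d <- t2[t2$country == "Bangladesh" & t2$religion == "Muslim", ]
  act <- setNames(ifelse(is.na(d$actual), 0, d$actual), d$category)
  alt <- diet_alteration(act, religion = "Muslim")
  expect_equal(alt$delta[alt$category == "cereals"], -36)
  d <- t2[t2$country == "Pakistan" & t2$religion == "Buddhist", ]
  act <- setNames(ifelse(is.na(d$actual), 0, d$actual), d$category)
  alt <- diet_alteration(act, religion = "Buddhist")
  expect_equal(alt$delta[alt$category == "cereals"], -24)
})

test_that("diet alteration is a fixed point at the target and conserves shares", {
  tgt <- eat_lancet_targets()
  alt <- diet_alteration(tgt, religion = "Muslim")
  expect_true(all(alt$delta == 0))

  t2 <- isc_diet_table()
  for (rel in c("Hindu", "Buddhist", "Christian")) {
    d <- t2[t2$country == "India" & t2$religion == rel, ]
    act <- setNames(ifelse(is.na(d$actual), 0, d$actual), d$category)
    alt <- diet_alteration(act, religion = rel)
    # share points are conserved: freed decrease equals granted increase
    expect_equal(sum(alt$delta), 0)
    # altered shares stay non-negative
    expect_true(all(alt$actual + alt$delta >= 0))
    # excluded categories never gain share
    excl <- setdiff(food_categories(), religion_profiles()[[rel]])
    expect_true(all(alt$delta[alt$category %in% excl] == 0))
    # meat, eggs and fish are never altered
    expect_true(all(alt$delta[alt$category %in%
      c("meat and offal", "eggs", "fish and seafood")] == 0))
    # decrease categories land exactly on the target
    dec <- alt$note == "decrease"
    expect_equal((alt$actual + alt$delta)[dec], alt$target[dec])
  }
})

test_that("small gaps are suppressed and infeasible redistribution errors", {
  act <- eat_lancet_targets()
  act["cereals"] <- 34  # gap of 2, at the threshold
  alt <- diet_alteration(act, religion = "Muslim")
  expect_equal(alt$delta[alt$category == "cereals"], 0)
  # freed share with no under-target plant category to take it
  act2 <- eat_lancet_targets()
  act2["cereals"] <- 50
  act2[c("vegetables", "fruits", "oil crops and pulses",
    "other plant products", "starchy roots")] <-
    act2[c("vegetables", "fruits", "oil crops and pulses",
      "other plant products", "starchy roots")] + 5
  expect_error(diet_alteration(act2, religion = "Muslim"),
    "no feasible redistribution")
})

test_that("altered supplies hit decrease targets and respect the anchor", {
  w <- generate_world(world_spec(years = 2013, seed = 21,
    supply_noise_sd = 0, ss_sd = 0))
  sup_c <- w$supply[w$supply$country == "India", ]
  sup_c <- validate_supply(sup_c, nf_config(years = c(2013, 2013)))
  spec <- scenario_spec("EAT_LANCET")
  shares <- nitrofoot:::community_shares(sup_c, "Hindu")
  alt <- diet_alteration(shares, religion = "Hindu", spec = spec)

  # zero alteration leaves supplies untouched
  alt0 <- alt
  alt0$delta <- 0
  spec_none <- scenario_spec("EAT_LANCET", anchor_mode = "none")
  out0 <- altered_protein_supply(sup_c, alt0, "Hindu", spec_none)
  expect_equal(out0$protein_supply,
    sup_c$protein_supply[sup_c$category %in%
      religion_profiles()$Hindu], tolerance = 1e-12)

  # with the anchor disabled, altered shares equal actual + delta
  out <- altered_protein_supply(sup_c, alt, "Hindu", spec_none)
  new_shares <- nitrofoot:::community_shares(out, "Hindu")
  dec <- alt$category[alt$note == "decrease"]
  expect_equal(new_shares[dec],
    setNames(alt$target[alt$note == "decrease"], dec), tolerance = 1e-9)
  expect_true(all(out$protein_supply >= 0))

  # capped anchor never exceeds 51 g/day
  out_cap <- altered_protein_supply(sup_c, alt, "Hindu", spec)
  expect_lte(sum(out_cap$protein_supply), spec$protein_anchor + 1e-9)
})

test_that("single-category scaling only touches that category", {
  sup_c <- tiny_supply(countries = "A")
  sup_c <- validate_supply(sup_c, nf_config(years = c(2000, 2000)))
  shares <- nitrofoot:::community_shares(sup_c, "Muslim")
  alt <- tibble::tibble(category = food_categories(),
    actual = unname(shares[food_categories()]), target = 0, delta = 0,
    note = "no change")
  alt$delta[alt$category == "fruits"] <- -shares[["fruits"]] / 2
  out <- altered_protein_supply(sup_c, alt, "Muslim",
    scenario_spec("EAT_LANCET", anchor_mode = "none"))
  expect_equal(out$protein_supply[out$category == "fruits"],
    sup_c$protein_supply[sup_c$category == "fruits"] / 2,
    tolerance = 1e-9)
  other <- out$category != "fruits"
  expect_equal(out$protein_supply[other],
    sup_c$protein_supply[sup_c$category != "fruits"], tolerance = 1e-9)
})

test_that("scenario construction freezes, scales and composes as specified", {
  w <- generate_world(world_spec(years = 2010:2013, seed = 22))
  cfg <- nf_config(years = c(2010, 2013))
  baseline <- world_baseline(w)

  bau <- build_scenario_inputs(scenario_spec("BAU"), baseline, cfg)
  nue <- build_scenario_inputs(scenario_spec("NUE"), baseline, cfg)
  eat <- build_scenario_inputs(scenario_spec("EAT_LANCET"), baseline, cfg)
  int <- build_scenario_inputs(scenario_spec("INTEGRATED"), baseline, cfg)

  # idempotent: applying a spec to its own output returns it unchanged
  expect_identical(build_scenario_inputs(scenario_spec("NUE"), nue, cfg),
    nue)

  # BAU footprint in 2050 equals the baseline-2013 footprint
  fp_bau <- scenario_footprints(bau, cfg)
  vnf13 <- build_vnf_table(w$budgets, w$components, w$supply, cfg,
    by = "year")
  fp13 <- country_footprint(
    w$supply[w$supply$year == 2013, ], vnf13, w$weights, cfg)
  b50 <- fp_bau[fp_bau$year == 2050 & fp_bau$country == "India" &
    fp_bau$religion == "all", ]
  expect_equal(b50$total_nf,
    fp13$total_nf[fp13$country == "India" & fp13$religion == "all"],
    tolerance = 1e-9)

  # the integrated scenario composes the two single transformations,
  # which act on disjoint inputs (order independence)
  expect_equal(int$components, nue$components)
  expect_equal(int$supply, eat$supply)

  # NUE multiplier acts only on crop categories
  plant <- nue$components$category %in% plant_categories()
  expect_equal(nue$components$cultivation_nue[!plant],
    bau$components$cultivation_nue[!plant])
  expect_equal(nue$components$cultivation_nue[plant],
    pmin(bau$components$cultivation_nue[plant] * 1.3, 1))

  # religious exclusions survive the diet shift
  budd <- eat$supply[eat$supply$religion == "Buddhist", ]
  expect_true(all(budd$category %in% plant_categories()))

  expect_error(build_scenario_inputs(scenario_spec("BAU"), nue, cfg),
    "already a 'NUE' scenario")
})

test_that("efficiency and diet scenarios lower the footprint as expected", {
  w <- generate_world(world_spec(years = 2010:2013, seed = 23))
  cfg <- nf_config(years = c(2010, 2013))
  baseline <- world_baseline(w)
  fps <- lapply(c("BAU", "NUE", "EAT_LANCET", "INTEGRATED"), function(nm) {
    scenario_footprints(
      build_scenario_inputs(scenario_spec(nm), baseline, cfg), cfg)
  })
  names(fps) <- c("BAU", "NUE", "EAT_LANCET", "INTEGRATED")
  pick <- function(fp) {
    fp$production_nf[fp$country == "ISC average" & fp$religion == "all" &
      fp$year == 2050]
  }
  tot <- function(fp) {
    fp$total_nf[fp$country == "ISC average" & fp$religion == "all" &
      fp$year == 2050]
  }
  # every cultivation NUE is below cap/1.3, so production NF must drop
  expect_lt(pick(fps$NUE), pick(fps$BAU))
  # the diet shift moves protein into lower-VNF plant categories here
  expect_lt(tot(fps$EAT_LANCET), tot(fps$BAU))
  expect_lte(tot(fps$INTEGRATED), tot(fps$NUE) + 1e-12)
  expect_lte(tot(fps$INTEGRATED), tot(fps$EAT_LANCET) + 1e-12)
})
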