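# Synthetic food-balance-sheet worlds with known ground truth.
#
# The generator emulates the structure of FAO food balance sheets plus
# fertilizer-derived nitrogen budgets: per-item protein supplies with a
# linear trend and multiplicative lognormal noise, crop budgets
# reverse-engineered from a prescribed cultivation-NUE trajectory (so the
# pipeline's pooled quotient recovers the truth exactly), beta-distributed
# self-sufficiency ratios, fixed waste fractions, and per-country religious
# population mixes. Alongside the data it returns GroundTruth tables
# computed in closed form from the noise-free model, written as direct
# arithmetic independent of the pipeline functions.

default_religion_mix <- function(countries) {
  known <- list(
    "Bangladesh" = c(0.890, 0.090, 0.006, 0.005, 0.009),
    "India"      = c(0.140, 0.800, 0.008, 0.023, 0.029),
    "Pakistan"   = c(0.960, 0.020, 0.002, 0.016, 0.002),
    "Sri Lanka"  = c(0.100, 0.130, 0.700, 0.060, 0.010),
    "Nepal"      = c(0.044, 0.810, 0.090, 0.014, 0.042),
    "Bhutan"     = c(0.002, 0.220, 0.750, 0.005, 0.023)
  )
  generic <- c(0.35, 0.35, 0.25, 0.03, 0.02)
  rows <- lapply(seq_along(countries), function(k) {
    w <- known[[countries[k]]]
    if (is.null(w)) w <- generic
    tibble::tibble(country = countries[k], religion = religions(),
      weight = w / sum(w))
  })
  dplyr::bind_rows(rows)
}

#' Specification of a synthetic food-balance world
#'
#' Default scale: the six subcontinent countries, 1961--2013, two supply
#' items per category (20 items), one representative crop per plant
#' category, five religious communities. Supply levels, trends and waste
#' fractions default to magnitudes typical of the region's food balance
#' sheets (a total of roughly 45--55 g protein per capita per day, cereals
#' dominant); the crop cultivation NUE declines linearly from 0.45 to 0.35
#' across the period, with deterministic per-country and per-category
#' offsets so trade blending is non-trivial.
#'
#' @param countries Character vector of country names.
#' @param years Integer years covered.
#' @param items_per_category Supply items generated per category.
#' @param religion_mix Tibble (`country`, `religion`, `weight`); default
#'   region-like mixes.
#' @param supply_base Named per-category base protein supply in the first
#'   year, g per capita per day.
#' @param supply_trend Named per-category linear trend, g per capita per
#'   day per year.
#' @param supply_noise_sd Lognormal sd of multiplicative supply noise
#'   (0 = deterministic).
#' @param nue_start,nue_end Cultivation NUE at the first and last year
#'   (linear in between).
#' @param animal_chain_nue Named chain cultivation efficiencies of the
#'   four animal categories.
#' @param processing_nue,consumer_nue Chain-stage NUEs, shared by all
#'   categories.
#' @param ss_mean Named per-category mean self-sufficiency ratio.
#' @param ss_sd Standard deviation of the beta-distributed ratios
#'   (0 = deterministic).
#' @param waste Named per-category food-waste fraction.
#' @param seed Integer seed; all randomness flows from it through
#'   per-stage subseeds, so adding a stage does not perturb earlier draws.
#' @return An object of class `nf_world_spec`.
#' @export
world_spec <- function(countries = isc_countries(),
                       years = 1961:2013,
                       items_per_category = 2L,
                       religion_mix = default_religion_mix(countries),
                       supply_base = NULL,
                       supply_trend = NULL,
                       supply_noise_sd = 0.05,
                       nue_start = 0.45,
                       nue_end = 0.35,
                       animal_chain_nue = c(
                         "meat and offal" = 0.30,
                         "milk and dairy products" = 0.11,
                         "eggs" = 0.27, "fish and seafood" = 0.85
                       ),
                       processing_nue = 0.92,
                       consumer_nue = 0.90,
                       ss_mean = NULL,
                       ss_sd = 0.03,
                       waste = NULL,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  cats <- food_categories()
  if (is.null(supply_base)) {
    supply_base <- setNames(
      c(25, 1.5, 4, 1, 0.7, 6, 1.2, 5, 0.3, 1.5), cats)
  }
  if (is.null(supply_trend)) {
    supply_trend <- setNames(
      c(0.12, 0.01, 0.03, 0.015, 0.01, 0.04, 0.012, 0.05, 0.005, 0.012),
      cats)
  }
  if (is.null(ss_mean)) {
    ss_mean <- setNames(
      c(0.92, 0.95, 0.80, 0.95, 0.90, 0.85, 0.95, 0.90, 0.97, 0.88), cats)
  }
  if (is.null(waste)) {
    waste <- setNames(c(rep(0.08, 6), rep(0.12, 4)), cats)
  }
  stopifnot(
    all(cats %in% names(supply_base)), all(cats %in% names(supply_trend)),
    all(cats %in% names(ss_mean)), all(cats %in% names(waste)),
    all(animal_categories() %in% names(animal_chain_nue)),
    nue_start > 0, nue_end > 0, processing_nue > 0, processing_nue <= 1,
    consumer_nue > 0, consumer_nue <= 1
  )
  if (nue_start > 1 || nue_end > 1) {
    stop("infeasible spec: cultivation NUE above 1 cannot be generated ",
      "with non-negative seed N", call. = FALSE)
  }
  validate_religion_weights(religion_mix)
  structure(
    list(
      countries = countries, years = as.integer(years),
      items_per_category = as.integer(items_per_category),
      religion_mix = religion_mix, supply_base = supply_base,
      supply_trend = supply_trend, supply_noise_sd = supply_noise_sd,
      nue_start = nue_start, nue_end = nue_end,
      animal_chain_nue = animal_chain_nue,
      processing_nue = processing_nue, consumer_nue = consumer_nue,
      ss_mean = ss_mean, ss_sd = ss_sd, waste = waste,
      seed = as.integer(seed)
    ),
    class = "nf_world_spec"
  )
}

# Deterministic country factors: small symmetric spreads around 1 so that
# countries differ without extra randomness.
country_factors <- function(countries, spread = 0.1) {
  k <- length(countries)
  f <- if (k == 1) 1 else seq(1 - spread, 1 + spread, length.out = k)
  setNames(f, countries)
}

# Deterministic per-category NUE multipliers (plant categories).
category_nue_factors <- function(spread = 0.08) {
  cats <- plant_categories()
  setNames(seq(1 - spread, 1 + spread, length.out = length(cats)), cats)
}

# True cultivation NUE of (country, plant category, year), noise-free.
true_cultivation_nue <- function(spec, country, category, year) {
  yr <- spec$years
  frac <- if (length(yr) == 1) 0 else (year - yr[1]) / (yr[length(yr)] - yr[1])
  base <- spec$nue_start + (spec$nue_end - spec$nue_start) * frac
  cf <- country_factors(spec$countries, 0.06)[country]
  kf <- category_nue_factors()[category]
  pmin(base * cf * kf, 0.999)
}

# Noise-free per-item protein supply, g/cap/day.
true_item_supply <- function(spec, country, category, year) {
  lvl <- (spec$supply_base[[category]] +
    spec$supply_trend[[category]] * (year - spec$years[1])) *
    country_factors(spec$countries)[[country]]
  max(lvl, 0) / spec$items_per_category
}

#' Generate a synthetic world
#'
#' Produces the full input set the pipeline reads (supply, budgets, NUE
#' components, religion weights) plus closed-form GroundTruth tables.
#' Budgets are reverse-engineered from the prescribed NUE trajectory: the
#' input side is split over the five budget components by a Dirichlet draw
#' and the harvested N is set to the target ratio times the input sum, so
#' the pooled cultivation NUE recovers the truth exactly whatever the
#' composition. Reproducible given the spec seed.
#'
#' @param spec A [world_spec()].
#' @return An `nf_world` list: `spec`, `supply`, `budgets`, `components`,
#'   `weights`, and `truth` (list of `vnf` and `footprint` tibbles
#'   computed in closed form from the noise-free model).
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "nf_world_spec"))
  set.seed(spec$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3)
  cats <- food_categories()
  years <- spec$years
  grid_items <- tidyr::expand_grid(
    country = spec$countries,
    category = cats,
    item = seq_len(spec$items_per_category),
    year = years
  )

  # --- supply (stage 1: lognormal level noise, beta self-sufficiency) ---
  set.seed(stage_seeds[1])
  mu <- mapply(function(co, ca, yr) true_item_supply(spec, co, ca, yr),
    grid_items$country, grid_items$category, grid_items$year)
  noise <- if (spec$supply_noise_sd > 0) {
    exp(rnorm(nrow(grid_items), -spec$supply_noise_sd^2 / 2,
      spec$supply_noise_sd))
  } else {
    rep(1, nrow(grid_items))
  }
  ssm <- spec$ss_mean[grid_items$category]
  ss <- if (spec$ss_sd > 0) {
    v <- pmin(spec$ss_sd^2, ssm * (1 - ssm) * 0.5)
    kappa <- ssm * (1 - ssm) / v - 1
    rbeta(nrow(grid_items), ssm * kappa, (1 - ssm) * kappa)
  } else {
    ssm
  }
  supply <- grid_items |>
    dplyr::mutate(
      item_id = paste0(gsub(" ", "_", .data$category), "_", .data$item),
      protein_supply = mu * noise,
      food_waste = spec$waste[.data$category],
      self_sufficiency = unname(ss)
    ) |>
    dplyr::select("country", "year", "item_id", "category",
      "protein_supply", "food_waste", "self_sufficiency")

  # --- budgets (stage 2: Dirichlet input composition) ---
  set.seed(stage_seeds[2])
  grid_crops <- tidyr::expand_grid(
    country = spec$countries, category = plant_categories(), year = years)
  comp <- matrix(rgamma(nrow(grid_crops) * 5, shape = 2), ncol = 5)
  comp <- comp / rowSums(comp)
  den_total <- 1000 * country_factors(spec$countries)[grid_crops$country]
  nue_true <- mapply(function(co, ca, yr) {
    true_cultivation_nue(spec, co, ca, yr)
  }, grid_crops$country, grid_crops$category, grid_crops$year)
  budgets <- grid_crops |>
    dplyr::mutate(
      crop_id = paste0("crop_", gsub(" ", "_", .data$category)),
      n_fert = comp[, 1] * den_total,
      n_man = comp[, 2] * den_total,
      n_adep = comp[, 3] * den_total,
      n_bfix = comp[, 4] * den_total,
      n_seed = comp[, 5] * den_total,
      n_cont = unname(nue_true) * den_total
    ) |>
    dplyr::select("crop_id", "country", "year", "category",
      "n_cont", "n_fert", "n_man", "n_adep", "n_bfix", "n_seed")

  # --- components ---
  components <- tidyr::expand_grid(
    country = spec$countries, category = cats) |>
    dplyr::mutate(
      cultivation_nue = ifelse(.data$category %in% animal_categories(),
        spec$animal_chain_nue[.data$category], NA_real_),
      processing_nue = spec$processing_nue,
      consumer_nue = spec$consumer_nue
    )

  truth <- world_truth(spec)

  structure(
    list(spec = spec, supply = supply, budgets = budgets,
      components = components, weights = spec$religion_mix, truth = truth),
    class = "nf_world"
  )
}

# Closed-form ground truth from the noise-free model. Deliberately written
# as direct arithmetic (no calls into the NUE/VNF/footprint operations) so
# it can stand as an independent oracle for parameter-recovery tests.
world_truth <- function(spec) {
  cats <- food_categories()
  years <- spec$years
  proc <- spec$processing_nue
  cons <- spec$consumer_nue

  vnf_rows <- list()
  for (yr in years) {
    dom <- matrix(NA_real_, length(spec$countries), length(cats),
      dimnames = list(spec$countries, cats))
    for (co in spec$countries) {
      for (ca in cats) {
        cult <- if (ca %in% plant_categories()) {
          true_cultivation_nue(spec, co, ca, yr)
        } else {
          spec$animal_chain_nue[[ca]]
        }
        dom[co, ca] <- 1 / (cult * proc * cons)
      }
    }
    reg <- colMeans(dom)
    for (co in spec$countries) {
      for (ca in cats) {
        s <- spec$ss_mean[[ca]]
        vnf_rows[[length(vnf_rows) + 1]] <- tibble::tibble(
          country = co, category = ca, year = yr,
          domestic_vnf = dom[co, ca],
          trade_vnf = s * dom[co, ca] + (1 - s) * reg[[ca]]
        )
      }
    }
  }
  truth_vnf <- dplyr::bind_rows(vnf_rows)

  p2n <- 0.16  # matches the ingest default when no per-item value is given
  fp_rows <- list()
  for (co in spec$countries) {
    w <- spec$religion_mix[spec$religion_mix$country == co, , drop = FALSE]
    for (yr in years) {
      tv <- truth_vnf[truth_vnf$country == co & truth_vnf$year == yr, ,
        drop = FALSE]
      trade <- setNames(tv$trade_vnf, tv$category)
      intake <- vapply(cats, function(ca) {
        sup <- true_item_supply(spec, co, ca, yr) * spec$items_per_category
        sup * 365 / 1000 * p2n * (1 - spec$waste[[ca]])
      }, numeric(1))
      prod_all <- 0
      cons_all <- 0
      for (rel in religions()) {
        ok <- cats %in% religion_profiles()[[rel]]
        p <- sum(intake[ok] * trade[cats][ok])
        q <- sum(intake[ok])  # denitrification ratio 0
        fp_rows[[length(fp_rows) + 1]] <- tibble::tibble(
          country = co, year = yr, religion = rel,
          production_nf = p, consumption_nf = q, total_nf = p + q
        )
        wr <- w$weight[w$religion == rel]
        prod_all <- prod_all + wr * p
        cons_all <- cons_all + wr * q
      }
      fp_rows[[length(fp_rows) + 1]] <- tibble::tibble(
        country = co, year = yr, religion = "all",
        production_nf = prod_all, consumption_nf = cons_all,
        total_nf = prod_all + cons_all
      )
    }
  }
  list(vnf = truth_vnf, footprint = dplyr::bind_rows(fp_rows))
}

#' @export
print.nf_world <- function(x, ...) {
  cat("<nf_world>", length(x$spec$countries), "countries,",
    length(x$spec$years), "years,", nrow(x$supply), "supply records\n")
  invisible(x)
}

#' Published decadal trade-considered VNF table
#'
#' The packaged transcription of the published decadal trade-considered
#' VNFs of the six subcontinent countries and the regional average, by the
#' ten food categories and the six decade buckets (kg-N loss per kg-N
#' intake).
#'
#' @return Tibble with columns `country` (six countries plus
#'   `"ISC average"`), `category`, `decade`, `vnf`.
#' @export
#' @examples
#' t1 <- isc_vnf_table()
#' subset(t1, country == "ISC average" & decade == "2010s")
isc_vnf_table <- function() {
  path <- system.file("extdata", "vnf_table_isc.csv", package = "nitrofoot",
    mustWork = TRUE)
  readr::read_csv(path, col_types = "cccd", progress = FALSE)
}

#' Published religion-sensitive diet-share table
#'
#' The packaged transcription of the published 2013 food-share table:
#' actual category shares of each community in each country, the
#' EAT-Lancet target shares, and the published recommended alterations
#' (share points). Dash cells are encoded as `NA` in `actual` /
#' `alteration` and as `"no change"` in `change`.
#'
#' @return Tibble with columns `country`, `religion`, `category`,
#'   `eat_lancet_target`, `actual`, `alteration`, `change`.
#' @export
isc_diet_table <- function() {
  path <- system.file("extdata", "diet_shares_isc.csv",
    package = "nitrofoot", mustWork = TRUE)
  tbl <- readr::read_csv(path, col_types = "cccddd", progress = FALSE)
  tbl$change <- ifelse(is.na(tbl$alteration), "no change",
    ifelse(tbl$alteration < 0, "decrease", "increase"))
  tbl
}
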