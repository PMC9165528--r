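# Diet and efficiency scenarios for 2014-2050.
#
# Four scenarios transform the baseline-year (2013) inputs: BAU freezes
# them; NUE raises every crop cultivation NUE by 30% (capped at 1);
# EAT_LANCET shifts each community's food-share composition toward the
# EAT-Lancet planetary health diet while respecting religious exclusions;
# INTEGRATED applies both. The two transformations act on disjoint inputs
# (production efficiencies vs. consumption composition), so their
# composition is order-independent.

#' EAT-Lancet planetary health diet category shares
#'
#' Food-share targets (% of food share) of the planetary health diet,
#' aggregated to the ten categories: cereals 32, starchy roots 2, oil
#' crops and pulses 18, vegetables 3, fruits 5, other plant products 27,
#' meat and offal 4, milk and dairy products 6, eggs 1, fish and
#' seafood 2 (sums to 100).
#'
#' @return Named numeric vector over [food_categories()].
#' @export
eat_lancet_targets <- function() {
  setNames(
    c(32, 2, 18, 3, 5, 27, 4, 6, 1, 2),
    food_categories()
  )
}

#' Scenario specification
#'
#' @param name One of `"BAU"`, `"NUE"`, `"EAT_LANCET"`, `"INTEGRATED"`.
#' @param baseline_year Year whose inputs seed the scenario (default 2013).
#' @param horizon Final projected year (default 2050).
#' @param nue_multiplier Crop cultivation NUE multiplier; defaults to 1.3
#'   for NUE and INTEGRATED, 1 otherwise.
#' @param diet_altered Whether the EAT-Lancet diet shift applies; defaults
#'   to `TRUE` for EAT_LANCET and INTEGRATED.
#' @param calorie_anchor Adult daily calorie reference, kcal (metadata
#'   only; the model operates on protein mass).
#' @param protein_anchor Adult daily protein reference, g per day.
#' @param anchor_mode How the protein anchor constrains altered supplies:
#'   `"cap"` (default) rescales only totals above the anchor down to it,
#'   `"rescale"` rescales every total to the anchor, `"none"` leaves
#'   totals unchanged.
#' @param suppression_threshold Share-point gaps at or below this value are
#'   emitted as "no change" on the decrease side (default 2).
#' @param dairy_protected Communities whose milk-and-dairy share is frozen
#'   (default Muslim and Hindu, the pattern of the published alteration
#'   table; Hindu dairy dependence reflects the lacto-vegetarian diet).
#' @return An object of class `nf_scenario`.
#' @export
#' @examples
#' scenario_spec("INTEGRATED")
scenario_spec <- function(name = c("BAU", "NUE", "EAT_LANCET", "INTEGRATED"),
                          baseline_year = 2013L,
                          horizon = 2050L,
                          nue_multiplier = NULL,
                          diet_altered = NULL,
                          calorie_anchor = 2500,
                          protein_anchor = 51,
                          anchor_mode = c("cap", "rescale", "none"),
                          suppression_threshold = 2,
                          dairy_protected = c("Muslim", "Hindu")) {
  name <- match.arg(name)
  anchor_mode <- match.arg(anchor_mode)
  if (is.null(nue_multiplier)) {
    nue_multiplier <- if (name %in% c("NUE", "INTEGRATED")) 1.3 else 1
  }
  if (is.null(diet_altered)) {
    diet_altered <- name %in% c("EAT_LANCET", "INTEGRATED")
  }
  if (nue_multiplier < 1) {
    stop("nue_multiplier must be at least 1", call. = FALSE)
  }
  if (horizon <= baseline_year) {
    stop("horizon must lie beyond the baseline year", call. = FALSE)
  }
  structure(
    list(
      name = name, baseline_year = as.integer(baseline_year),
      horizon = as.integer(horizon), nue_multiplier = nue_multiplier,
      diet_altered = isTRUE(diet_altered), calorie_anchor = calorie_anchor,
      protein_anchor = protein_anchor, anchor_mode = anchor_mode,
      suppression_threshold = suppression_threshold,
      dairy_protected = dairy_protected
    ),
    class = "nf_scenario"
  )
}

#' @export
print.nf_scenario <- function(x, ...) {
  cat("<nf_scenario>", x$name, "\n")
  cat("  baseline", x$baseline_year, "-> horizon", x$horizon, "\n")
  cat("  cultivation NUE multiplier:", x$nue_multiplier,
    " diet altered:", x$diet_altered, "\n")
  invisible(x)
}

#' Scale crop cultivation NUEs for the NUE scenario
#'
#' Multiplies the cultivation NUE of every crop (plant-category) row by the
#' scenario multiplier, capping at 1; processing and consumer NUEs and
#' animal-chain efficiencies are untouched. The domestic VNF shrinks
#' accordingly.
#'
#' @param components A resolved NUE component tibble (columns `category`,
#'   `cultivation_nue`, `processing_nue`, `consumer_nue`).
#' @param multiplier Factor, at least 1.
#' @return The transformed component tibble.
#' @export
apply_nue_scenario <- function(components, multiplier) {
  if (multiplier < 1) stop("multiplier must be at least 1", call. = FALSE)
  plant <- components$category %in% plant_categories()
  components$cultivation_nue[plant] <-
    pmin(components$cultivation_nue[plant] * multiplier, 1)
  components
}

#' Religion-sensitive diet alteration toward the EAT-Lancet targets
#'
#' Computes per-category share-point deltas for one community. Categories
#' the community excludes, and the animal categories (meat and offal,
#' eggs, fish and seafood), are never altered; milk and dairy is frozen
#' for communities in `spec$dairy_protected`. Any remaining category whose
#' actual share exceeds its target by more than the suppression threshold
#' is decreased exactly to the target; the freed share is redistributed
#' over the under-target plant categories proportionally to their gaps;
#' when the input shares are whole points (as in published tables) the
#' increases are rounded to integers by largest remainder, so the total is
#' conserved either way.
#'
#' @param actual Named numeric vector (or tibble with `category`, `share`)
#'   of the community's actual food shares, % of food share.
#' @param target Named numeric vector of target shares; default
#'   [eat_lancet_targets()].
#' @param religion Community label.
#' @param spec An [scenario_spec()] supplying thresholds and protections.
#' @return Tibble with `category`, `actual`, `target`, `delta`
#'   (share points) and `note` (`"decrease"`, `"increase"`, `"no change"`,
#'   `"frozen"`, `"excluded"`).
#' @export
diet_alteration <- function(actual, target = eat_lancet_targets(),
                            religion, spec = scenario_spec("EAT_LANCET")) {
  if (is.data.frame(actual)) {
    actual <- setNames(actual$share, actual$category)
  }
  cats <- food_categories()
  act <- setNames(rep(0, length(cats)), cats)
  act[names(actual)] <- actual
  tgt <- setNames(rep(0, length(cats)), cats)
  tgt[names(target)] <- target

  permitted <- religion_profiles()[[match.arg(religion, religions())]]
  excluded <- setdiff(cats, permitted)
  frozen <- union(
    c("meat and offal", "eggs", "fish and seafood"),
    if (religion %in% spec$dairy_protected) "milk and dairy products"
  )
  frozen <- setdiff(frozen, excluded)
  free <- setdiff(cats, union(excluded, frozen))

  delta <- setNames(rep(0, length(cats)), cats)
  note <- setNames(rep("no change", length(cats)), cats)
  note[excluded] <- "excluded"
  note[frozen] <- "frozen"

  dec <- free[act[free] - tgt[free] > spec$suppression_threshold]
  delta[dec] <- tgt[dec] - act[dec]
  note[dec] <- "decrease"
  freed <- -sum(delta[dec])

  if (freed > 0) {
    inc <- setdiff(free, dec)
    gaps <- pmax(tgt[inc] - act[inc], 0)
    if (sum(gaps) <= 0) {
      stop("no feasible redistribution: freed share but no under-target ",
        "category to receive it", call. = FALSE)
    }
    raw <- freed * gaps / sum(gaps)
    integral <- abs(freed - round(freed)) < 1e-9 &&
      all(abs(act - round(act)) < 1e-9) && all(abs(tgt - round(tgt)) < 1e-9)
    if (integral) {
      # largest-remainder apportionment keeps the integer deltas summing
      # to the freed share, mirroring published whole-point tables
      fl <- floor(raw)
      rem <- round(freed) - sum(fl)
      add <- rep(0, length(raw))
      if (rem > 0) {
        ord <- order(raw - fl, decreasing = TRUE)
        add[ord[seq_len(rem)]] <- 1
      }
      delta[inc] <- fl + add
    } else {
      delta[inc] <- raw
    }
    note[inc][delta[inc] > 0] <- "increase"
  }

  tibble::tibble(
    category = cats, actual = unname(act), target = unname(tgt),
    delta = unname(delta), note = unname(note)
  )
}

# Actual category shares (% of protein) of one community: protein shares
# over the community's permitted categories.
community_shares <- function(supply_cy, religion) {
  permitted <- religion_profiles()[[religion]]
  sup <- supply_cy[supply_cy$category %in% permitted, , drop = FALSE]
  total <- sum(sup$protein_supply)
  if (total <= 0) {
    return(setNames(rep(0, length(food_categories())), food_categories()))
  }
  by_cat <- tapply(sup$protein_supply, sup$category, sum)
  shares <- setNames(rep(0, length(food_categories())), food_categories())
  shares[names(by_cat)] <- 100 * by_cat / total
  shares
}

#' Apply a diet-alteration table to baseline protein supplies
#'
#' Rescales the community's per-category protein supplies so the altered
#' shares equal actual + delta (record order preserved), then applies the
#' protein anchor per
#' `spec$anchor_mode` (default: totals above 51 g/day are capped at it).
#' Items within a category scale proportionally; a category growing from
#' zero spreads its protein equally over the category's items. No supply
#' ever becomes negative.
#'
#' @param supply_cy National supply records of one country and the
#'   baseline year.
#' @param alteration Output of [diet_alteration()] for one community.
#' @param religion Community label.
#' @param spec An [scenario_spec()].
#' @return Supply records with adjusted `protein_supply` and a `religion`
#'   column, restricted to the community's permitted categories.
#' @export
altered_protein_supply <- function(supply_cy, alteration, religion,
                                   spec = scenario_spec("EAT_LANCET")) {
  permitted <- religion_profiles()[[religion]]
  sup <- supply_cy[supply_cy$category %in% permitted, , drop = FALSE]
  total <- sum(sup$protein_supply)
  new_share <- alteration$actual + alteration$delta
  if (any(new_share < -1e-9)) {
    stop("alteration drives a share negative; no feasible diet", call. = FALSE)
  }
  names(new_share) <- alteration$category
  old_share <- setNames(alteration$actual, alteration$category)

  new_total <- total * sum(new_share) / 100
  anchor_scale <- switch(spec$anchor_mode,
    cap = if (new_total > spec$protein_anchor) {
      spec$protein_anchor / new_total
    } else {
      1
    },
    rescale = if (new_total > 0) spec$protein_anchor / new_total else 1,
    none = 1
  )

  sup$.row <- seq_len(nrow(sup))
  parts <- lapply(split(sup, sup$category), function(d) {
    cat <- d$category[1]
    old_p <- sum(d$protein_supply)
    new_p <- total * new_share[[cat]] / 100 * anchor_scale
    if (old_p > 0) {
      d$protein_supply <- d$protein_supply * new_p / old_p
    } else {
      d$protein_supply <- rep(new_p / nrow(d), nrow(d))
    }
    d
  })
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$.row), setdiff(names(out), ".row"), drop = FALSE]
  out$religion <- religion
  tibble::as_tibble(out)
}

#' Build the transformed input set of a scenario
#'
#' Resolves the baseline-year inputs into a scenario input set: the NUE
#' component table is resolved per (country, category) — crop categories
#' pooled from the baseline-year budgets, animal chains taken as supplied —
#' and then transformed per the spec. Applying a spec to an input set it
#' already produced returns it unchanged (the transformation is
#' idempotent).
#'
#' @param spec An [scenario_spec()].
#' @param baseline List with elements `supply`, `budgets`, `components`,
#'   `weights` covering the baseline year.
#' @param config An [nf_config()].
#' @return An `nf_scenario_inputs` list: `spec`, `years`
#'   (baseline + 1 ... horizon), `supply` (with a `religion` column when the
#'   diet is altered), `components` (resolved), `weights`.
#' @export
build_scenario_inputs <- function(spec, baseline, config = nf_config()) {
  if (inherits(baseline, "nf_scenario_inputs")) {
    if (identical(baseline$spec$name, spec$name)) {
      return(baseline)
    }
    stop("baseline is already a '", baseline$spec$name,
      "' scenario input set", call. = FALSE)
  }
  supply <- validate_supply(baseline$supply, config) |>
    dplyr::filter(.data$year == spec$baseline_year)
  if (nrow(supply) == 0) {
    stop("baseline supply does not cover the baseline year ",
      spec$baseline_year, call. = FALSE)
  }
  budgets <- validate_budgets(baseline$budgets) |>
    dplyr::filter(.data$year == spec$baseline_year)
  components <- validate_nue_components(baseline$components)
  if ("year" %in% names(components)) {
    components <- dplyr::filter(components,
      .data$year == spec$baseline_year)
  }

  cult <- if (nrow(budgets) > 0) {
    budgets |>
      dplyr::summarise(
        pooled_nue = sum(.data$n_cont) /
          sum(.data$n_fert + .data$n_man + .data$n_adep + .data$n_bfix +
            .data$n_seed),
        .by = c("country", "category")
      )
  } else {
    tibble::tibble(country = character(), category = character(),
      pooled_nue = numeric())
  }
  resolved <- components |>
    dplyr::left_join(cult, by = c("country", "category")) |>
    dplyr::mutate(
      cultivation_nue = dplyr::coalesce(.data$pooled_nue,
        .data$cultivation_nue)
    ) |>
    dplyr::select("country", "category", "cultivation_nue",
      "processing_nue", "consumer_nue")
  if (any(is.na(resolved$cultivation_nue))) {
    stop("baseline cultivation NUE unresolved for some (country, category)",
      call. = FALSE)
  }

  if (spec$nue_multiplier > 1) {
    resolved <- apply_nue_scenario(resolved, spec$nue_multiplier)
  }

  if (spec$diet_altered) {
    pieces <- list()
    for (ctry in unique(supply$country)) {
      sup_c <- supply[supply$country == ctry, , drop = FALSE]
      for (rel in religions()) {
        shares <- community_shares(sup_c, rel)
        alt <- diet_alteration(shares, eat_lancet_targets(), rel, spec)
        pieces[[paste(ctry, rel)]] <-
          altered_protein_supply(sup_c, alt, rel, spec)
      }
    }
    supply <- dplyr::bind_rows(pieces)
  }

  structure(
    list(
      spec = spec,
      years = seq(spec$baseline_year + 1L, spec$horizon),
      supply = supply,
      components = resolved,
      weights = validate_religion_weights(baseline$weights)
    ),
    class = "nf_scenario_inputs"
  )
}

#' Footprints of a scenario input set, 2014-2050
#'
#' Computes the footprint of the transformed inputs through the VNF and
#' footprint stages and carries it across the projection years (scenario
#' inputs are held constant after the baseline year). Self-sufficiency for
#' the VNF blend comes from the (community-invariant) item records.
#'
#' @param inputs An `nf_scenario_inputs` from [build_scenario_inputs()].
#' @param config An [nf_config()].
#' @return Tibble with `scenario`, `country` (countries plus
#'   `"ISC average"`), `year`, `religion`, `production_nf`,
#'   `consumption_nf`, `total_nf`.
#' @export
scenario_footprints <- function(inputs, config = nf_config()) {
  stopifnot(inherits(inputs, "nf_scenario_inputs"))
  spec <- inputs$spec
  supply <- inputs$supply
  item_supply <- supply |>
    dplyr::distinct(.data$country, .data$year, .data$item_id,
      .keep_all = TRUE)
  if ("religion" %in% names(item_supply)) {
    item_supply$religion <- NULL
  }
  empty_budgets <- tibble::tibble(
    crop_id = character(), country = character(), year = integer(),
    category = character(), n_cont = numeric(), n_fert = numeric(),
    n_man = numeric(), n_adep = numeric(), n_bfix = numeric(),
    n_seed = numeric()
  )
  vnf <- build_vnf_table(empty_budgets, inputs$components, item_supply,
    config, by = "year")
  base <- country_footprint(supply, vnf, inputs$weights, config)
  base <- dplyr::bind_rows(base, regional_footprint(base)) |>
    dplyr::select("country", "religion", "production_nf",
      "consumption_nf", "total_nf")
  out <- tidyr::expand_grid(year = inputs$years, base) |>
    dplyr::mutate(scenario = spec$name) |>
    dplyr::relocate("scenario", "country", "year")
  out
}
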