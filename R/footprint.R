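# Religion-weighted per-capita food nitrogen footprints.
#
# For each food item the N intake is protein supply x N content of protein
# x (1 - food waste), annualized. The production footprint multiplies the
# intake by the trade-considered VNF; the consumption footprint multiplies
# it by (1 - denitrification ratio), which with the default ratio of 0
# equals the intake itself. Community totals sum permitted items only, and
# the country total is the population-weighted sum over communities.

#' Annual per-capita nitrogen intake of one food item
#'
#' @param protein_supply g protein per capita per day.
#' @param protein_to_n kg-N per kg protein, in (0, 0.25\].
#' @param food_waste Wasted fraction of the supply, in \[0, 1\].
#' @return kg-N per capita per year. Vectorized. Annualization uses 365
#'   days per year uniformly.
#' @export
#' @examples
#' n_intake(100, 0.16, 0)  # 5.84 kg-N/yr
n_intake <- function(protein_supply, protein_to_n, food_waste) {
  if (any(protein_supply < 0)) {
    stop("protein supply must be non-negative", call. = FALSE)
  }
  if (any(protein_to_n <= 0)) {
    stop("protein-to-N fraction must be positive", call. = FALSE)
  }
  if (any(food_waste < 0 | food_waste > 1)) {
    stop("food waste must lie in [0, 1]", call. = FALSE)
  }
  protein_supply * 365 / 1000 * protein_to_n * (1 - food_waste)
}

#' Production nitrogen footprint of one item
#'
#' N lost to the environment while producing the item's consumed N: the
#' intake times the trade-considered VNF.
#'
#' @param intake_n kg-N per capita per year, non-negative.
#' @param trade_vnf Trade-considered VNF, positive.
#' @return kg-N per capita per year. Vectorized.
#' @export
production_nf_item <- function(intake_n, trade_vnf) {
  if (any(intake_n < 0)) stop("intake must be non-negative", call. = FALSE)
  if (any(trade_vnf <= 0)) stop("VNF must be positive", call. = FALSE)
  intake_n * trade_vnf
}

#' Consumption nitrogen footprint of one item
#'
#' N released after consumption: the intake times one minus the
#' denitrification ratio. With the default ratio of 0 (no N-removing
#' wastewater treatment) this equals the intake.
#'
#' @param intake_n kg-N per capita per year, non-negative.
#' @param denitrification_ratio Fraction in \[0, 1\].
#' @return kg-N per capita per year. Vectorized.
#' @export
consumption_nf_item <- function(intake_n, denitrification_ratio = 0) {
  if (any(intake_n < 0)) stop("intake must be non-negative", call. = FALSE)
  if (any(denitrification_ratio < 0 | denitrification_ratio > 1)) {
    stop("denitrification ratio must lie in [0, 1]", call. = FALSE)
  }
  intake_n * (1 - denitrification_ratio)
}

#' Per-capita food nitrogen footprint of countries
#'
#' Computes, for every (country, year) present in `supply`, the per-capita
#' production, consumption and total N footprint of each religious
#' community and the population-weighted country total (religion
#' `"all"`). Communities consume only their permitted categories; with
#' `config$redistribute_excluded = TRUE` the protein of excluded categories
#' is redistributed proportionally over permitted items, otherwise it is
#' dropped.
#'
#' @param supply Supply tibble ([read_supply_table()] schema). An optional
#'   `religion` column marks community-specific supplies (as produced by
#'   diet scenarios); otherwise the national supply is shared.
#' @param vnf Yearly VNF tibble (`build_vnf_table(..., by = "year")`) with
#'   columns `country`, `category`, `year`, `trade_vnf`.
#' @param weights Religion weight tibble (`country`, `religion`, `weight`).
#' @param config An [nf_config()].
#' @return Tibble with columns `country`, `year`, `religion` (the five
#'   communities plus `"all"`), `production_nf`, `consumption_nf`,
#'   `total_nf` (kg-N per capita per year) and a `breakdown` list-column of
#'   named per-category total footprints.
#' @export
country_footprint <- function(supply, vnf, weights, config = nf_config()) {
  supply <- validate_supply(supply, config)
  weights <- validate_religion_weights(weights)
  check_columns(vnf, c("country", "category", "year", "trade_vnf"),
    "VNF table")
  denit <- config$denitrification_ratio
  has_rel <- "religion" %in% names(supply)

  per_rel <- lapply(religions(), function(rel) {
    sup <- if (has_rel) {
      dplyr::filter(supply, .data$religion == rel) |>
        dplyr::select(-"religion")
    } else {
      supply
    }
    permitted <- religion_profiles()[[rel]]
    sup_r <- dplyr::filter(sup, .data$category %in% permitted)
    if (config$redistribute_excluded && !has_rel) {
      totals <- sup |>
        dplyr::summarise(total_p = sum(.data$protein_supply),
          .by = c("country", "year"))
      kept <- sup_r |>
        dplyr::summarise(kept_p = sum(.data$protein_supply),
          .by = c("country", "year"))
      sup_r <- sup_r |>
        dplyr::left_join(totals, by = c("country", "year")) |>
        dplyr::left_join(kept, by = c("country", "year")) |>
        dplyr::mutate(
          protein_supply = ifelse(.data$kept_p > 0,
            .data$protein_supply * .data$total_p / .data$kept_p,
            .data$protein_supply)
        ) |>
        dplyr::select(-"total_p", -"kept_p")
    }
    sup_r <- sup_r |>
      dplyr::left_join(
        dplyr::select(vnf, "country", "category", "year", "trade_vnf"),
        by = c("country", "category", "year")
      )
    missing <- sup_r |>
      dplyr::filter(is.na(.data$trade_vnf), .data$protein_supply > 0) |>
      dplyr::distinct(.data$country, .data$category)
    if (nrow(missing) > 0) {
      stop("no trade VNF for consumed category: ",
        paste(paste0(missing$country, "/", missing$category),
          collapse = "; "), call. = FALSE)
    }
    sup_r |>
      dplyr::filter(!is.na(.data$trade_vnf)) |>
      dplyr::mutate(
        intake = n_intake(.data$protein_supply, .data$protein_to_n,
          .data$food_waste),
        prod = production_nf_item(.data$intake, .data$trade_vnf),
        cons = consumption_nf_item(.data$intake, denit)
      ) |>
      dplyr::summarise(
        production_nf = sum(.data$prod),
        consumption_nf = sum(.data$cons),
        .by = c("country", "year", "category")
      ) |>
      dplyr::mutate(religion = rel)
  })

  by_cat <- dplyr::bind_rows(per_rel)
  # weighted "all" rows share the per-category layout
  all_cat <- by_cat |>
    dplyr::left_join(weights[c("country", "religion", "weight")],
      by = c("country", "religion")) |>
    dplyr::summarise(
      production_nf = sum(.data$production_nf * .data$weight),
      consumption_nf = sum(.data$consumption_nf * .data$weight),
      .by = c("country", "year", "category")
    ) |>
    dplyr::mutate(religion = "all")
  by_cat <- dplyr::bind_rows(by_cat, all_cat) |>
    dplyr::mutate(total = .data$production_nf + .data$consumption_nf)

  totals <- by_cat |>
    dplyr::summarise(
      production_nf = sum(.data$production_nf),
      consumption_nf = sum(.data$consumption_nf),
      .by = c("country", "year", "religion")
    ) |>
    dplyr::mutate(total_nf = .data$production_nf + .data$consumption_nf)

  breakdowns <- by_cat |>
    tidyr::nest(.by = c("country", "year", "religion"),
      .key = "breakdown_tbl") |>
    dplyr::mutate(breakdown = lapply(.data$breakdown_tbl, function(d) {
      setNames(d$total, d$category)
    })) |>
    dplyr::select(-"breakdown_tbl")

  totals |>
    dplyr::left_join(breakdowns, by = c("country", "year", "religion")) |>
    dplyr::arrange(.data$country, .data$year,
      match(.data$religion, c(religions(), "all")))
}

#' Regional average footprint
#'
#' The regional per-capita footprint is the unweighted mean of the country
#' per-capita footprints, computed per year and religion (mirroring the
#' country-level rule for per-religion values).
#'
#' @param country_results Output of [country_footprint()].
#' @return Tibble keyed by (`year`, `religion`) with `country` set to
#'   `"ISC average"` and mean footprint columns.
#' @export
regional_footprint <- function(country_results) {
  if (nrow(country_results) == 0) {
    stop("no country results supplied", call. = FALSE)
  }
  country_results |>
    dplyr::summarise(
      production_nf = mean(.data$production_nf),
      consumption_nf = mean(.data$consumption_nf),
      total_nf = mean(.data$total_nf),
      .by = c("year", "religion")
    ) |>
    dplyr::mutate(country = "ISC average") |>
    dplyr::relocate("country")
}
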