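# Nitrogen use efficiency and virtual nitrogen factors.
#
# The cultivation NUE is a mass-balance quotient: harvested-crop N over the
# sum of the five N inputs (fertilizer, manure, deposition, fixation, seed).
# The domestic VNF is the reciprocal of the chain product of cultivation,
# processing and consumer-level NUEs; the trade-considered VNF blends the
# domestic VNF with the regional average by the self-sufficiency ratio.

#' Cultivation nitrogen use efficiency of a set of crop budgets
#'
#' Computed as a ratio of sums (pooled harvested N over pooled inputs), not
#' a mean of per-crop ratios: pooling is the mass-balance-consistent way to
#' aggregate budgets across crops and years. Values above 1 are arithmetic
#' evidence of soil N mining and are flagged with a warning.
#'
#' @param budgets Tibble of budget records (see [read_budget_table()]), or
#'   any data frame carrying the six `n_*` columns.
#' @return A single fraction, pooled NUE.
#' @export
#' @examples
#' b <- tibble::tibble(n_cont = 40, n_fert = 60, n_man = 20,
#'   n_adep = 5, n_bfix = 10, n_seed = 5)
#' cultivation_nue(b)  # 0.4
cultivation_nue <- function(budgets) {
  if (nrow(budgets) == 0) stop("no budgets supplied", call. = FALSE)
  num <- sum(budgets$n_cont)
  den <- sum(budgets$n_fert + budgets$n_man + budgets$n_adep +
    budgets$n_bfix + budgets$n_seed)
  if (den <= 0) {
    stop("degenerate budget: nitrogen inputs sum to zero", call. = FALSE)
  }
  nue <- num / den
  if (nue > 1) {
    warning("cultivation NUE ", signif(nue, 4),
      " exceeds 1: harvested N exceeds inputs (soil N mining)",
      call. = FALSE)
  }
  nue
}

#' Domestic virtual nitrogen factor from chain NUEs
#'
#' The VNF is the kg of N lost to the environment per kg of N in the food
#' actually consumed: the reciprocal of the product of the cultivation,
#' processing and consumer-level utilization NUEs. It is strictly
#' decreasing in each component.
#'
#' @param cultivation_nue,processing_nue,consumer_nue Positive fractions
#'   (processing and consumer efficiencies at most 1).
#' @return VNF value(s), kg-N loss per kg-N intake. Vectorized.
#' @export
#' @examples
#' domestic_vnf(0.5, 0.8, 0.9)  # 1 / 0.36
domestic_vnf <- function(cultivation_nue, processing_nue = 1,
                         consumer_nue = 1) {
  if (any(cultivation_nue <= 0) || any(processing_nue <= 0) ||
      any(consumer_nue <= 0)) {
    stop("NUE components must be positive", call. = FALSE)
  }
  if (any(processing_nue > 1) || any(consumer_nue > 1)) {
    stop("processing and consumer NUEs must be at most 1", call. = FALSE)
  }
  1 / (cultivation_nue * processing_nue * consumer_nue)
}

#' Trade-considered virtual nitrogen factor
#'
#' Convex combination of the domestic VNF and the regional-average domestic
#' VNF, weighted by the self-sufficiency ratio: fully self-sufficient
#' supply carries the domestic factor, fully imported supply the regional
#' one.
#'
#' @param self_sufficiency Fraction(s) in \[0, 1\].
#' @param domestic Domestic VNF value(s), positive.
#' @param regional_avg Regional-average domestic VNF value(s), positive.
#' @return Trade-considered VNF value(s). Vectorized.
#' @export
#' @examples
#' trade_considered_vnf(0.5, 2, 4)  # 3
trade_considered_vnf <- function(self_sufficiency, domestic, regional_avg) {
  if (any(self_sufficiency < 0) || any(self_sufficiency > 1)) {
    stop("self-sufficiency ratio must lie in [0, 1]", call. = FALSE)
  }
  if (any(domestic <= 0) || any(regional_avg <= 0)) {
    stop("VNF values must be positive", call. = FALSE)
  }
  self_sufficiency * domestic + (1 - self_sufficiency) * regional_avg
}

#' Regional average VNF
#'
#' Unweighted arithmetic mean over the per-country VNF values of one
#' category and decade. Tables report it rounded to 2 decimals; full
#' precision is kept internally.
#'
#' @param country_vnfs Numeric vector of positive per-country VNF values.
#' @return The mean VNF.
#' @export
regional_average_vnf <- function(country_vnfs) {
  if (length(country_vnfs) == 0) {
    stop("no country VNF values supplied", call. = FALSE)
  }
  if (any(!is.finite(country_vnfs)) || any(country_vnfs <= 0)) {
    stop("VNF values must be positive and finite", call. = FALSE)
  }
  mean(country_vnfs)
}

# Round half away from zero, the convention used by the printed tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build the VNF table from budgets, chain NUEs and self-sufficiency
#'
#' Composes the cultivation-NUE, domestic-VNF and trade-considered-VNF
#' steps over every (country, category, year) and aggregates to decades.
#' Plant-category cultivation NUEs are pooled from the crop budgets mapped
#' to the category; animal-category chain NUEs come from the component
#' table's `cultivation_nue` column. Self-sufficiency per (country,
#' category, year) is the unweighted mean over the supply items of the
#' category. Decadal values are equal-weight means of the yearly VNFs
#' within each bucket, and a `"ISC average"` country block holds the
#' unweighted cross-country mean.
#'
#' @param budgets Budget tibble ([read_budget_table()] schema).
#' @param components NUE component tibble ([read_nue_table()] schema); a
#'   `year` column is optional (time-constant components otherwise).
#' @param supply Supply tibble ([read_supply_table()] schema), the source
#'   of self-sufficiency ratios.
#' @param config An [nf_config()].
#' @param by `"decade"` (default, table-shaped) or `"year"` (the yearly
#'   factors consumed by the footprint stage).
#' @return Tibble with columns `country`, `category`, `decade` or `year`,
#'   `self_sufficiency`, `domestic_vnf`, `trade_vnf`. Gaps (a country and
#'   category with no budget, component or supply coverage) are reported
#'   in the `gaps` attribute and omitted, never imputed.
#' @export
build_vnf_table <- function(budgets, components, supply,
                            config = nf_config(),
                            by = c("decade", "year")) {
  by <- match.arg(by)
  budgets <- validate_budgets(budgets)
  components <- validate_nue_components(components)
  supply <- validate_supply(supply, config)

  years <- sort(unique(supply$year))
  grid <- tidyr::expand_grid(
    country = unique(supply$country),
    category = food_categories(),
    year = years
  )

  # cultivation NUE per (country, plant category, year), pooled over crops
  cult <- budgets |>
    dplyr::summarise(
      cultivation_nue = sum(.data$n_cont) /
        sum(.data$n_fert + .data$n_man + .data$n_adep + .data$n_bfix +
          .data$n_seed),
      .by = c("country", "category", "year")
    )

  comp_keys <- intersect(c("country", "category", "year"), names(components))
  comp <- components |>
    dplyr::select(dplyr::all_of(comp_keys), "processing_nue", "consumer_nue",
      chain_nue = "cultivation_nue")

  ss <- supply |>
    dplyr::summarise(self_sufficiency = mean(.data$self_sufficiency),
      .by = c("country", "category", "year"))

  tbl <- grid |>
    dplyr::left_join(cult, by = c("country", "category", "year")) |>
    dplyr::left_join(comp, by = comp_keys) |>
    dplyr::left_join(ss, by = c("country", "category", "year")) |>
    dplyr::mutate(
      cultivation_nue = dplyr::coalesce(.data$cultivation_nue,
        .data$chain_nue)
    )

  gaps <- tbl |>
    dplyr::filter(is.na(.data$cultivation_nue) | is.na(.data$processing_nue) |
      is.na(.data$consumer_nue) | is.na(.data$self_sufficiency)) |>
    dplyr::distinct(.data$country, .data$category)
  if (nrow(gaps) > 0) {
    warning("no VNF computable for ", nrow(gaps),
      " (country, category) pair(s); see attr(., 'gaps')", call. = FALSE)
  }
  tbl <- tbl |>
    dplyr::filter(!is.na(.data$cultivation_nue), !is.na(.data$processing_nue),
      !is.na(.data$consumer_nue), !is.na(.data$self_sufficiency)) |>
    dplyr::mutate(
      domestic_vnf = domestic_vnf(.data$cultivation_nue,
        .data$processing_nue, .data$consumer_nue)
    )

  regional <- tbl |>
    dplyr::summarise(regional_avg = mean(.data$domestic_vnf),
      .by = c("category", "year"))

  yearly <- tbl |>
    dplyr::left_join(regional, by = c("category", "year")) |>
    dplyr::mutate(
      trade_vnf = trade_considered_vnf(.data$self_sufficiency,
        .data$domestic_vnf, .data$regional_avg)
    ) |>
    dplyr::select("country", "category", "year", "self_sufficiency",
      "domestic_vnf", "trade_vnf")

  out <- if (by == "year") {
    yearly
  } else {
    dec <- yearly |>
      dplyr::mutate(decade = assign_decade(.data$year, config)) |>
      dplyr::summarise(
        self_sufficiency = mean(.data$self_sufficiency),
        domestic_vnf = mean(.data$domestic_vnf),
        trade_vnf = mean(.data$trade_vnf),
        .by = c("country", "category", "decade")
      )
    avg <- dec |>
      dplyr::summarise(
        self_sufficiency = mean(.data$self_sufficiency),
        domestic_vnf = mean(.data$domestic_vnf),
        trade_vnf = mean(.data$trade_vnf),
        .by = c("category", "decade")
      ) |>
      dplyr::mutate(country = "ISC average")
    dplyr::bind_rows(dec, avg) |>
      dplyr::relocate("country")
  }
  attr(out, "gaps") <- gaps
  out
}

#' Format a VNF table for presentation
#'
#' Rounds VNFs half away from zero to 2 decimals, matching the precision of
#' published decadal tables.
#'
#' @param vnf_table Output of [build_vnf_table()].
#' @return The table with `domestic_vnf` and `trade_vnf` rounded.
#' @export
format_vnf_table <- function(vnf_table) {
  vnf_table |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("domestic_vnf", "trade_vnf")),
      \(x) round_half_up(x, 2)))
}
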