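# Readers and writers for the long-format CSV interchange tables.
#
# One unambiguous schema per table; FAOSTAT-style wide layouts must be
# pre-melted before ingest. Malformed rows are rejected with row-numbered
# diagnostics rather than silently dropped.

check_columns <- function(tbl, need, what) {
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  invisible(tbl)
}

fail_rows <- function(bad, msg) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    stop(msg, " in row(s): ",
      paste(head(rows, 10), collapse = ", "),
      if (length(rows) > 10) sprintf(" (and %d more)", length(rows) - 10),
      call. = FALSE)
  }
}

#' Read a per-capita protein supply table
#'
#' The canonical interchange format is a long CSV with one row per
#' (country, year, item): columns `country`, `year`, `item_id`, `category`,
#' `protein_supply` (g protein per capita per day), `food_waste` (fraction),
#' `self_sufficiency` (fraction), and optionally `protein_to_n` (kg-N per kg
#' protein; defaults to the configured Jones-factor value where absent).
#'
#' Self-sufficiency ratios above 1 (net exporters) are clamped to 1 on
#' ingest so the trade-considered VNF stays a convex combination of the
#' domestic and regional factors.
#'
#' @param path CSV file path.
#' @param config An [nf_config()].
#' @return Tibble of validated supply records.
#' @export
read_supply_table <- function(path, config = nf_config()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_supply(tbl, config)
}

#' @rdname read_supply_table
#' @param tbl An in-memory supply table to validate (same schema).
#' @export
validate_supply <- function(tbl, config = nf_config()) {
  check_columns(tbl, c("country", "year", "item_id", "category",
    "protein_supply", "food_waste", "self_sufficiency"), "supply table")
  fail_rows(!tbl$category %in% food_categories(), "unknown food category")
  fail_rows(tbl$protein_supply < 0, "negative protein supply")
  fail_rows(tbl$food_waste < 0 | tbl$food_waste > 1,
    "food waste outside [0, 1]")
  fail_rows(tbl$self_sufficiency < 0, "negative self-sufficiency ratio")
  if (!"protein_to_n" %in% names(tbl)) {
    tbl$protein_to_n <- config$protein_to_n_default
  }
  tbl$protein_to_n[is.na(tbl$protein_to_n)] <- config$protein_to_n_default
  fail_rows(tbl$protein_to_n <= 0 | tbl$protein_to_n > 0.25,
    "protein-to-N fraction outside (0, 0.25]")
  n_clamped <- sum(tbl$self_sufficiency > 1)
  if (n_clamped > 0) {
    message("clamped ", n_clamped,
      " self-sufficiency ratio(s) > 1 to 1 (net exporters)")
    tbl$self_sufficiency <- pmin(tbl$self_sufficiency, 1)
  }
  dup_keys <- intersect(c("country", "year", "item_id", "religion"),
    names(tbl))
  dup <- duplicated(tbl[dup_keys])
  fail_rows(dup, "duplicate (country, year, item) record")
  tbl$year <- as.integer(tbl$year)
  tibble::as_tibble(tbl)
}

#' Read a per-crop nitrogen budget table
#'
#' One row per (crop, country, year) with the harvested-N output and the
#' five nitrogen inputs of the cultivation budget: columns `crop_id`,
#' `country`, `year`, `category` (the food category the crop maps to),
#' `n_cont` (kg-N in the harvested crop), `n_fert`, `n_man`, `n_adep`,
#' `n_bfix`, `n_seed` (kg-N from fertilizer, manure, atmospheric
#' deposition, biological fixation and seed).
#'
#' @param path CSV file path.
#' @return Tibble of validated budget records.
#' @export
read_budget_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_budgets(tbl)
}

#' @rdname read_budget_table
#' @param tbl An in-memory budget table to validate.
#' @export
validate_budgets <- function(tbl) {
  ncols <- c("n_cont", "n_fert", "n_man", "n_adep", "n_bfix", "n_seed")
  check_columns(tbl, c("crop_id", "country", "year", "category", ncols),
    "budget table")
  for (cc in ncols) {
    fail_rows(tbl[[cc]] < 0, paste("negative", cc))
  }
  fail_rows(!tbl$category %in% food_categories(), "unknown food category")
  tbl$year <- as.integer(tbl$year)
  tibble::as_tibble(tbl)
}

#' Read a table of chain-stage nitrogen use efficiencies
#'
#' One row per (country, category) or (country, category, year) with
#' `processing_nue` and `consumer_nue` in (0, 1\]. For animal-based
#' categories, whose production-chain efficiency is not derived from crop
#' budgets, a `cultivation_nue` column supplies the whole-chain cultivation
#' efficiency directly; it may be NA for plant categories (computed from
#' budgets instead).
#'
#' @param path CSV file path.
#' @return Tibble of validated NUE component records.
#' @export
read_nue_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_nue_components(tbl)
}

#' @rdname read_nue_table
#' @param tbl An in-memory NUE component table to validate.
#' @export
validate_nue_components <- function(tbl) {
  check_columns(tbl, c("country", "category", "processing_nue",
    "consumer_nue"), "NUE component table")
  fail_rows(!tbl$category %in% food_categories(), "unknown food category")
  for (cc in c("processing_nue", "consumer_nue")) {
    fail_rows(tbl[[cc]] <= 0 | tbl[[cc]] > 1,
      paste(cc, "outside (0, 1]"))
  }
  if (!"cultivation_nue" %in% names(tbl)) tbl$cultivation_nue <- NA_real_
  fail_rows(!is.na(tbl$cultivation_nue) & tbl$cultivation_nue <= 0,
    "non-positive cultivation_nue")
  need_chain <- tbl$category %in% animal_categories()
  fail_rows(need_chain & is.na(tbl$cultivation_nue),
    "animal category without a supplied cultivation_nue")
  tibble::as_tibble(tbl)
}

#' Read a religious population weight table
#'
#' Columns `country`, `religion`, `weight` (optionally `year`); weights sum
#' to 1 per country. Weights are treated as time-constant unless a year
#' column is supplied.
#'
#' @param path CSV file path.
#' @return Tibble of validated weights.
#' @export
read_religion_weights <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_religion_weights(tibble::as_tibble(tbl))
}

#' Write a result or input table to CSV
#'
#' Plain UTF-8 CSV with a header row; the inverse of the readers, so that
#' `read(write(x))` round-trips field-wise.
#'
#' @param tbl Tibble to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_nf_table <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Echoes the configuration, record counts and any collected warnings so a
#' run can be audited without re-executing it.
#'
#' @param config The [nf_config()] used.
#' @param counts Named list of record counts.
#' @param warnings Character vector of warnings (may be empty).
#' @param path Destination path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(config, counts, warnings = character(), path) {
  report <- list(
    config = list(
      countries = config$countries,
      years = config$years,
      denitrification_ratio = config$denitrification_ratio,
      protein_to_n_default = config$protein_to_n_default,
      redistribute_excluded = config$redistribute_excluded,
      seed = config$seed
    ),
    counts = counts,
    warnings = as.character(warnings)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(path)
}
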