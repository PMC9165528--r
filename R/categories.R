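# Aggregated food categories and religious dietary profiles.

#' The ten aggregated food categories
#'
#' Food-balance-sheet items are aggregated into ten categories for virtual
#' nitrogen factor (VNF) and footprint accounting: six plant-based and four
#' animal-based groups.
#'
#' @return Character vector of the 10 category labels.
#' @export
#' @examples
#' food_categories()
food_categories <- function() {
  c(
    "cereals", "starchy roots", "oil crops and pulses", "vegetables",
    "fruits", "other plant products", "meat and offal",
    "milk and dairy products", "eggs", "fish and seafood"
  )
}

#' @rdname food_categories
#' @export
plant_categories <- function() food_categories()[1:6]

#' @rdname food_categories
#' @export
animal_categories <- function() food_categories()[7:10]

#' Religious communities and their category-level dietary profiles
#'
#' Five communities are modelled. Hindus are treated as lacto-vegetarians
#' (no meat and offal, eggs, or fish and seafood; dairy permitted);
#' Buddhists as vegetarians consuming plant products only (additionally no
#' milk and dairy products); Muslims, Christians and the residual "Others"
#' group carry no category-level restrictions.
#'
#' @return `religions()`: character vector of the five community labels.
#'   `religion_profiles()`: named list mapping each community to its allowed
#'   category labels.
#' @export
#' @examples
#' religion_profiles()$Hindu
religions <- function() {
  c("Muslim", "Hindu", "Buddhist", "Christian", "Others")
}

#' @rdname religions
#' @export
religion_profiles <- function() {
  cats <- food_categories()
  list(
    Muslim    = cats,
    Hindu     = setdiff(cats, c("meat and offal", "eggs", "fish and seafood")),
    Buddhist  = plant_categories(),
    Christian = cats,
    Others    = cats
  )
}

#' Is a food category permitted for a religious community?
#'
#' Excluded categories contribute zero nitrogen intake for that community.
#'
#' @param category Category label(s), from [food_categories()].
#' @param religion A single community label, from [religions()].
#' @return Logical vector, `TRUE` where the category is permitted.
#' @export
#' @examples
#' religion_filter("meat and offal", "Hindu")
#' religion_filter("milk and dairy products", "Hindu")
religion_filter <- function(category, religion) {
  religion <- match.arg(religion, religions())
  bad <- setdiff(category, food_categories())
  if (length(bad) > 0) {
    stop("unknown food category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  category %in% religion_profiles()[[religion]]
}

#' Check a table of religious population weights
#'
#' Weights must cover the five communities and sum to 1 per country (and per
#' year, when a year column is present).
#'
#' @param weights Tibble with columns `country`, `religion`, `weight`
#'   (optionally `year`).
#' @param tol Tolerance on the per-country sum.
#' @return The validated tibble, invisibly usable downstream.
#' @export
validate_religion_weights <- function(weights, tol = 1e-9) {
  need <- c("country", "religion", "weight")
  miss <- setdiff(need, names(weights))
  if (length(miss) > 0) {
    stop("religion weights missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  bad <- setdiff(unique(weights$religion), religions())
  if (length(bad) > 0) {
    stop("unknown religious community: ", paste(bad, collapse = ", "),
      call. = FALSE)
  }
  if (any(weights$weight < 0)) stop("negative population weight", call. = FALSE)
  keys <- if ("year" %in% names(weights)) c("country", "year") else "country"
  sums <- weights |>
    dplyr::summarise(s = sum(.data$weight), .by = dplyr::all_of(keys))
  off <- sums[abs(sums$s - 1) > tol, , drop = FALSE]
  if (nrow(off) > 0) {
    stop("population weights do not sum to 1 for: ",
      paste(off$country, collapse = ", "), call. = FALSE)
  }
  weights
}
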