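# Analysis configuration: countries, year range, decade buckets, scalar
# parameters shared by every stage.

#' Analysis configuration
#'
#' Bundles the run-level choices: the country set, the inclusive year range,
#' the decade buckets used for tabulation, the wastewater denitrification
#' ratio (0 by default: no nitrogen-removing sewage treatment is assumed),
#' and the default nitrogen content of protein (0.16 kg-N per kg protein,
#' the reciprocal of the Jones factor 6.25, overridable per item).
#'
#' @param countries Character vector of country names.
#' @param years Inclusive year range, length-2 integer.
#' @param decade_buckets Named list mapping decade labels to length-2 year
#'   ranges. The default partitions 1961--2013 into "1960s" ... "2010s";
#'   the first bucket covers 1961--1969 because FAO series begin in 1961.
#' @param denitrification_ratio Fraction of consumed-food N removed during
#'   wastewater treatment, in \[0, 1\]. Default 0.
#' @param protein_to_n_default Default kg-N per kg protein, in (0, 0.25\].
#' @param redistribute_excluded If `TRUE`, protein from categories a
#'   community excludes is redistributed proportionally over its permitted
#'   categories; if `FALSE` (default) excluded categories simply contribute
#'   zero.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `nf_config`.
#' @export
#' @examples
#' cfg <- nf_config(countries = c("India", "Nepal"))
#' assign_decade(1975, cfg)
nf_config <- function(countries = isc_countries(),
                      years = c(1961L, 2013L),
                      decade_buckets = default_decade_buckets(years),
                      denitrification_ratio = 0,
                      protein_to_n_default = 0.16,
                      redistribute_excluded = FALSE,
                      seed = NULL) {
  stopifnot(length(years) == 2, years[1] <= years[2])
  if (denitrification_ratio < 0 || denitrification_ratio > 1) {
    stop("denitrification_ratio must lie in [0, 1]", call. = FALSE)
  }
  if (protein_to_n_default <= 0 || protein_to_n_default > 0.25) {
    stop("protein_to_n_default must lie in (0, 0.25]", call. = FALSE)
  }
  covered <- sort(unlist(lapply(decade_buckets, function(b) b[1]:b[2])))
  span <- years[1]:years[2]
  if (!identical(as.integer(covered), as.integer(span))) {
    stop("decade buckets must partition the year range with no overlap",
      call. = FALSE)
  }
  structure(
    list(
      countries = countries,
      years = as.integer(years),
      decade_buckets = decade_buckets,
      denitrification_ratio = denitrification_ratio,
      protein_to_n_default = protein_to_n_default,
      redistribute_excluded = isTRUE(redistribute_excluded),
      seed = seed
    ),
    class = "nf_config"
  )
}

#' @export
print.nf_config <- function(x, ...) {
  cat("<nf_config>\n")
  cat("  countries:", paste(x$countries, collapse = ", "), "\n")
  cat("  years:", x$years[1], "-", x$years[2], "\n")
  cat("  denitrification ratio:", x$denitrification_ratio, "\n")
  cat("  protein-to-N default:", x$protein_to_n_default, "\n")
  invisible(x)
}

#' @rdname nf_config
#' @export
isc_countries <- function() {
  c("Bangladesh", "India", "Pakistan", "Sri Lanka", "Nepal", "Bhutan")
}

#' @rdname nf_config
#' @export
default_decade_buckets <- function(years = c(1961L, 2013L)) {
  first <- (years[1] %/% 10) * 10
  last <- (years[2] %/% 10) * 10
  buckets <- lapply(seq(first, last, by = 10), function(d) {
    c(max(d, years[1]), min(d + 9, years[2]))
  })
  names(buckets) <- paste0(seq(first, last, by = 10), "s")
  buckets
}

#' Assign a year to its decade bucket
#'
#' @param year Integer year(s) within the configured range.
#' @param config An [nf_config()].
#' @return Character vector of decade labels, e.g. `"1960s"`.
#' @export
assign_decade <- function(year, config = nf_config()) {
  if (any(year < config$years[1] | year > config$years[2])) {
    stop("year outside configured range ", config$years[1], "-",
      config$years[2], call. = FALSE)
  }
  labels <- names(config$decade_buckets)
  out <- rep(NA_character_, length(year))
  for (lab in labels) {
    b <- config$decade_buckets[[lab]]
    out[year >= b[1] & year <= b[2]] <- lab
  }
  out
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror the arguments of [nf_config()]; absent keys take
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `nf_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(
    names(raw),
    c("countries", "years", "denitrification_ratio", "protein_to_n_default",
      "redistribute_excluded", "seed")
  )]
  if (!is.null(args$years)) args$years <- as.integer(unlist(args$years))
  if (!is.null(raw$decade_buckets)) {
    args$decade_buckets <- lapply(raw$decade_buckets, function(b) {
      as.integer(unlist(b))
    })
  }
  do.call(nf_config, args)
}
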