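# Small in-code fixtures and independent oracles shared across tests.

# A tiny valid supply table: n countries x (2 items per chosen category),
# one year, deterministic values.
tiny_supply <- function(countries = c("A", "B"),
                        categories = food_categories(),
                        year = 2000L, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(country = countries, category = categories,
    item = 1:1, stringsAsFactors = FALSE)
  tibble::tibble(
    country = grid$country,
    year = year,
    item_id = paste0(gsub(" ", "_", grid$category), "_", grid$item),
    category = grid$category,
    protein_supply = round(runif(nrow(grid), 0.5, 20), 3),
    food_waste = round(runif(nrow(grid), 0, 0.3), 3),
    self_sufficiency = round(runif(nrow(grid), 0.5, 1), 3)
  )
}

# A matching VNF table with positive factors.
tiny_vnf <- function(supply, seed = 2) {
  set.seed(seed)
  v <- unique(supply[c("country", "category", "year")])
  v$trade_vnf <- round(runif(nrow(v), 1, 8), 3)
  tibble::as_tibble(v)
}

# Religion weights: random positive vector normalized per country.
tiny_weights <- function(countries = c("A", "B"), seed = 3) {
  set.seed(seed)
  rows <- lapply(countries, function(co) {
    w <- runif(5, 0.1, 1)
    tibble::tibble(country = co, religion = religions(), weight = w / sum(w))
  })
  dplyr::bind_rows(rows)
}

# Independent triple-loop footprint oracle: plain loops over items,
# communities and countries, no joins, no pipeline calls.
oracle_footprint <- function(supply, vnf, weights, denit = 0,
                             protein_to_n = 0.16) {
  if (!"protein_to_n" %in% names(supply)) {
    supply$protein_to_n <- protein_to_n
  }
  out <- list()
  for (co in unique(supply$country)) {
    for (yr in unique(supply$year[supply$country == co])) {
      tot_p <- 0
      tot_c <- 0
      for (rel in religions()) {
        p <- 0
        q <- 0
        for (i in seq_len(nrow(supply))) {
          r <- supply[i, ]
          if (r$country != co || r$year != yr) next
          if (!(r$category %in% religion_profiles()[[rel]])) next
          v <- vnf$trade_vnf[vnf$country == co & vnf$year == yr &
            vnf$category == r$category]
          intake <- r$protein_supply * 365 / 1000 * r$protein_to_n *
            (1 - r$food_waste)
          p <- p + intake * v
          q <- q + intake * (1 - denit)
        }
        wr <- weights$weight[weights$country == co &
          weights$religion == rel]
        out[[length(out) + 1]] <- tibble::tibble(country = co, year = yr,
          religion = rel, production_nf = p, consumption_nf = q,
          total_nf = p + q)
        tot_p <- tot_p + wr * p
        tot_c <- tot_c + wr * q
      }
      out[[length(out) + 1]] <- tibble::tibble(country = co, year = yr,
        religion = "all", production_nf = tot_p, consumption_nf = tot_c,
        total_nf = tot_p + tot_c)
    }
  }
  dplyr::bind_rows(out)
}

# Baseline input list of a generated world, as the scenario stage expects.
world_baseline <- function(w) {
  list(supply = w$supply, budgets = w$budgets, components = w$components,
    weights = w$weights)
}
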