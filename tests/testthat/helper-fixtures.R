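# shared fixtures and the independent brute-force oracle

# naive record-by-record, factor-by-factor summation; deliberately loop-based
# and separate from the engine's merge/tapply path
oracle_footprint <- function(ledger, table) {
  fp <- attr(table, "footprint")
  gwp <- attr(table, "gwp")
  out_unit <- switch(fp, GHG = "t", N = "t", P = "kg", W = "m3")
  p_cats <- c("food", "fertilizer", "wastewater")
  total <- 0
  by_cat <- setNames(numeric(length(footprint_categories())),
                     footprint_categories())
  for (i in seq_len(nrow(ledger))) {
    r <- as.data.frame(ledger)[i, ]
    if (fp == "P" && !(r$category %in% p_cats)) next
    for (j in seq_len(nrow(table))) {
      f <- as.data.frame(table)[j, ]
      if (f$category == r$category && f$item == r$item) {
        q <- convert_unit(r$quantity, r$unit, f$per_unit)
        contrib <- convert_unit(q * f$value, f$numerator_unit, out_unit)
        if (fp == "GHG" && f$pollutant_form %in% names(gwp))
          contrib <- contrib * gwp[[f$pollutant_form]]
        total <- total + contrib
        by_cat[[r$category]] <- by_cat[[r$category]] + contrib
      }
    }
  }
  list(total = total, by_category = by_cat)
}

# random ledger over the synthetic campus item space (categories, items and
# units stay valid; quantities are random)
random_ledger <- function(n, qmax = 1e6) {
  base <- as.data.frame(generate_campus_ledger(seed = 1)$ledger)
  rows <- base[sample(nrow(base), n, replace = TRUE), ]
  rows$quantity <- runif(n, 0, qmax)
  activity_ledger(rows, label = "random", year = 2016)
}

campus_tables <- function() generate_campus_ledger(seed = 1)$tables

# one-record electricity ledger + one-factor GHG table used across tests
tiny_ledger <- function(quantity = 2, unit = "kWh") {
  activity_ledger(data.frame(category = "purchased_electricity",
                             item = "grid electricity",
                             quantity = quantity, unit = unit),
                  label = "tiny", year = 2016)
}

tiny_ghg_table <- function(value = 3, per_unit = "kWh", form = "CO2") {
  factor_table("GHG", data.frame(category = "purchased_electricity",
                                 item = "grid electricity",
                                 pollutant_form = form, value = value,
                                 numerator_unit = "t", per_unit = per_unit))
}
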