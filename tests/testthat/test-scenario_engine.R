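food_state <- function(beef = 100000, chicken = 50000) {
  led <- activity_ledger(data.frame(
    category = "food", item = c("beef", "chicken", "grains"),
    quantity = c(beef, chicken, 200000), unit = "kg"), "food", 2016)
  scenario_state(led, campus_tables())
}

ledger_mass_kg <- function(ledger, category = "food") {
  df <- as.data.frame(ledger)
  df <- df[df$category == category, ]
  sum(convert_unit(df$quantity, df$unit, "kg"))
}

test_that("the default catalog has 29 strategies with the right plan flags", {
  cat29 <- default_strategy_catalog()
  expect_length(cat29, 29L)
  ids <- vapply(cat29, `[[`, integer(1), "id")
  expect_identical(ids, 1:29)
  in_nap <- vapply(cat29, `[[`, logical(1), "in_nap")
  in_ghgap <- vapply(cat29, `[[`, logical(1), "in_ghgap")
  expect_true(all(in_nap))
  expect_true(all(in_ghgap[1:16]))
  expect_false(any(in_ghgap[17:29]))
})

test_that("catalogs round-trip through YAML and empty configs give empty catalogs", {
  p <- withr::local_tempfile(fileext = ".yaml")
  save_strategy_catalog(default_strategy_catalog(), p)
  cat2 <- build_strategy_catalog(p)
  expect_length(cat2, 29L)
  expect_identical(vapply(cat2, `[[`, character(1), "kind"),
                   vapply(default_strategy_catalog(), `[[`, character(1), "kind"))
  expect_equal(cat2[[22]]$params$fraction, 0.20)

  pe <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(strategies = list()), pe)
  expect_length(build_strategy_catalog(pe), 0L)

  pb <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(strategies = list(list(id = 7, name = "bad",
                                               kind = "no_such_kind"))), pb)
  expect_error(build_strategy_catalog(pb), "malformed strategy entry \\(id 7\\)")
})

test_that("strategy parameter invariants are enforced", {
  expect_error(strategy(1, "x", "efficiency", list(fraction = 1.2)),
               "\\[0, 1\\]")
  expect_error(strategy(1, "x", "food_substitution",
                        list(from_item = "beef", fraction = 0.1,
                             to_items = c("a", "b"), weights = c(0.7, 0.6))),
               "sum to 1")
})

test_that("food substitution moves mass and conserves the total", {
  st <- food_state(beef = 100000)
  s <- strategy(22, "beef to chicken", "food_substitution",
                list(from_item = "beef", fraction = 0.2,
                     to_items = "chicken", weights = 1))
  before <- ledger_mass_kg(st$ledger)
  st2 <- apply_strategy(st, s)
  df <- as.data.frame(st2$ledger)
  expect_equal(df$quantity[df$item == "beef"], 80000)
  expect_equal(df$quantity[df$item == "chicken"], 70000)
  expect_equal(ledger_mass_kg(st2$ledger), before, tolerance = 1e-9)
  expect_identical(st2$applied, 22L)

  # multi-source, multi-destination, destinations not yet in the ledger
  s17 <- strategy(17, "veg meals", "food_substitution",
                  list(from_item = c("beef", "chicken"), fraction = 0.15,
                       to_items = c("legumes", "vegetables"),
                       weights = c(0.6, 0.4)))
  st3 <- apply_strategy(food_state(), s17)
  expect_equal(ledger_mass_kg(st3$ledger), ledger_mass_kg(food_state()$ledger),
               tolerance = 1e-9)
  df3 <- as.data.frame(st3$ledger)
  moved <- 0.15 * (100000 + 50000)
  expect_equal(df3$quantity[df3$item == "legumes"], moved * 0.6)
})

test_that("zero-fraction strategies are identities", {
  st <- food_state()
  for (kind in c("efficiency", "food_substitution", "fuel_switch",
                 "sourcing_factor_change")) {
    params <- switch(kind,
      efficiency = list(category = "food", fraction = 0),
      food_substitution = list(from_item = "beef", fraction = 0,
                               to_items = "chicken", weights = 1),
      fuel_switch = list(from_item = "coal", to_item = "natural gas",
                         fraction = 0),
      sourcing_factor_change = list(category = "food", fraction = 0))
    st2 <- apply_strategy(st, strategy(1, kind, kind, params))
    expect_equal(as.data.frame(st2$ledger), as.data.frame(st$ledger))
    expect_equal(as.data.frame(st2$tables$N), as.data.frame(st$tables$N))
  }
})

test_that("a full fuel switch zeroes the source and adds the energy equivalent", {
  led <- activity_ledger(data.frame(category = "stationary_fuels",
                                    item = c("coal", "natural gas"),
                                    quantity = c(1000, 5000),
                                    unit = c("t", "MMBtu")), "fuels", 2016)
  st <- scenario_state(led, campus_tables())
  s <- strategy(1, "fuel optimization", "fuel_switch",
                list(from_item = "coal", to_item = "natural gas",
                     fraction = 1.0))
  st2 <- apply_strategy(st, s)
  df <- as.data.frame(st2$ledger)
  fe <- fuel_energy_defaults()
  mj_moved <- 1000 * fe$mj_per_unit[fe$item == "coal"]
  expect_equal(df$quantity[df$item == "coal"], 0)
  expect_equal(df$quantity[df$item == "natural gas"],
               5000 + mj_moved / fe$mj_per_unit[fe$item == "natural gas"])
  # delivered heat preserved
  mj <- function(d) sum(d$quantity * fe$mj_per_unit[match(d$item, fe$item)] *
                          convert_unit(1, d$unit, fe$unit[match(d$item, fe$item)]))
  expect_equal(mj(df), mj(as.data.frame(led)), tolerance = 1e-9)
})

test_that("strategies targeting absent items warn and leave the state unchanged", {
  st <- food_state()
  s <- strategy(2, "ghost", "food_substitution",
                list(from_item = "ostrich", fraction = 0.5,
                     to_items = "chicken", weights = 1))
  expect_warning(st2 <- apply_strategy(st, s), "no-op")
  expect_equal(as.data.frame(st2$ledger), as.data.frame(st$ledger))
})

test_that("renewable offsets floor purchased electricity at zero", {
  st <- scenario_state(tiny_ledger(100), campus_tables())
  s_small <- strategy(6, "solar", "renewable_offset",
                      list(amount = 40, unit = "kWh"))
  st2 <- apply_strategy(st, s_small)
  expect_equal(as.data.frame(st2$ledger)$quantity, 60)
  s_big <- strategy(7, "huge solar", "renewable_offset",
                    list(amount = 1e9, unit = "kWh"))
  expect_warning(st3 <- apply_strategy(st, s_big), "floored at 0")
  expect_equal(as.data.frame(st3$ledger)$quantity, 0)
})

test_that("factor-change strategies scale factors, not quantities", {
  st <- scenario_state(tiny_ledger(1000), campus_tables())
  before <- compute_footprint(st$ledger, st$tables$GHG, warn_missing = FALSE)
  s <- strategy(5, "grid improvements", "grid_factor_change",
                list(category = "purchased_electricity", fraction = 0.30))
  st2 <- apply_strategy(st, s)
  expect_equal(as.data.frame(st2$ledger)$quantity, 1000)
  after <- compute_footprint(st2$ledger, st2$tables$GHG, warn_missing = FALSE)
  expect_equal(after$total, before$total * 0.70, tolerance = 1e-12)
})

test_that("disjoint-category strategies commute exactly", {
  led <- generate_campus_ledger(seed = 9)$ledger
  st <- scenario_state(led, campus_tables())
  s_food <- strategy(22, "beef to chicken", "food_substitution",
                     list(from_item = "beef", fraction = 0.2,
                          to_items = "chicken", weights = 1))
  s_commute <- strategy(15, "outreach", "behavior_reduction",
                        list(category = "commuting", fraction = 0.03))
  ab <- apply_strategy(apply_strategy(st, s_food), s_commute)
  ba <- apply_strategy(apply_strategy(st, s_commute), s_food)
  expect_identical(as.data.frame(ab$ledger)[order(as.data.frame(ab$ledger)$item), ],
                   as.data.frame(ba$ledger)[order(as.data.frame(ba$ledger)$item), ])
})

test_that("composition applies in id order, rejects duplicates, and matches stepping by hand", {
  b <- generate_campus_ledger(seed = 42)
  st0 <- scenario_state(project_bau(b$ledger, b$drivers, 2025), b$tables)
  catalog <- default_strategy_catalog()
  expect_error(compose_strategies(st0, catalog[c(1, 1, 2)]),
               "duplicate strategy id")
  expect_identical(compose_strategies(st0, list())$applied, integer())

  shuffled <- catalog[sample(29)]
  composed <- compose_strategies(st0, shuffled)
  stepped <- st0
  for (s in catalog) stepped <- apply_strategy(stepped, s)
  expect_identical(composed$applied, 1:29)
  expect_equal(as.data.frame(composed$ledger), as.data.frame(stepped$ledger))
  expect_equal(footprint_totals(compute_integrated(composed$ledger,
                                                   composed$tables,
                                                   warn_missing = FALSE)),
               footprint_totals(compute_integrated(stepped$ledger,
                                                   stepped$tables,
                                                   warn_missing = FALSE)),
               tolerance = 1e-12)
})

test_that("no action-plan strategy increases any footprint on the synthetic campus", {
  b <- generate_campus_ledger(seed = 42)
  bau <- project_bau(b$ledger, b$drivers, 2025)
  bau_tot <- footprint_totals(compute_integrated(bau, b$tables,
                                                 warn_missing = FALSE))
  st <- compose_strategies(scenario_state(bau, b$tables),
                           default_strategy_catalog())
  all_tot <- footprint_totals(compute_integrated(st$ledger, st$tables,
                                                 warn_missing = FALSE))
  expect_true(all(all_tot <= bau_tot + 1e-9))
  expect_true(all(as.data.frame(st$ledger)$quantity >= 0))
})

test_that("run_portfolio produces the reference rows and self-consistent percents", {
  b <- generate_campus_ledger(seed = 42)
  catalog <- default_strategy_catalog()

  empty <- run_portfolio(b$ledger, b$drivers, catalog, list(), b$tables,
                         warn_missing = FALSE)
  expect_identical(nrow(empty), 2L)
  expect_identical(empty$scenario, c("baseline 2016", "BAU 2025"))
  expect_equal(empty$GHG_pct[2], 0)

  port <- run_portfolio(b$ledger, b$drivers, catalog,
                        list(beef_chicken = 22L), b$tables,
                        warn_missing = FALSE)
  # recompute through the engine directly
  bau <- project_bau(b$ledger, b$drivers, 2025)
  st <- compose_strategies(scenario_state(bau, b$tables),
                           catalog_subset(catalog, 22L))
  direct <- footprint_totals(compute_integrated(st$ledger, st$tables,
                                                warn_missing = FALSE))
  bau_tot <- footprint_totals(compute_integrated(bau, b$tables,
                                                 warn_missing = FALSE))
  expect_equal(unlist(port[3, c("GHG", "N", "P", "W")]),
               direct, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unlist(port[3, c("GHG_pct", "N_pct", "P_pct", "W_pct")]),
               percent_change(bau_tot, direct), ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_error(catalog_subset(catalog, c(3L, 99L)), "unknown strategy id")
})
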