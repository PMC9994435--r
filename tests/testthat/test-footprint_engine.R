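test_that("the engine multiplies activity by factor and normalises units", {
  # 2 kWh x 3 t CO2 per kWh = 6 t CO2e
  res <- compute_footprint(tiny_ledger(2), tiny_ghg_table(3))
  expect_equal(res$total, 6)
  expect_equal(unname(res$by_category[["purchased_electricity"]]), 6)
  expect_equal(unname(res$by_form[["CO2"]]), 6)

  # activity unit converted to the factor's per-unit basis: 1 MWh = 1000 kWh
  res <- compute_footprint(tiny_ledger(1, unit = "MWh"), tiny_ghg_table(3))
  expect_equal(res$total, 3000)

  # 1 t CH4 becomes gwp[CH4] t CO2e
  led <- activity_ledger(data.frame(category = "wastewater",
                                    item = "treated wastewater",
                                    quantity = 1, unit = "m3"), "g", 2016)
  tab <- factor_table("GHG", data.frame(category = "wastewater",
                                        item = "treated wastewater",
                                        pollutant_form = "CH4", value = 1,
                                        numerator_unit = "t", per_unit = "m3"),
                      gwp = c(CH4 = 28, N2O = 265))
  expect_equal(compute_footprint(led, tab)$total, 28)
})

test_that("an empty ledger gives exactly zero everywhere", {
  led <- activity_ledger(NULL, "empty", 2016)
  for (tab in campus_tables()) {
    res <- compute_footprint(led, tab)
    expect_identical(res$total, 0)
    expect_true(all(res$by_category == 0))
    expect_true(all(res$by_form == 0))
  }
  fp <- compute_integrated(led, campus_tables())
  expect_identical(unname(footprint_totals(fp)), c(0, 0, 0, 0))
})

test_that("engine totals and breakdowns match the brute-force oracle", {
  led <- generate_campus_ledger(seed = 42)$ledger
  for (tab in campus_tables()) {
    res <- compute_footprint(led, tab, warn_missing = FALSE)
    orc <- oracle_footprint(led, tab)
    expect_equal(res$total, orc$total, tolerance = 1e-12)
    expect_equal(res$by_category, orc$by_category, tolerance = 1e-12)
    expect_equal(sum(res$by_category), res$total, tolerance = 1e-9)
    expect_equal(sum(res$by_form), res$total, tolerance = 1e-9)
  }
})

test_that("the engine is linear, additive and monotone", {
  set.seed(7)
  tabs <- campus_tables()
  for (rep in 1:25) {
    led <- random_ledger(sample(1:40, 1))
    tab <- tabs[[sample(4, 1)]]
    a <- runif(1, 0, 5)
    scaled <- activity_ledger(within(as.data.frame(led),
                                     quantity <- quantity * a), "s", 2016)
    expect_equal(compute_footprint(scaled, tab, warn_missing = FALSE)$total,
                 a * compute_footprint(led, tab, warn_missing = FALSE)$total,
                 tolerance = 1e-9)

    led2 <- random_ledger(sample(1:40, 1))
    both <- activity_ledger(rbind(as.data.frame(led), as.data.frame(led2)),
                            "cat", 2016)
    expect_equal(compute_footprint(both, tab, warn_missing = FALSE)$total,
                 compute_footprint(led, tab, warn_missing = FALSE)$total +
                   compute_footprint(led2, tab, warn_missing = FALSE)$total,
                 tolerance = 1e-9)

    df <- as.data.frame(led)
    i <- sample(nrow(df), 1)
    df$quantity[i] <- df$quantity[i] * runif(1)
    less <- activity_ledger(df, "less", 2016)
    expect_lte(compute_footprint(less, tab, warn_missing = FALSE)$total,
               compute_footprint(led, tab, warn_missing = FALSE)$total + 1e-9)
  }
})

test_that("the P footprint excludes combustion and energy categories", {
  led <- activity_ledger(data.frame(
    category = c("stationary_fuels", "purchased_electricity"),
    item = c("coal", "grid electricity"),
    quantity = c(1000, 1e6), unit = c("t", "kWh")), "energy only", 2016)
  fp <- compute_integrated(led, campus_tables(), warn_missing = FALSE)
  expect_identical(fp$p_total, 0)
  expect_gt(fp$ghg_total, 0)
  # water contribution only through the energy water factors
  expect_equal(fp$w_total,
               unname(fp$by_category$W[["stationary_fuels"]] +
                        fp$by_category$W[["purchased_electricity"]]))
})

test_that("compute_integrated requires exactly one table per footprint", {
  led <- tiny_ledger()
  tabs <- campus_tables()
  expect_error(compute_integrated(led, tabs[c("GHG", "N", "P")]),
               "exactly one factor table")
  expect_error(compute_integrated(led, tabs[c("GHG", "GHG", "N", "P")]),
               "exactly one factor table")
})

test_that("missing factors contribute zero with a consolidated warning", {
  led <- activity_ledger(data.frame(category = c("food", "food"),
                                    item = c("beef", "dragonfruit"),
                                    quantity = c(1, 1), unit = "kg"),
                         "m", 2016)
  tab <- campus_tables()$N
  expect_warning(res <- compute_footprint(led, tab), "dragonfruit")
  expect_equal(res$total,
               compute_footprint(activity_ledger(
                 data.frame(category = "food", item = "beef", quantity = 1,
                            unit = "kg"), "b", 2016), tab,
                 warn_missing = FALSE)$total)
})

test_that("percent change follows the signed reduction convention", {
  expect_equal(percent_change(100, 62), -38)
  expect_equal(percent_change(57.3, 57.3), 0)
  expect_error(percent_change(0, 5), "zero baseline")
  set.seed(11)
  b <- runif(50, 1, 1e6); x <- runif(50, 0, 1e6)
  expect_equal(percent_change(b, x), (x - b) / b * 100)
})

test_that("category aggregation reports the full vocabulary and sums to the total", {
  res <- compute_footprint(tiny_ledger(5), tiny_ghg_table(2))
  agg <- aggregate_by_category(res)
  expect_setequal(names(agg$by_category), footprint_categories())
  expect_equal(sum(agg$by_category), agg$total, tolerance = 1e-9)
  expect_equal(unname(agg$by_category[["food"]]), 0)

  led <- generate_campus_ledger(seed = 42)$ledger
  res <- compute_footprint(led, campus_tables()$N, warn_missing = FALSE)
  orc <- oracle_footprint(led, campus_tables()$N)
  expect_equal(aggregate_by_category(res)$by_category, orc$by_category,
               tolerance = 1e-12)
})

test_that("integrated results serialize to the documented JSON layout", {
  fp <- compute_integrated(tiny_ledger(2), campus_tables(),
                           warn_missing = FALSE)
  parsed <- jsonlite::fromJSON(footprint_to_json(fp))
  expect_setequal(names(parsed$footprints), c("GHG", "N", "P", "W"))
  expect_equal(parsed$footprints$GHG$total, fp$ghg_total)
  expect_equal(parsed$footprints$W$by_category$purchased_electricity,
               unname(fp$by_category$W[["purchased_electricity"]]))
})
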