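#' @name damage_costs
#' @title Monetising GHG and reactive-nitrogen releases
#'
#' @description
#' Damage costs attach a marginal dollar value to each unit of pollutant
#' released, assuming a linear response: dollars per metric ton of
#' CO2-equivalent for GHG (the social cost of carbon), and dollars per kg
#' of reactive N by chemical form (NOx, NH3, N2O, NO3, dissolved N),
#' release medium (air, land, surface water, groundwater, coastal) and
#' impacted sector (human health, agriculture, ecosystems, climate).
#' Short-lived NOx/NHy aerosols cool the climate, so the climate sector
#' may carry *negative* unit costs (a benefit). Virtual N embedded in food
#' production is first apportioned into dissolved N, NH3, NOx and N2O
#' before costing. All dollar values are pegged to a common base year with
#' a consumer-price-index series.
#'
#' No damage-cost valuations exist yet for the P and W footprints, so only
#' GHG and N are monetised.
NULL

.damage_forms <- c("NOx_N", "NH3_N", "N2O_N", "NO3_N", "dissolved_N", "CO2e")
.damage_media <- c("air", "land", "surface_water", "groundwater", "coastal")
.damage_sectors <- c("human_health", "agriculture", "ecosystems", "climate")

#' Construct a damage-cost table
#'
#' @param entries data.frame with columns `pollutant_form`, `medium`,
#'   `impact_sector`, `unit_cost` (2016 USD per kg N, signed),
#'   `currency_year`, `provenance`. Negative unit costs are only admitted
#'   for the climate sector (aerosol cooling credits).
#' @return object of class `damage_cost_table`.
#' @export
damage_cost_table <- function(entries) {
  cols <- c("pollutant_form", "medium", "impact_sector", "unit_cost",
            "currency_year", "provenance")
  missing_cols <- setdiff(cols, names(entries))
  if (length(missing_cols))
    stop("damage table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  entries <- entries[cols]
  bad_form <- setdiff(unique(entries$pollutant_form), .damage_forms)
  if (length(bad_form))
    stop("unknown pollutant form(s): ", paste(bad_form, collapse = ", "),
         call. = FALSE)
  bad_med <- setdiff(unique(entries$medium), .damage_media)
  if (length(bad_med))
    stop("unknown medium(s): ", paste(bad_med, collapse = ", "), call. = FALSE)
  bad_sec <- setdiff(unique(entries$impact_sector), .damage_sectors)
  if (length(bad_sec))
    stop("unknown impact sector(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  neg <- entries$unit_cost < 0 & entries$impact_sector != "climate"
  if (any(neg))
    stop("negative unit cost outside the climate sector (row ",
         which(neg)[1L], ")", call. = FALSE)
  rownames(entries) <- NULL
  structure(entries, class = c("damage_cost_table", "data.frame"))
}

#' @export
print.damage_cost_table <- function(x, ...) {
  cat(sprintf("<damage_cost_table> %d entries, %d forms, %d sectors\n",
              nrow(x), length(unique(x$pollutant_form)),
              length(unique(x$impact_sector))))
  invisible(x)
}

#' Read / write a damage-cost table (CSV)
#'
#' Columns: `pollutant_form,medium,impact_sector,unit_cost,currency_year,provenance`.
#'
#' @param path CSV path.
#' @return `damage_cost_table`.
#' @export
load_damage_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  damage_cost_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname load_damage_table
#' @param table `damage_cost_table` to write.
#' @export
save_damage_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Default marginal damage costs for reactive nitrogen
#'
#' Illustrative defaults on the scale reported by regional
#' damage-cost syntheses for the Chesapeake Bay watershed and the US
#' (Birch et al. 2011; Sobota et al. 2015; Compton et al. 2011): air-borne
#' NOx and NH3 dominated by human respiratory health, N2O by climate,
#' hydrologic N by eutrophication/ecosystem damages, and a small negative
#' climate entry for aerosol cooling. Values are 2016 USD per kg N and
#' must be replaced with study-specific tables for site work.
#'
#' @return `damage_cost_table`.
#' @export
default_damage_costs <- function() {
  e <- function(form, medium, sector, cost)
    data.frame(pollutant_form = form, medium = medium, impact_sector = sector,
               unit_cost = cost, currency_year = 2016L,
               provenance = "illustrative default")
  damage_cost_table(rbind(
    e("NOx_N", "air", "human_health", 16),
    e("NOx_N", "air", "agriculture", 2),
    e("NOx_N", "air", "ecosystems", 3),
    e("NOx_N", "air", "climate", -1.5),
    e("NH3_N", "air", "human_health", 25),
    e("NH3_N", "air", "ecosystems", 3),
    e("NH3_N", "air", "climate", -1.0),
    e("N2O_N", "air", "climate", 12),
    e("dissolved_N", "surface_water", "ecosystems", 8),
    e("dissolved_N", "surface_water", "human_health", 2),
    e("dissolved_N", "groundwater", "human_health", 5),
    e("dissolved_N", "coastal", "ecosystems", 10),
    e("NO3_N", "surface_water", "ecosystems", 6),
    e("NO3_N", "groundwater", "human_health", 4)))
}

#' Social-cost-of-carbon valuation of a GHG footprint
#'
#' Multiplies the footprint (metric tons CO2e) by the social cost of
#' carbon. The default SCC is $30 per MTCDE, an intermediate value within
#' the $14-$74 global-scale range of interagency estimates (national-scale
#' estimates run $1-$7).
#'
#' @param ghg_total GHG footprint in metric tons CO2-equivalent.
#' @param scc social cost of carbon, USD per MTCDE (>= 0).
#' @return damage cost in USD.
#' @export
ghg_damage_cost <- function(ghg_total, scc = 30) {
  if (any(scc < 0)) stop("scc must be >= 0", call. = FALSE)
  ghg_total * scc
}

#' Construct a virtual-N apportionment scheme
#'
#' Virtual N embedded in food production is split into dissolved N, NH3,
#' NOx and N2O before damage costing. Fractions must sum to 1. The
#' defaults are illustrative (agricultural N budgets put roughly half of
#' farm-gate losses into the hydrologic pathway and most of the airborne
#' remainder into NH3 volatilisation).
#'
#' @param dissolved_N,NH3_N,NOx_N,N2O_N fractions in [0, 1] summing to 1.
#' @return named numeric vector of class `apportionment_scheme`.
#' @export
apportionment_scheme <- function(dissolved_N = 0.50, NH3_N = 0.30,
                                 NOx_N = 0.10, N2O_N = 0.10) {
  f <- c(dissolved_N = dissolved_N, NH3_N = NH3_N, NOx_N = NOx_N,
         N2O_N = N2O_N)
  if (any(f < 0 | f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("apportionment fractions must lie in [0,1] and sum to 1",
         call. = FALSE)
  structure(f, class = c("apportionment_scheme", "numeric"))
}

#' Apportion virtual food-production N into release forms
#'
#' @param food_n virtual N mass (any consistent unit).
#' @param scheme `apportionment_scheme`.
#' @return named numeric vector over the four forms, summing to `food_n`.
#' @export
apportion_virtual_n <- function(food_n, scheme = apportionment_scheme()) {
  if (!inherits(scheme, "apportionment_scheme"))
    scheme <- do.call(apportionment_scheme, as.list(scheme))
  stats::setNames(food_n * as.numeric(scheme), names(scheme))
}

#' Build the N release profile of a ledger for damage costing
#'
#' Converts an N-footprint computation into a flux table of
#' (source category, pollutant form, release medium, mass in kg N):
#' combustion and transport N goes to air in its ledgered forms
#' (NOx-N, N2O-N); virtual N from food and fertilizer is apportioned into
#' dissolved N, NH3, NOx and N2O, with the dissolved share split across
#' surface water, groundwater and coastal systems by `hydro_split`;
#' wastewater N is released to surface water as dissolved N.
#'
#' @param ledger `activity_ledger`.
#' @param n_table the N `factor_table`.
#' @param scheme `apportionment_scheme` for virtual N.
#' @param hydro_split named fractions over surface_water, groundwater,
#'   coastal (sum 1) for hydrologic N; configuration, not prediction.
#' @param warn_missing see [compute_footprint()].
#' @return data.frame with columns `category`, `pollutant_form`, `medium`,
#'   `mass_kg`.
#' @export
n_release_profile <- function(ledger, n_table,
                              scheme = apportionment_scheme(),
                              hydro_split = c(surface_water = 0.6,
                                              groundwater = 0.25,
                                              coastal = 0.15),
                              warn_missing = FALSE) {
  if (abs(sum(hydro_split) - 1) > 1e-9)
    stop("hydro_split must sum to 1", call. = FALSE)
  fluxes <- list()
  add <- function(category, form, medium, mass_kg) {
    if (mass_kg != 0)
      fluxes[[length(fluxes) + 1L]] <<-
        data.frame(category = category, pollutant_form = form,
                   medium = medium, mass_kg = mass_kg)
  }
  df <- as.data.frame(ledger)
  for (cat in unique(df$category)) {
    sub <- activity_ledger(df[df$category == cat, , drop = FALSE],
                           label = cat, year = attr(ledger, "year"))
    res <- compute_footprint(sub, n_table, warn_missing = warn_missing)
    forms_t <- res$by_form  # metric tons N by ledgered form
    kg <- forms_t * 1000
    if (cat %in% c("food", "fertilizer")) {
      virt <- apportion_virtual_n(sum(kg), scheme)
      for (m in names(hydro_split))
        add(cat, "dissolved_N", m, virt[["dissolved_N"]] * hydro_split[[m]])
      add(cat, "NH3_N", "air", virt[["NH3_N"]])
      add(cat, "NOx_N", "air", virt[["NOx_N"]])
      add(cat, "N2O_N", "air", virt[["N2O_N"]])
    } else if (cat == "wastewater") {
      add(cat, "dissolved_N", "surface_water", sum(kg))
    } else {
      add(cat, "NOx_N", "air", kg[["NOx_N"]])
      add(cat, "N2O_N", "air", kg[["N2O_N"]])
      add(cat, "NOx_N", "air", kg[["other_N"]])  # residual combustion N as NOx
    }
  }
  if (!length(fluxes))
    return(data.frame(category = character(), pollutant_form = character(),
                      medium = character(), mass_kg = numeric()))
  out <- do.call(rbind, fluxes)
  rownames(out) <- NULL
  out
}

#' Cost a nitrogen release profile
#'
#' Total cost is the sum over fluxes and matching table entries of
#' mass x unit cost; a (form, medium) pair with no table entry contributes
#' zero with a warning. The impact-sector rollup can include a negative
#' climate component (aerosol cooling).
#'
#' @param releases data.frame with columns `category`, `pollutant_form`,
#'   `medium`, `mass_kg` (e.g. from [n_release_profile()]).
#' @param table `damage_cost_table`.
#' @param warn_missing warn about fluxes with no cost entry?
#' @return list with `total` (USD), `by_sector` (named over the four
#'   impact sectors), `by_category` (named over source categories present).
#' @export
n_damage_cost <- function(releases, table = default_damage_costs(),
                          warn_missing = TRUE) {
  by_sector <- stats::setNames(numeric(length(.damage_sectors)), .damage_sectors)
  by_category <- stats::setNames(numeric(0), character(0))
  if (nrow(releases)) {
    m <- merge(releases, as.data.frame(table),
               by = c("pollutant_form", "medium"))
    if (warn_missing) {
      have <- unique(paste(table$pollutant_form, table$medium))
      need <- unique(paste(releases$pollutant_form, releases$medium))
      miss <- setdiff(need, have)
      if (length(miss))
        warning("no damage-cost entry for flux(es): ",
                paste(miss, collapse = "; "), "; contributing zero",
                call. = FALSE)
    }
    if (nrow(m)) {
      cost <- m$mass_kg * m$unit_cost
      s <- tapply(cost, m$impact_sector, sum)
      by_sector[names(s)] <- s
      by_category <- tapply(cost, m$category, sum)
      by_category <- stats::setNames(as.numeric(by_category), names(by_category))
    }
  }
  list(total = sum(by_sector), by_sector = by_sector,
       by_category = by_category)
}

#' Construct a consumer-price-index series
#'
#' @param years integer years.
#' @param index positive index values (e.g. CPI-U annual averages).
#' @param base_year currency peg year (default 2016).
#' @return object of class `cpi_series`.
#' @export
cpi_series <- function(years, index, base_year = 2016L) {
  if (length(years) != length(index)) stop("years/index length mismatch",
                                           call. = FALSE)
  if (any(index <= 0)) stop("CPI indices must be > 0", call. = FALSE)
  structure(list(index = stats::setNames(as.numeric(index),
                                         as.character(as.integer(years))),
                 base_year = as.integer(base_year)),
            class = "cpi_series")
}

#' The bundled US CPI-U annual-average series (2000-2020)
#'
#' @param base_year peg year, default 2016.
#' @return `cpi_series`.
#' @export
default_cpi <- function(base_year = 2016L) {
  path <- system.file("extdata", "cpi_us_annual.csv", package = "campusfp")
  df <- utils::read.csv(path)
  cpi_series(df$year, df$index, base_year = base_year)
}

#' Adjust a dollar amount between years with a CPI series
#'
#' `amount * cpi[to_year] / cpi[from_year]`; path-independent by
#' construction.
#'
#' @param amount dollar amount.
#' @param from_year,to_year years present in the series.
#' @param cpi `cpi_series`.
#' @return adjusted amount.
#' @export
adjust_for_inflation <- function(amount, from_year, to_year,
                                 cpi = default_cpi()) {
  i <- cpi$index[as.character(as.integer(from_year))]
  j <- cpi$index[as.character(as.integer(to_year))]
  if (anyNA(c(i, j)))
    stop("year(s) absent from CPI series: ",
         paste(c(from_year, to_year)[is.na(c(i, j))], collapse = ", "),
         call. = FALSE)
  amount * unname(j) / unname(i)
}

#' Health-cost savings from a NOx emission reduction
#'
#' Monetary savings = (BAU NOx emissions - scenario NOx emissions) x the
#' marginal damage per ton of NOx, evaluated separately for the ozone and
#' fine-particulate (PM2.5) formation pathways. Negative savings mean
#' emissions rose. Default unit costs are illustrative values on the
#' scale of regional health-damage estimates and must be overridden for
#' site-specific work.
#'
#' @param nox_bau,nox_scenario NOx emissions (tons) under BAU and under
#'   the scenario; both >= 0.
#' @param cost_ozone,cost_pm25 damage per ton of NOx via each pathway
#'   (USD/ton).
#' @return list with `ozone_savings`, `pm25_savings`, `total` (USD).
#' @export
nox_health_savings <- function(nox_bau, nox_scenario,
                               cost_ozone = 5000, cost_pm25 = 8600) {
  if (any(c(nox_bau, nox_scenario) < 0))
    stop("NOx emissions must be >= 0", call. = FALSE)
  delta <- nox_bau - nox_scenario
  oz <- delta * cost_ozone
  pm <- delta * cost_pm25
  list(ozone_savings = oz, pm25_savings = pm, total = oz + pm)
}
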