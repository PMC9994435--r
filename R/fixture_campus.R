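#' @name fixture_campus
#' @title Synthetic campus generator and supplementary-bundle loader
#'
#' @description
#' Generates a complete, internally consistent synthetic campus: an
#' activity ledger over all ten categories, the four emission-factor
#' tables, a damage-cost table and growth drivers. Magnitudes are loosely
#' calibrated to a mid-size university (order 1e5 t CO2e GHG, order 1e2
#' t N) and the factor ordering mirrors the field's structural facts:
#' per-kg GHG, N, P and water factors for beef exceed chicken's, which
#' exceed plant staples'; the food category carries at least half of the
#' reactive-N footprint, as typically reported for institutions; natural
#' gas emits less CO2 and NOx per MJ than coal, so a coal-to-gas fuel
#' switch reduces both GHG and N. The generator is deterministic in its
#' seed (only activity quantities are jittered; factors are fixed), and
#' does not attempt to reproduce any specific institution's numbers.
NULL

.campus_generator_id <- "campus-gen-1"

.base_quantities <- function() {
  rbind(
    data.frame(category = "purchased_electricity", item = "grid electricity",
               quantity = 2.5e8, unit = "kWh"),
    data.frame(category = "stationary_fuels",
               item = c("coal", "natural gas", "fuel oil"),
               quantity = c(2.5e4, 6.0e5, 1.0e5),
               unit = c("t", "MMBtu", "gallon")),
    data.frame(category = "direct_transportation",
               item = c("gasoline", "diesel"),
               quantity = c(2.5e5, 1.5e5), unit = "gallon"),
    data.frame(category = "commuting", item = "commuter miles",
               quantity = 6.0e7, unit = "mile"),
    data.frame(category = "food",
               item = c("beef", "chicken", "pork", "fish", "dairy", "eggs",
                        "grains", "vegetables", "fruits", "legumes"),
               quantity = c(4.5e5, 7.0e5, 2.5e5, 1.5e5, 1.2e6, 3.0e5,
                            1.5e6, 1.8e6, 9.0e5, 2.0e5),
               unit = "kg"),
    data.frame(category = "fertilizer",
               item = c("synthetic N fertilizer", "P fertilizer"),
               quantity = c(5.0e4, 1.5e4), unit = "kg"),
    data.frame(category = "animals", item = "livestock",
               quantity = 5.0e3, unit = "head"),
    data.frame(category = "refrigerants_chemicals", item = "refrigerant R-134a",
               quantity = 5.0e2, unit = "kg"),
    data.frame(category = "wastewater", item = "treated wastewater",
               quantity = 1.2e6, unit = "m3"),
    data.frame(category = "direct_water", item = "potable water",
               quantity = 2.0e6, unit = "m3"))
}

.campus_factors <- function() {
  f <- function(category, item, form, value, num, per)
    data.frame(category = category, item = item, pollutant_form = form,
               value = value, numerator_unit = num, per_unit = per)
  food <- c("beef", "chicken", "pork", "fish", "dairy", "eggs",
            "grains", "vegetables", "fruits", "legumes")
  ghg <- rbind(
    f("purchased_electricity", "grid electricity", "CO2", 4.5e-4, "t", "kWh"),
    f("purchased_electricity", "grid electricity", "CH4", 1.0e-8, "t", "kWh"),
    f("purchased_electricity", "grid electricity", "N2O", 7.0e-9, "t", "kWh"),
    f("stationary_fuels", "coal", "CO2", 2.5, "t", "t"),
    f("stationary_fuels", "coal", "CH4", 3.0e-4, "t", "t"),
    f("stationary_fuels", "coal", "N2O", 4.0e-5, "t", "t"),
    f("stationary_fuels", "natural gas", "CO2", 5.3e-2, "t", "MMBtu"),
    f("stationary_fuels", "natural gas", "CH4", 1.0e-6, "t", "MMBtu"),
    f("stationary_fuels", "natural gas", "N2O", 1.0e-7, "t", "MMBtu"),
    f("stationary_fuels", "fuel oil", "CO2", 1.0e-2, "t", "gallon"),
    f("direct_transportation", "gasoline", "CO2", 8.9e-3, "t", "gallon"),
    f("direct_transportation", "diesel", "CO2", 1.02e-2, "t", "gallon"),
    f("commuting", "commuter miles", "CO2", 4.04e-4, "t", "mile"),
    f("food", food, "CO2",
      c(3.0e-2, 6.9e-3, 1.2e-2, 6.0e-3, 1.9e-3, 4.5e-3,
        1.4e-3, 2.0e-3, 1.1e-3, 9.0e-4), "t", "kg"),
    f("fertilizer", "synthetic N fertilizer", "N2O", 1.57e-5, "t", "kg"),
    f("animals", "livestock", "CH4", 5.0e-4, "t", "head"),
    f("refrigerants_chemicals", "refrigerant R-134a", "refrigerant_CO2e",
      1.3, "t", "kg"),
    f("wastewater", "treated wastewater", "CH4", 3.0e-5, "t", "m3"))
  n <- rbind(
    f("purchased_electricity", "grid electricity", "NOx_N", 2.3e-7, "t", "kWh"),
    f("stationary_fuels", "coal", "NOx_N", 4.0e-3, "t", "t"),
    f("stationary_fuels", "natural gas", "NOx_N", 4.5e-5, "t", "MMBtu"),
    f("stationary_fuels", "fuel oil", "NOx_N", 1.0e-5, "t", "gallon"),
    f("direct_transportation", "gasoline", "NOx_N", 4.0e-6, "t", "gallon"),
    f("direct_transportation", "diesel", "NOx_N", 1.0e-5, "t", "gallon"),
    f("commuting", "commuter miles", "NOx_N", 5.0e-8, "t", "mile"),
    f("food", food, "other_N",
      c(2.5e-4, 8.0e-5, 1.2e-4, 9.0e-5, 2.0e-5, 5.0e-5,
        1.0e-5, 8.0e-6, 6.0e-6, 7.0e-6), "t", "kg"),
    f("fertilizer", "synthetic N fertilizer", "other_N", 4.0e-4, "t", "kg"),
    f("wastewater", "treated wastewater", "other_N", 4.0e-6, "t", "m3"))
  p <- rbind(
    f("food", food, "P",
      c(6.0e-3, 3.0e-3, 4.0e-3, 3.0e-3, 1.0e-3, 2.0e-3,
        8.0e-4, 5.0e-4, 3.0e-4, 1.0e-3), "kg", "kg"),
    f("fertilizer", "P fertilizer", "P", 0.9, "kg", "kg"),
    f("wastewater", "treated wastewater", "P", 1.0e-3, "kg", "m3"))
  w <- rbind(
    f("purchased_electricity", "grid electricity", "blue_water",
      1.9e-3, "m3", "kWh"),
    f("stationary_fuels", "coal", "blue_water", 1.0, "m3", "t"),
    f("stationary_fuels", "natural gas", "blue_water", 1.0e-2, "m3", "MMBtu"),
    f("direct_transportation", "gasoline", "blue_water", 1.0e-2, "m3", "gallon"),
    f("direct_transportation", "diesel", "blue_water", 1.0e-2, "m3", "gallon"),
    f("food", food, "blue_water",
      c(0.60, 0.30, 0.50, 0.10, 0.10, 0.20, 0.15, 0.10, 0.20, 0.30),
      "m3", "kg"),
    f("food", food, "green_water",
      c(14.4, 4.0, 5.5, 0.50, 0.90, 3.1, 1.5, 0.20, 0.70, 3.7),
      "m3", "kg"),
    f("wastewater", "treated wastewater", "blue_water", 5.0e-2, "m3", "m3"),
    f("direct_water", "potable water", "direct_water", 1.0, "m3", "m3"))
  list(GHG = factor_table("GHG", ghg, provenance = "synthetic campus-gen-1"),
       N = factor_table("N", n, provenance = "synthetic campus-gen-1"),
       P = factor_table("P", p, provenance = "synthetic campus-gen-1"),
       W = factor_table("W", w, provenance = "synthetic campus-gen-1"))
}

#' Generate a synthetic campus bundle
#'
#' @param seed integer seed; the same seed always yields the same bundle.
#' @param scale nonnegative scalar on all activity quantities; `scale = 0`
#'   gives an empty (zero-footprint) campus.
#' @param year ledger year (default 2016).
#' @return object of class `campus_bundle`: list with `ledger`
#'   (`activity_ledger`), `tables` (four `factor_table`s), `damage_table`,
#'   `drivers` (`growth_drivers`), and `meta` (generator id, seed, scale).
#' @examples
#' b <- generate_campus_ledger(seed = 42)
#' fp <- compute_integrated(b$ledger, b$tables)
#' @export
generate_campus_ledger <- function(seed = 42L, scale = 1, year = 2016L) {
  if (scale < 0) stop("scale must be >= 0", call. = FALSE)
  base <- .base_quantities()
  set.seed(as.integer(seed))
  jitter <- stats::runif(nrow(base), 0.9, 1.1)
  base$quantity <- base$quantity * jitter * scale
  if (scale == 0) base <- base[0, , drop = FALSE]
  ledger <- activity_ledger(base, label = sprintf("synthetic campus (seed %d)", seed),
                            year = year)
  structure(list(
    ledger = ledger,
    tables = .campus_factors(),
    damage_table = default_damage_costs(),
    drivers = growth_drivers(population_mult = 1.12, gsf_mult = 1.20,
                             food_mult = 1.18),
    meta = list(generator = .campus_generator_id, seed = as.integer(seed),
                scale = scale, year = as.integer(year))),
    class = "campus_bundle")
}

#' @export
print.campus_bundle <- function(x, ...) {
  cat(sprintf("<campus_bundle> %s seed %d scale %g: %d ledger records\n",
              x$meta$generator, x$meta$seed, x$meta$scale, nrow(x$ledger)))
  invisible(x)
}

.bundle_files <- c(ledger = "ledger.csv",
                   GHG = "factors_GHG.csv", N = "factors_N.csv",
                   P = "factors_P.csv", W = "factors_W.csv",
                   damage = "damage_costs.csv", drivers = "drivers.yaml")

#' Export a campus bundle to a directory of plain-text tables
#'
#' Writes `ledger.csv`, `factors_{GHG,N,P,W}.csv` (each with a YAML
#' sidecar), `damage_costs.csv`, `drivers.yaml` and `meta.yaml` — the same
#' layout [load_supplementary_tables()] reads.
#'
#' @param bundle `campus_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_ledger(bundle$ledger, file.path(dir, .bundle_files[["ledger"]]))
  for (fp in c("GHG", "N", "P", "W"))
    save_factor_table(bundle$tables[[fp]], file.path(dir, .bundle_files[[fp]]))
  save_damage_table(bundle$damage_table, file.path(dir, .bundle_files[["damage"]]))
  save_drivers(bundle$drivers, file.path(dir, .bundle_files[["drivers"]]))
  meta <- bundle$meta
  meta$label <- attr(bundle$ledger, "label")
  meta$year <- attr(bundle$ledger, "year")
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load a supplementary-data bundle from a directory
#'
#' Reads an institution's exported tables in the documented layout
#' (`ledger.csv`, `factors_GHG.csv` ... `factors_W.csv`,
#' `damage_costs.csv`, `drivers.yaml`, optional `meta.yaml`), validates
#' everything through the data-model validators, and returns the same
#' bundle structure as [generate_campus_ledger()]. Use this to run the
#' pipeline on real campus data instead of the synthetic fixture.
#'
#' @param dir directory containing the bundle.
#' @param year ledger year expected (default: `meta.yaml`'s year, else 2016).
#' @return `campus_bundle` with provenance marked "supplementary".
#' @export
load_supplementary_tables <- function(dir, year = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  missing <- .bundle_files[!file.exists(file.path(dir, .bundle_files))]
  if (length(missing))
    stop("bundle directory ", dir, " is missing expected table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta_path <- file.path(dir, "meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(year)) year <- meta$year %||% 2016L
  tables <- lapply(stats::setNames(nm = c("GHG", "N", "P", "W")), function(fp)
    load_factor_table(file.path(dir, .bundle_files[[fp]])))
  for (fp in names(tables)) {
    rep <- validate_factor_table(tables[[fp]])
    if (nrow(rep))
      stop("invalid ", fp, " factor table in bundle: ", rep$message[1L],
           call. = FALSE)
  }
  structure(list(
    ledger = load_ledger(file.path(dir, .bundle_files[["ledger"]]), year = year,
                         label = meta$label),
    tables = tables,
    damage_table = load_damage_table(file.path(dir, .bundle_files[["damage"]])),
    drivers = load_drivers(file.path(dir, .bundle_files[["drivers"]])),
    meta = utils::modifyList(list(provenance = "supplementary"), meta)),
    class = "campus_bundle")
}
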