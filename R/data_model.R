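#' @name data_model
#' @title Shared data containers: activity ledgers and factor tables
#'
#' @description
#' The accounting engine is built on two containers. An **activity ledger**
#' is the campus consumption record for one calendar year: rows of
#' (category, item, quantity, unit, year), e.g. kWh of electricity
#' purchased, tons of coal burned, kg of beef served, commuter miles
#' driven. One ledger feeds all four footprints, which is what makes the
#' footprints directly comparable. A **factor table** carries, for one
#' footprint, the emission (or consumption) factors keyed by
#' (category, item, pollutant form), each expressed as mass (or volume) of
#' pollutant per activity unit.
#'
#' Categories come from a controlled ten-element vocabulary; items are an
#' open vocabulary (food taxonomies differ between institutions).
NULL

#' The controlled activity-category vocabulary
#'
#' @return character vector of the ten recognised categories.
#' @export
footprint_categories <- function() {
  c("purchased_electricity", "stationary_fuels", "direct_transportation",
    "commuting", "food", "fertilizer", "animals", "refrigerants_chemicals",
    "wastewater", "direct_water")
}

#' The four footprints and their normalised reporting units
#'
#' GHG in metric tons CO2-equivalent (MTCDE), N in metric tons of N,
#' P in kg of P, W in cubic meters of freshwater (also rendered in gallons).
#'
#' @return named character vector mapping footprint code to unit label.
#' @export
footprint_units <- function() {
  c(GHG = "t CO2e", N = "t N", P = "kg P", W = "m3")
}

#' Pollutant forms recognised per footprint
#'
#' @param footprint one of "GHG", "N", "P", "W".
#' @return character vector of admissible pollutant forms.
#' @export
footprint_forms <- function(footprint) {
  switch(match.arg(footprint, c("GHG", "N", "P", "W")),
         GHG = c("CO2", "CH4", "N2O", "refrigerant_CO2e"),
         N   = c("NOx_N", "N2O_N", "other_N"),
         P   = "P",
         W   = c("blue_water", "green_water", "direct_water"))
}

# categories that count toward the P footprint; P from fuel combustion is
# negligible and excluded by construction
.p_categories <- c("food", "fertilizer", "wastewater")

#' Construct an activity ledger
#'
#' @param records data.frame with columns `category`, `item`, `quantity`,
#'   `unit` and optionally `year` (filled from `year` argument otherwise).
#'   A zero-row data.frame gives an empty ledger.
#' @param label human-readable label carried through reports.
#' @param year calendar year of the snapshot; all records must share it.
#' @return object of class `activity_ledger` (a validated data.frame with
#'   `label` and `year` attributes).
#' @examples
#' activity_ledger(data.frame(category = "food", item = "beef",
#'                            quantity = 100, unit = "kg"), "demo", 2016)
#' @export
activity_ledger <- function(records = NULL, label = "ledger", year = 2016L) {
  cols <- c("category", "item", "quantity", "unit", "year")
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(category = character(), item = character(),
                          quantity = numeric(), unit = character(),
                          year = integer())
  }
  if (!("year" %in% names(records))) records$year <- as.integer(year)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("ledger records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[cols]
  records$category <- as.character(records$category)
  records$item <- as.character(records$item)
  records$quantity <- as.numeric(records$quantity)
  records$unit <- as.character(records$unit)
  records$year <- as.integer(records$year)
  rownames(records) <- NULL
  led <- structure(records, label = as.character(label),
                   year = as.integer(year), class = c("activity_ledger", "data.frame"))
  validate_ledger(led)
  led
}

validate_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "activity_ledger"))
  bad_cat <- setdiff(unique(ledger$category), footprint_categories())
  if (length(bad_cat)) {
    rows <- which(ledger$category %in% bad_cat)
    stop("unknown category '", bad_cat[1L], "' in ledger row ", rows[1L],
         " (vocabulary: ", paste(footprint_categories(), collapse = ", "), ")",
         call. = FALSE)
  }
  if (nrow(ledger) && any(!is.finite(ledger$quantity) | ledger$quantity < 0)) {
    row <- which(!is.finite(ledger$quantity) | ledger$quantity < 0)[1L]
    stop("negative or non-finite quantity in ledger row ", row, call. = FALSE)
  }
  if (nrow(ledger)) unit_dimension(ledger$unit)  # errors on unresolvable units
  if (nrow(ledger) && any(ledger$year != attr(ledger, "year"))) {
    stop("all records must share the ledger year ", attr(ledger, "year"),
         call. = FALSE)
  }
  invisible(ledger)
}

#' @export
print.activity_ledger <- function(x, ...) {
  cat(sprintf("<activity_ledger> '%s', year %d, %d records\n",
              attr(x, "label"), attr(x, "year"), nrow(x)))
  if (nrow(x)) {
    tot <- tapply(seq_len(nrow(x)), x$category, length)
    cat("  categories:",
        paste(sprintf("%s(%d)", names(tot), tot), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an activity ledger from CSV
#'
#' Columns: `category,item,quantity,unit[,year]`. Row order is preserved.
#'
#' @param path CSV file path.
#' @param year ledger year; if the file has a `year` column it must agree.
#' @param label ledger label (defaults to the file name).
#' @return `activity_ledger`.
#' @export
load_ledger <- function(path, year = 2016L, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(label)) label <- sub("\\.csv$", "", basename(path))
  activity_ledger(df, label = label, year = year)
}

#' Write an activity ledger to CSV
#'
#' Deterministic column order (`category,item,quantity,unit,year`), one row
#' per record; two saves of the same ledger are byte-identical.
#'
#' @param ledger `activity_ledger`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_ledger <- function(ledger, path) {
  validate_ledger(ledger)
  df <- as.data.frame(ledger)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Construct an emission-factor table for one footprint
#'
#' Each factor states pollutant output per activity unit, e.g. for GHG
#' 0.0006 t CO2 per kWh of purchased electricity. CH4 and N2O factors are
#' stored as mass of the gas itself; conversion to CO2-equivalents happens
#' in the engine through the table's 100-year global warming potentials.
#'
#' @param footprint "GHG", "N", "P" or "W".
#' @param factors data.frame with columns `category`, `item`,
#'   `pollutant_form`, `value`, `numerator_unit`, `per_unit`.
#' @param gwp named list/vector of 100-yr global warming potentials for
#'   CH4 and N2O (defaults: AR5 values 28 and 265). Only used for GHG.
#' @param provenance free-text source note carried into output metadata.
#' @return object of class `factor_table`.
#' @export
factor_table <- function(footprint, factors,
                         gwp = c(CH4 = 28, N2O = 265),
                         provenance = "unspecified") {
  footprint <- match.arg(footprint, c("GHG", "N", "P", "W"))
  cols <- c("category", "item", "pollutant_form", "value",
            "numerator_unit", "per_unit")
  if (nrow(factors) == 0L) {
    factors <- data.frame(category = character(), item = character(),
                          pollutant_form = character(), value = numeric(),
                          numerator_unit = character(), per_unit = character())
  }
  missing_cols <- setdiff(cols, names(factors))
  if (length(missing_cols)) {
    stop("factor table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  factors <- factors[cols]
  for (ch in c("category", "item", "pollutant_form", "numerator_unit", "per_unit"))
    factors[[ch]] <- as.character(factors[[ch]])
  factors$value <- as.numeric(factors$value)
  rownames(factors) <- NULL
  gwp <- as.list(gwp)
  if (footprint == "GHG" && any(unlist(gwp) <= 1)) {
    stop("global warming potentials must exceed 1", call. = FALSE)
  }
  tab <- structure(factors, footprint = footprint, gwp = gwp,
                   provenance = as.character(provenance),
                   class = c("factor_table", "data.frame"))
  rep <- validate_factor_table(tab)
  if (nrow(rep)) {
    stop("invalid factor table: ", rep$message[1L],
         if (nrow(rep) > 1L) sprintf(" (and %d more finding(s))", nrow(rep) - 1L),
         call. = FALSE)
  }
  tab
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf("<factor_table> footprint %s, %d factors (%s)\n",
              attr(x, "footprint"), nrow(x), attr(x, "provenance")))
  invisible(x)
}

#' Validate a factor table, returning a findings report
#'
#' Checks for duplicate (category, item, pollutant_form) keys, negative
#' values, pollutant forms inconsistent with the table's footprint,
#' unknown categories, and units the registry cannot resolve. An empty
#' report (zero rows) means the table is valid. This reports rather than
#' errors so callers can triage externally supplied tables.
#'
#' @param table a `factor_table` (or a data.frame with a `footprint`
#'   attribute set).
#' @return data.frame with columns `kind`, `key`, `message`; zero rows iff
#'   valid.
#' @export
validate_factor_table <- function(table) {
  fp <- attr(table, "footprint")
  findings <- list()
  add <- function(kind, key, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(kind = kind, key = key, message = message)
  }
  if (nrow(table)) {
    key <- paste(table$category, table$item, table$pollutant_form, sep = "|")
    dup <- unique(key[duplicated(key)])
    for (k in dup) add("duplicate_key", k, paste0("duplicate factor key ", k))
    neg <- which(!is.finite(table$value) | table$value < 0)
    for (i in neg) add("negative_value", key[i],
                      paste0("negative or non-finite factor value for ", key[i]))
    bad_form <- which(!(table$pollutant_form %in% footprint_forms(fp)))
    for (i in bad_form)
      add("form_mismatch", key[i],
          sprintf("pollutant form %s inconsistent with footprint %s",
                  table$pollutant_form[i], fp))
    bad_cat <- which(!(table$category %in% footprint_categories()))
    for (i in bad_cat)
      add("unknown_category", key[i],
          paste0("unknown category ", table$category[i]))
    units_ok <- tryCatch({
      unit_dimension(table$per_unit); unit_dimension(table$numerator_unit); TRUE
    }, error = function(e) FALSE)
    if (!units_ok) {
      for (i in seq_len(nrow(table))) {
        bad <- tryCatch({
          unit_dimension(table$per_unit[i]); unit_dimension(table$numerator_unit[i]); FALSE
        }, error = function(e) TRUE)
        if (bad) add("unit_error", key[i],
                     paste0("unresolvable unit in factor ", key[i]))
      }
    } else {
      # numerator must be a mass for GHG/N/P and a volume for W
      want <- if (fp == "W") "volume" else "mass"
      bad_num <- which(unit_dimension(table$numerator_unit) != want)
      for (i in bad_num)
        add("unit_error", key[i],
            sprintf("numerator unit %s is not a %s unit",
                    table$numerator_unit[i], want))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(kind = character(), key = character(), message = character())
}

#' Read a factor table from CSV (plus optional YAML sidecar)
#'
#' CSV columns: `footprint,category,item,pollutant_form,value,
#' numerator_unit,per_unit`. A sidecar `<path>.yaml`, when present, carries
#' `gwp:` overrides and `provenance:`.
#'
#' @param path CSV file path.
#' @return `factor_table`.
#' @export
load_factor_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fp <- unique(df$footprint)
  if (length(fp) != 1L)
    stop("factor CSV must carry exactly one footprint, got: ",
         paste(fp, collapse = ", "), call. = FALSE)
  side <- paste0(path, ".yaml")
  gwp <- c(CH4 = 28, N2O = 265)
  prov <- "unspecified"
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$gwp)) gwp <- unlist(meta$gwp)
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  factor_table(fp, df[setdiff(names(df), "footprint")], gwp = gwp,
               provenance = prov)
}

#' Write a factor table to CSV with a YAML sidecar
#'
#' @param table `factor_table`.
#' @param path output CSV path; `<path>.yaml` gets gwp + provenance.
#' @return `path`, invisibly.
#' @export
save_factor_table <- function(table, path) {
  df <- cbind(footprint = attr(table, "footprint"), as.data.frame(table))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  yaml::write_yaml(list(gwp = attr(table, "gwp"),
                        provenance = attr(table, "provenance")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Construct growth drivers for business-as-usual projection
#'
#' Three named multipliers (population, gross square footage, food demand)
#' plus a mapping from each ledger category to the driver that scales it.
#' The default mapping: food follows food demand; energy, refrigerants and
#' direct water follow floor area; commuting, fleet transport and
#' wastewater follow population; fertilizer and animals are held constant.
#'
#' @param population_mult,gsf_mult,food_mult positive multipliers for the
#'   target year relative to the base year.
#' @param driver_map named character vector category -> one of
#'   "population", "gsf", "food", "identity". Defaults cover all ten
#'   categories and can be partially overridden.
#' @return object of class `growth_drivers`.
#' @export
growth_drivers <- function(population_mult = 1, gsf_mult = 1, food_mult = 1,
                           driver_map = NULL) {
  default_map <- c(purchased_electricity = "gsf", stationary_fuels = "gsf",
                   refrigerants_chemicals = "gsf", direct_water = "gsf",
                   food = "food", commuting = "population",
                   direct_transportation = "population",
                   wastewater = "population",
                   fertilizer = "identity", animals = "identity")
  if (!is.null(driver_map)) {
    bad <- setdiff(names(driver_map), footprint_categories())
    if (length(bad)) stop("driver_map has unknown categories: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    default_map[names(driver_map)] <- driver_map
  }
  mult <- c(population = population_mult, gsf = gsf_mult, food = food_mult,
            identity = 1)
  if (any(!is.finite(mult)) || any(mult <= 0))
    stop("growth multipliers must be finite and > 0", call. = FALSE)
  bad_driver <- setdiff(unique(default_map), names(mult))
  if (length(bad_driver)) stop("unknown driver name(s): ",
                               paste(bad_driver, collapse = ", "), call. = FALSE)
  structure(list(multipliers = mult, driver_map = default_map),
            class = "growth_drivers")
}

#' @export
print.growth_drivers <- function(x, ...) {
  m <- x$multipliers
  cat(sprintf("<growth_drivers> population %.3f, gsf %.3f, food %.3f\n",
              m[["population"]], m[["gsf"]], m[["food"]]))
  invisible(x)
}

#' Read growth drivers from YAML
#'
#' Layout: `{population_mult, gsf_mult, food_mult, driver_map: {category: driver}}`.
#'
#' @param path YAML file path.
#' @return `growth_drivers`.
#' @export
load_drivers <- function(path) {
  y <- yaml::read_yaml(path)
  growth_drivers(population_mult = y$population_mult %||% 1,
                 gsf_mult = y$gsf_mult %||% 1,
                 food_mult = y$food_mult %||% 1,
                 driver_map = if (!is.null(y$driver_map)) unlist(y$driver_map))
}

#' Write growth drivers to YAML
#'
#' @param drivers `growth_drivers`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_drivers <- function(drivers, path) {
  m <- drivers$multipliers
  yaml::write_yaml(list(population_mult = unname(m[["population"]]),
                        gsf_mult = unname(m[["gsf"]]),
                        food_mult = unname(m[["food"]]),
                        driver_map = as.list(drivers$driver_map)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
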