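#' @name scenario_engine
#' @title Action-plan strategies as declarative ledger transformations
#'
#' @description
#' A sustainability-action-plan strategy is a small declarative
#' transformation of the activity ledger and/or the emission-factor
#' tables: switch a fuel on an energy-equivalent basis, shave a category
#' by an efficiency fraction, decarbonise the electricity grid (a factor
#' change), offset purchased electricity with renewables, substitute one
#' food for others at constant total food mass, cut avoidable food waste,
#' or improve a vehicle fleet. Strategies compose sequentially in catalog
#' id order, each fraction interpreted against the running ledger, so a
#' composed portfolio is reproducible and order-stamped.
NULL

.strategy_kinds <- c("fuel_switch", "efficiency", "grid_factor_change",
                     "renewable_offset", "food_substitution",
                     "food_waste_reduction", "sourcing_factor_change",
                     "fleet_improvement", "behavior_reduction")

#' Construct a strategy
#'
#' @param id integer id, unique within a catalog; composition order.
#' @param name human-readable name.
#' @param kind one of `fuel_switch`, `efficiency`, `grid_factor_change`,
#'   `renewable_offset`, `food_substitution`, `food_waste_reduction`,
#'   `sourcing_factor_change`, `fleet_improvement`, `behavior_reduction`.
#' @param params kind-specific parameter list, e.g. for `fuel_switch`:
#'   `from_item`, `to_item`, `fraction`; for `food_substitution`:
#'   `from_item` (may be a vector), `to_items`, `weights` (sum to 1),
#'   `fraction`; for `efficiency`/`behavior_reduction`: `category`,
#'   optional `items`, `fraction`; for `renewable_offset`: `amount`,
#'   `unit`; for the factor-change kinds: `category`, optional `items`,
#'   optional `footprints`, `fraction`.
#' @param in_nap,in_ghgap membership flags for the nitrogen and GHG
#'   action plans.
#' @return object of class `strategy`.
#' @export
strategy <- function(id, name, kind, params = list(),
                     in_nap = TRUE, in_ghgap = TRUE) {
  kind <- match.arg(kind, .strategy_kinds)
  if (!is.null(params$fraction)) {
    if (params$fraction < 0 || params$fraction > 1)
      stop("strategy ", id, ": fraction must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "food_substitution") {
    w <- params$weights %||% rep(1 / length(params$to_items),
                                 length(params$to_items))
    if (length(w) != length(params$to_items))
      stop("strategy ", id, ": weights must match to_items", call. = FALSE)
    if (abs(sum(w) - 1) > 1e-9)
      stop("strategy ", id, ": substitution weights must sum to 1", call. = FALSE)
    params$weights <- w
  }
  structure(list(id = as.integer(id), name = as.character(name), kind = kind,
                 params = params, in_nap = isTRUE(in_nap),
                 in_ghgap = isTRUE(in_ghgap)),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy #%d> %s [%s] NAP=%s GHGAP=%s\n", x$id, x$name,
              x$kind, x$in_nap, x$in_ghgap))
  invisible(x)
}

#' Open a scenario state over a ledger and factor tables
#'
#' The state carries the running ledger, the (possibly strategy-modified)
#' factor tables, and the ordered list of applied strategy ids.
#'
#' @param ledger `activity_ledger` (typically the BAU projection).
#' @param tables named/attributed list of the four `factor_table`s.
#' @return object of class `scenario_state`.
#' @export
scenario_state <- function(ledger, tables) {
  validate_ledger(ledger)
  fps <- vapply(tables, function(t) attr(t, "footprint"), character(1))
  names(tables) <- fps
  structure(list(ledger = ledger, tables = tables, applied = integer()),
            class = "scenario_state")
}

#' @export
print.scenario_state <- function(x, ...) {
  cat(sprintf("<scenario_state> %d records, applied: %s\n", nrow(x$ledger),
              if (length(x$applied)) paste(x$applied, collapse = ",") else "none"))
  invisible(x)
}

# default higher heating values, MJ per reference unit, for the
# energy-equivalence basis of fuel switches
#' Default fuel energy contents for energy-equivalent fuel switching
#'
#' @return data.frame with columns `item`, `unit`, `mj_per_unit`.
#' @export
fuel_energy_defaults <- function() {
  data.frame(
    item = c("coal", "natural gas", "fuel oil", "gasoline", "diesel",
             "biomass"),
    unit = c("t", "MMBtu", "gallon", "gallon", "gallon", "t"),
    mj_per_unit = c(26000, 1055.05585262, 146.5, 132.3, 146.5, 16000))
}

.ledger_replace <- function(state, df) {
  state$ledger <- activity_ledger(df, label = attr(state$ledger, "label"),
                                  year = attr(state$ledger, "year"))
  state
}

# move `fraction` of from_item's quantity (converted to kg) to to_items in
# proportion `weights`, conserving total mass; appends rows for absent
# destination items
.apply_food_substitution <- function(state, p) {
  df <- as.data.frame(state$ledger)
  from <- p$from_item
  sel_from <- df$category == "food" & df$item %in% from
  if (!any(sel_from)) {
    warning("food_substitution: item(s) ", paste(from, collapse = ", "),
            " absent from ledger; no-op", call. = FALSE)
    return(state)
  }
  moved_kg_total <- 0
  for (i in which(sel_from)) {
    q_kg <- convert_unit(df$quantity[i], df$unit[i], "kg")
    moved <- q_kg * p$fraction
    df$quantity[i] <- convert_unit(q_kg - moved, "kg", df$unit[i])
    moved_kg_total <- moved_kg_total + moved
  }
  for (k in seq_along(p$to_items)) {
    add_kg <- moved_kg_total * p$weights[k]
    j <- which(df$category == "food" & df$item == p$to_items[k])
    if (length(j)) {
      j <- j[1L]
      df$quantity[j] <- df$quantity[j] + convert_unit(add_kg, "kg", df$unit[j])
    } else {
      df <- rbind(df, data.frame(category = "food", item = p$to_items[k],
                                 quantity = add_kg, unit = "kg",
                                 year = attr(state$ledger, "year")))
    }
  }
  .ledger_replace(state, df)
}

.apply_fuel_switch <- function(state, p) {
  df <- as.data.frame(state$ledger)
  category <- p$category %||% "stationary_fuels"
  energy <- p$fuel_energy %||% fuel_energy_defaults()
  sel <- df$category == category & df$item == p$from_item
  if (!any(sel)) {
    warning("fuel_switch: item ", p$from_item, " absent from ledger; no-op",
            call. = FALSE)
    return(state)
  }
  e_from <- energy[energy$item == p$from_item, ]
  e_to <- energy[energy$item == p$to_item, ]
  if (nrow(e_from) != 1L || nrow(e_to) != 1L)
    stop("fuel_switch: missing energy content for ",
         p$from_item, " or ", p$to_item, call. = FALSE)
  moved_mj <- 0
  for (i in which(sel)) {
    q_ref <- convert_unit(df$quantity[i], df$unit[i], e_from$unit)
    mj <- q_ref * e_from$mj_per_unit * p$fraction
    df$quantity[i] <- df$quantity[i] * (1 - p$fraction)
    moved_mj <- moved_mj + mj
  }
  add_ref <- moved_mj / e_to$mj_per_unit
  j <- which(df$category == category & df$item == p$to_item)
  if (length(j)) {
    j <- j[1L]
    df$quantity[j] <- df$quantity[j] + convert_unit(add_ref, e_to$unit, df$unit[j])
  } else {
    df <- rbind(df, data.frame(category = category, item = p$to_item,
                               quantity = add_ref, unit = e_to$unit,
                               year = attr(state$ledger, "year")))
  }
  .ledger_replace(state, df)
}

.apply_quantity_scaling <- function(state, p, default_category) {
  df <- as.data.frame(state$ledger)
  category <- p$category %||% default_category
  sel <- df$category == category
  if (!is.null(p$items)) sel <- sel & df$item %in% p$items
  if (!any(sel)) {
    warning("strategy targets (", category,
            if (!is.null(p$items)) paste0(": ", paste(p$items, collapse = ", ")),
            ") absent from ledger; no-op", call. = FALSE)
    return(state)
  }
  df$quantity[sel] <- df$quantity[sel] * (1 - p$fraction)
  .ledger_replace(state, df)
}

.apply_renewable_offset <- function(state, p) {
  df <- as.data.frame(state$ledger)
  sel <- which(df$category == "purchased_electricity")
  if (!is.null(p$item)) sel <- sel[df$item[sel] == p$item]
  if (!length(sel)) {
    warning("renewable_offset: no purchased electricity in ledger; no-op",
            call. = FALSE)
    return(state)
  }
  remaining <- p$amount  # in p$unit (default kWh)
  unit <- p$unit %||% "kWh"
  for (i in sel) {
    if (remaining <= 0) break
    q <- convert_unit(df$quantity[i], df$unit[i], unit)
    take <- min(q, remaining)
    df$quantity[i] <- convert_unit(q - take, unit, df$unit[i])
    remaining <- remaining - take
  }
  if (remaining > 1e-9)
    warning(sprintf(
      "renewable_offset: offset exceeds purchased electricity by %.4g %s; floored at 0",
      remaining, unit), call. = FALSE)
  .ledger_replace(state, df)
}

.apply_factor_scaling <- function(state, p, default_category) {
  category <- p$category %||% default_category
  fps <- p$footprints %||% names(state$tables)
  touched <- FALSE
  for (fp in fps) {
    tab <- state$tables[[fp]]
    sel <- tab$category == category
    if (!is.null(p$items)) sel <- sel & tab$item %in% p$items
    if (any(sel)) {
      touched <- TRUE
      df <- as.data.frame(tab)
      df$value[sel] <- df$value[sel] * (1 - p$fraction)
      state$tables[[fp]] <- factor_table(fp, df, gwp = attr(tab, "gwp"),
                                         provenance = attr(tab, "provenance"))
    }
  }
  if (!touched)
    warning("factor change targets no factors in category ", category,
            "; no-op", call. = FALSE)
  state
}

.apply_food_waste_reduction <- function(state, p) {
  avoidable <- p$avoidable_share %||% 0.1
  .apply_quantity_scaling(
    state, list(category = "food", fraction = p$fraction * avoidable), "food")
}

#' Apply one strategy to a scenario state
#'
#' Kind semantics: `fuel_switch` moves a fraction of the source fuel to the
#' destination fuel on an energy-content basis (delivered heat preserved);
#' `efficiency`, `behavior_reduction` and `fleet_improvement` multiply the
#' targeted quantities by (1 - fraction); `grid_factor_change` and
#' `sourcing_factor_change` multiply the targeted emission factors by
#' (1 - fraction); `food_substitution` moves a fraction of the source
#' food's mass to the destination foods, conserving total food mass;
#' `food_waste_reduction` removes a fraction of the avoidable-waste share
#' of all food; `renewable_offset` subtracts an absolute amount from
#' purchased electricity, floored at zero. A strategy whose target is
#' absent from the ledger warns and leaves the state unchanged.
#'
#' @param state `scenario_state`.
#' @param s `strategy`.
#' @return updated `scenario_state` (applied ids extended by `s$id`).
#' @export
apply_strategy <- function(state, s) {
  stopifnot(inherits(state, "scenario_state"), inherits(s, "strategy"))
  p <- s$params
  if (!is.null(p$fraction) && p$fraction == 0 &&
      s$kind != "renewable_offset") {
    state$applied <- c(state$applied, s$id)
    return(state)
  }
  state <- switch(s$kind,
    fuel_switch           = .apply_fuel_switch(state, p),
    efficiency            = .apply_quantity_scaling(state, p, "stationary_fuels"),
    behavior_reduction    = .apply_quantity_scaling(state, p, "commuting"),
    fleet_improvement     = .apply_quantity_scaling(state, p, "direct_transportation"),
    grid_factor_change    = .apply_factor_scaling(state, p, "purchased_electricity"),
    sourcing_factor_change = .apply_factor_scaling(state, p, "food"),
    renewable_offset      = .apply_renewable_offset(state, p),
    food_substitution     = .apply_food_substitution(state, p),
    food_waste_reduction  = .apply_food_waste_reduction(state, p))
  state$applied <- c(state$applied, s$id)
  state
}

#' Compose a subset of strategies onto a state, in catalog id order
#'
#' @param state `scenario_state`.
#' @param strategies list of `strategy` objects (a catalog subset); applied
#'   sequentially in increasing id order, each against the running state.
#' @return updated `scenario_state` with `applied` recording the order.
#' @export
compose_strategies <- function(state, strategies) {
  if (!length(strategies)) return(state)
  ids <- vapply(strategies, `[[`, integer(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate strategy id(s) in subset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (s in strategies[order(ids)]) state <- apply_strategy(state, s)
  state
}

#' The default 29-strategy action-plan catalog
#'
#' Rows 1-16 (fuel optimization, plant/distribution efficiency, grid
#' improvements, solar, building standards, fleet, outreach, green IT)
#' belong to both the nitrogen and the GHG action plans; rows 17-29 (the
#' food strategies: vegetarian meal replacement, beef-to-chicken
#' substitutions, waste reduction, sustainable sourcing) belong to the
#' nitrogen action plan only. Strategy names are fixed; numeric parameters
#' not fixed by the plan descriptions themselves are illustrative defaults
#' for a mid-size campus and should be overridden with institution-specific
#' values via a catalog YAML.
#'
#' @return list of 29 `strategy` objects.
#' @export
default_strategy_catalog <- function() {
  veg <- c("legumes", "eggs", "grains", "vegetables")
  meats <- c("beef", "chicken", "pork", "fish")
  both <- function(id, name, kind, params)
    strategy(id, name, kind, params, in_nap = TRUE, in_ghgap = TRUE)
  nap <- function(id, name, kind, params)
    strategy(id, name, kind, params, in_nap = TRUE, in_ghgap = FALSE)
  list(
    both(1L, "Fuel optimization", "fuel_switch",
         list(from_item = "coal", to_item = "natural gas", fraction = 1.0)),
    both(2L, "Chilled water plant efficiency improvements", "efficiency",
         list(category = "purchased_electricity", fraction = 0.03)),
    both(3L, "Heat plant efficiency improvements", "efficiency",
         list(category = "stationary_fuels", fraction = 0.05)),
    both(4L, "Distribution efficiency / low-temperature hot water", "efficiency",
         list(category = "stationary_fuels", fraction = 0.04)),
    both(5L, "Electricity grid improvements", "grid_factor_change",
         list(category = "purchased_electricity", fraction = 0.30)),
    both(6L, "On-grounds solar", "renewable_offset",
         list(amount = 5e6, unit = "kWh")),
    both(7L, "Off-grounds utility-scale solar (site A)", "renewable_offset",
         list(amount = 2e7, unit = "kWh")),
    both(8L, "Off-grounds utility-scale solar (site B)", "renewable_offset",
         list(amount = 1.5e7, unit = "kWh")),
    both(9L, "Additional off-grounds utility-scale solar", "renewable_offset",
         list(amount = 3e7, unit = "kWh")),
    both(10L, "Existing building improvements", "efficiency",
         list(category = "purchased_electricity", fraction = 0.05)),
    both(11L, "Green building standards", "efficiency",
         list(category = "purchased_electricity", fraction = 0.02)),
    both(12L, "Green labs", "efficiency",
         list(category = "purchased_electricity", fraction = 0.02)),
    both(13L, "Gasoline fleet improvements", "fleet_improvement",
         list(items = "gasoline", fraction = 0.10)),
    both(14L, "Diesel fleet improvements", "fleet_improvement",
         list(items = "diesel", fraction = 0.10)),
    both(15L, "Outreach and engagement", "behavior_reduction",
         list(category = "commuting", fraction = 0.03)),
    both(16L, "Green IT", "behavior_reduction",
         list(category = "purchased_electricity", fraction = 0.02)),
    nap(17L, "15% vegetarian meal replacement", "food_substitution",
        list(from_item = meats, fraction = 0.15,
             to_items = veg, weights = c(0.4, 0.2, 0.2, 0.2))),
    nap(18L, "Meat-focused cafe becomes plant forward", "food_substitution",
        list(from_item = meats, fraction = 0.02,
             to_items = c("legumes", "vegetables"), weights = c(0.5, 0.5))),
    nap(19L, "Plant-forward dining venue", "food_substitution",
        list(from_item = meats, fraction = 0.01,
             to_items = c("legumes", "vegetables"), weights = c(0.5, 0.5))),
    nap(20L, "Plant-forward theme meals (3 per month)", "food_substitution",
        list(from_item = meats, fraction = 0.01,
             to_items = veg, weights = c(0.4, 0.2, 0.2, 0.2))),
    nap(21L, "Plant-forward Fridays in residential dining", "food_substitution",
        list(from_item = meats, fraction = 0.03,
             to_items = veg, weights = c(0.4, 0.2, 0.2, 0.2))),
    nap(22L, "20% beef replaced with chicken", "food_substitution",
        list(from_item = "beef", fraction = 0.20,
             to_items = "chicken", weights = 1)),
    nap(23L, "Blended burgers in dining halls", "food_substitution",
        list(from_item = "beef", fraction = 0.05,
             to_items = "vegetables", weights = 1)),
    nap(24L, "10% health-system beef replaced with chicken", "food_substitution",
        list(from_item = "beef", fraction = 0.10,
             to_items = "chicken", weights = 1)),
    nap(25L, "15% burgers replaced with plant-based burgers", "food_substitution",
        list(from_item = "beef", fraction = 0.05,
             to_items = "legumes", weights = 1)),
    nap(26L, "Mindful Mondays", "food_substitution",
        list(from_item = meats, fraction = 0.02,
             to_items = veg, weights = c(0.4, 0.2, 0.2, 0.2))),
    nap(27L, "Beef-free station for 6 months", "food_substitution",
        list(from_item = "beef", fraction = 0.05,
             to_items = c("chicken", "legumes"), weights = c(0.5, 0.5))),
    nap(28L, "50% avoidable food waste reduced", "food_waste_reduction",
        list(fraction = 0.50, avoidable_share = 0.10)),
    nap(29L, "50% food is sustainably sourced", "sourcing_factor_change",
        list(category = "food", fraction = 0.05)))
}

#' Build a strategy catalog from a YAML config
#'
#' Layout: a top-level `strategies:` list of
#' `{id, name, kind, params: {...}, in_nap, in_ghgap}` entries. An empty or
#' absent list gives an empty catalog. With `path = NULL` the built-in
#' default catalog is returned.
#'
#' @param path YAML file, or NULL for [default_strategy_catalog()].
#' @return list of `strategy` objects.
#' @export
build_strategy_catalog <- function(path = NULL) {
  if (is.null(path)) return(default_strategy_catalog())
  y <- yaml::read_yaml(path)
  entries <- y$strategies %||% list()
  lapply(entries, function(e) {
    tryCatch({
      p <- e$params %||% list()
      for (nm in c("from_item", "to_items", "weights", "items", "footprints"))
        if (!is.null(p[[nm]])) p[[nm]] <- unlist(p[[nm]])
      strategy(e$id, e$name, e$kind, p,
               in_nap = e$in_nap %||% TRUE, in_ghgap = e$in_ghgap %||% TRUE)
    }, error = function(err) {
      stop("malformed strategy entry (id ", e$id %||% "?", "): ",
           conditionMessage(err), call. = FALSE)
    })
  })
}

#' Write a strategy catalog to YAML
#'
#' @param catalog list of `strategy` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_strategy_catalog <- function(catalog, path) {
  yaml::write_yaml(list(strategies = lapply(catalog, function(s)
    list(id = s$id, name = s$name, kind = s$kind,
         params = lapply(s$params, function(v) if (length(v) > 1) as.list(v) else v),
         in_nap = s$in_nap, in_ghgap = s$in_ghgap))), path)
  invisible(path)
}

#' Select catalog strategies by id
#'
#' @param catalog list of `strategy` objects.
#' @param ids integer ids; every id must exist in the catalog.
#' @return list of `strategy` objects.
#' @export
catalog_subset <- function(catalog, ids) {
  all_ids <- vapply(catalog, `[[`, integer(1), "id")
  miss <- setdiff(ids, all_ids)
  if (length(miss))
    stop("unknown strategy id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  catalog[match(ids, all_ids)]
}

#' Run a portfolio of named scenario subsets against a baseline
#'
#' Produces the standard comparison table: the base-year footprints, the
#' projected business-as-usual footprints, and one row per named strategy
#' subset applied to the BAU ledger, with signed percent changes of every
#' footprint relative to BAU.
#'
#' @param baseline base-year `activity_ledger`.
#' @param drivers `growth_drivers` for the BAU projection.
#' @param catalog strategy catalog (list of `strategy`).
#' @param subsets named list of integer id vectors; may be empty.
#' @param tables the four `factor_table`s.
#' @param target_year BAU projection year (default 2025).
#' @param warn_missing see [compute_footprint()].
#' @return data.frame with columns `scenario`, `year`, `GHG`, `N`, `P`,
#'   `W`, `GHG_pct`, `N_pct`, `P_pct`, `W_pct` (percent change vs BAU).
#' @export
run_portfolio <- function(baseline, drivers, catalog, subsets, tables,
                          target_year = 2025L,
                          warn_missing = getOption("campusfp.warn_missing", TRUE)) {
  base_fp <- compute_integrated(baseline, tables, warn_missing = warn_missing)
  bau <- project_bau(baseline, drivers, target_year)
  bau_fp <- compute_integrated(bau, tables, warn_missing = FALSE)
  bau_tot <- footprint_totals(bau_fp)
  row <- function(name, year, fp) {
    tot <- footprint_totals(fp)
    pct <- percent_change(bau_tot, tot)
    data.frame(scenario = name, year = as.integer(year),
               GHG = tot[["GHG"]], N = tot[["N"]], P = tot[["P"]], W = tot[["W"]],
               GHG_pct = pct[["GHG"]], N_pct = pct[["N"]],
               P_pct = pct[["P"]], W_pct = pct[["W"]])
  }
  out <- list(row(paste0("baseline ", attr(baseline, "year")),
                  attr(baseline, "year"), base_fp),
              row(paste0("BAU ", target_year), target_year, bau_fp))
  for (nm in names(subsets)) {
    st <- scenario_state(bau, tables)
    st <- compose_strategies(st, catalog_subset(catalog, subsets[[nm]]))
    fp <- compute_integrated(st$ledger, st$tables, warn_missing = FALSE)
    out[[length(out) + 1L]] <- row(nm, target_year, fp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
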