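#' @name projection
#' @title Business-as-usual projection
#'
#' @description
#' A future baseline is obtained by scaling the current ledger, category by
#' category, with growth drivers: projected population, gross square
#' footage (floor area) and food demand. Because the footprint engine is
#' linear, scaling activities scales footprints identically, so a uniform
#' driver g multiplies every footprint by exactly g.
NULL

#' Project a ledger to a target year under business-as-usual growth
#'
#' Each record's quantity is multiplied by the driver mapped to its
#' category; the year is set to `target_year` and the label suffixed
#' " BAU <year>". Identity drivers leave quantities bit-identical.
#'
#' @param ledger `activity_ledger` for the base year.
#' @param drivers `growth_drivers`.
#' @param target_year projection year.
#' @return projected `activity_ledger`.
#' @examples
#' led <- activity_ledger(data.frame(category = "food", item = "beef",
#'                                   quantity = 100, unit = "kg"), "campus", 2016)
#' drv <- growth_drivers(food_mult = 1.18)
#' project_bau(led, drv, 2025)$quantity  # 118
#' @export
project_bau <- function(ledger, drivers, target_year) {
  validate_ledger(ledger)
  if (!inherits(drivers, "growth_drivers"))
    stop("`drivers` must be a growth_drivers object", call. = FALSE)
  unmapped <- setdiff(unique(ledger$category), names(drivers$driver_map))
  if (length(unmapped))
    stop("no growth driver mapped for category: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  df <- as.data.frame(ledger)
  if (nrow(df)) {
    mult <- drivers$multipliers[drivers$driver_map[df$category]]
    df$quantity <- df$quantity * unname(mult)
    df$year <- as.integer(target_year)
  }
  activity_ledger(df,
                  label = paste0(attr(ledger, "label"), " BAU ", target_year),
                  year = target_year)
}

#' Compose two growth-driver sets by elementwise multiplication
#'
#' Projecting with `a` then `b` equals projecting once with
#' `compose_drivers(a, b)` provided the two share a driver map.
#'
#' @param a,b `growth_drivers` with identical driver maps.
#' @return `growth_drivers`.
#' @export
compose_drivers <- function(a, b) {
  stopifnot(inherits(a, "growth_drivers"), inherits(b, "growth_drivers"))
  if (!identical(a$driver_map, b$driver_map))
    stop("cannot compose drivers with different category mappings", call. = FALSE)
  ma <- a$multipliers; mb <- b$multipliers
  growth_drivers(population_mult = ma[["population"]] * mb[["population"]],
                 gsf_mult = ma[["gsf"]] * mb[["gsf"]],
                 food_mult = ma[["food"]] * mb[["food"]],
                 driver_map = a$driver_map)
}
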