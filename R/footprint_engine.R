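#' @name footprint_engine
#' @title The multiply-and-sum footprint engine
#'
#' @description
#' Each footprint is the sum, over every ledger record, of activity
#' quantity times the matching emission factor, normalised to the
#' footprint's reporting unit: for GHG, CO2/CH4/N2O (and directly ledgered
#' refrigerant CO2e) in metric tons CO2-equivalent via 100-yr global
#' warming potentials; for N, NOx-N, N2O-N and other reactive N in metric
#' tons N; for P, kg P drawn only from food, fertilizer and wastewater
#' (P from fuel combustion is negligible and excluded); for W, blue +
#' green + direct water in cubic meters.
#'
#' The model is linear: footprints are additive over ledgers and
#' homogeneous in quantities, which is what makes scenario percent-change
#' arithmetic well-defined.
NULL

#' Compute one footprint from a ledger and its factor table
#'
#' A record contributes `quantity * value` for every factor whose
#' (category, item) matches it, after converting the record's quantity to
#' the factor's `per_unit` and the pollutant mass/volume to the
#' footprint's normalised unit. For GHG, CH4 and N2O masses are multiplied
#' by the table's global warming potentials. Records with no matching
#' factor contribute zero (the sector tables deliberately omit sectors per
#' footprint) and are reported in a consolidated warning.
#'
#' @param ledger `activity_ledger`.
#' @param table `factor_table` for the desired footprint.
#' @param warn_missing warn about (category, item) pairs with no factor?
#'   Default from option `campusfp.warn_missing` (TRUE).
#' @return object of class `footprint_result`: list with `footprint`,
#'   `total`, `unit`, `by_category` (all ten categories), `by_form`,
#'   `label`, `year`.
#' @examples
#' led <- activity_ledger(data.frame(category = "purchased_electricity",
#'   item = "grid electricity", quantity = 2, unit = "kWh"), "ex", 2016)
#' tab <- factor_table("GHG", data.frame(category = "purchased_electricity",
#'   item = "grid electricity", pollutant_form = "CO2", value = 3,
#'   numerator_unit = "t", per_unit = "kWh"))
#' compute_footprint(led, tab)$total  # 6 t CO2e
#' @export
compute_footprint <- function(ledger, table,
                              warn_missing = getOption("campusfp.warn_missing", TRUE)) {
  validate_ledger(ledger)
  if (!inherits(table, "factor_table"))
    stop("`table` must be a factor_table", call. = FALSE)
  fp <- attr(table, "footprint")
  gwp <- attr(table, "gwp")
  out_unit <- switch(fp, GHG = "t", N = "t", P = "kg", W = "m3")

  records <- as.data.frame(ledger)
  if (fp == "P") records <- records[records$category %in% .p_categories, , drop = FALSE]

  by_category <- stats::setNames(numeric(length(footprint_categories())),
                                 footprint_categories())
  forms <- footprint_forms(fp)
  by_form <- stats::setNames(numeric(length(forms)), forms)

  if (nrow(records) && nrow(table)) {
    fac <- as.data.frame(table)
    m <- merge(cbind(records, .rec = seq_len(nrow(records))), fac,
               by = c("category", "item"))
    if (nrow(m)) {
      # dimension guard: activity unit must convert to the factor's per_unit
      dim_rec <- unit_dimension(m$unit)
      dim_per <- unit_dimension(m$per_unit)
      if (any(dim_rec != dim_per)) {
        k <- which(dim_rec != dim_per)[1L]
        stop(sprintf(
          "unit mismatch for (%s, %s): activity in %s but factor per %s",
          m$category[k], m$item[k], m$unit[k], m$per_unit[k]), call. = FALSE)
      }
      q <- convert_unit(m$quantity, m$unit, m$per_unit)
      contrib <- q * m$value
      contrib <- convert_unit(contrib, m$numerator_unit, out_unit)
      if (fp == "GHG") {
        for (gas in names(gwp)) {
          sel <- m$pollutant_form == gas
          contrib[sel] <- contrib[sel] * gwp[[gas]]
        }
      }
      cat_sum <- tapply(contrib, m$category, sum)
      by_category[names(cat_sum)] <- cat_sum
      form_sum <- tapply(contrib, m$pollutant_form, sum)
      by_form[names(form_sum)] <- form_sum
    }
    if (warn_missing) {
      have <- unique(paste(fac$category, fac$item))
      need <- unique(paste(records$category, records$item))
      miss <- setdiff(need, have)
      if (length(miss)) {
        warning(sprintf("%s footprint: no factor for %s; contributing zero",
                        fp, paste(miss, collapse = "; ")), call. = FALSE)
      }
    }
  }
  structure(list(footprint = fp, total = sum(by_form), unit = footprint_units()[[fp]],
                 by_category = by_category, by_form = by_form,
                 label = attr(ledger, "label"), year = attr(ledger, "year")),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("<footprint_result> %s: %.4g %s ('%s', %d)\n",
              x$footprint, x$total, x$unit, x$label, x$year))
  invisible(x)
}

#' Compute all four footprints from one shared ledger
#'
#' Applies the four factor tables to the *same* ledger so the footprints
#' are directly comparable.
#'
#' @param ledger `activity_ledger`.
#' @param tables list of four `factor_table`s; names (or footprint
#'   attributes) must cover GHG, N, P, W exactly once each.
#' @param warn_missing see [compute_footprint()].
#' @return object of class `integrated_footprint`: list with `ghg_total`,
#'   `n_total`, `p_total`, `w_total`, `by_category`, `by_form`, `label`,
#'   `year`, `units`.
#' @export
compute_integrated <- function(ledger, tables,
                               warn_missing = getOption("campusfp.warn_missing", TRUE)) {
  fps <- vapply(tables, function(t) attr(t, "footprint"), character(1))
  names(tables) <- fps
  if (!setequal(fps, c("GHG", "N", "P", "W")) || anyDuplicated(fps))
    stop("need exactly one factor table per footprint (GHG, N, P, W); got: ",
         paste(fps, collapse = ", "), call. = FALSE)
  res <- lapply(c("GHG", "N", "P", "W"), function(fp)
    compute_footprint(ledger, tables[[fp]], warn_missing = warn_missing))
  names(res) <- c("GHG", "N", "P", "W")
  structure(list(
    ghg_total = res$GHG$total, n_total = res$N$total,
    p_total = res$P$total, w_total = res$W$total,
    by_category = lapply(res, `[[`, "by_category"),
    by_form = lapply(res, `[[`, "by_form"),
    units = footprint_units(),
    label = attr(ledger, "label"), year = attr(ledger, "year")),
    class = "integrated_footprint")
}

#' @export
print.integrated_footprint <- function(x, ...) {
  cat(sprintf("<integrated_footprint> '%s' (%d)\n", x$label, x$year))
  cat(sprintf("  GHG %12.4g %s\n  N   %12.4g %s\n  P   %12.4g %s\n  W   %12.4g %s (%.4g gallons)\n",
              x$ghg_total, x$units[["GHG"]], x$n_total, x$units[["N"]],
              x$p_total, x$units[["P"]], x$w_total, x$units[["W"]],
              convert_unit(x$w_total, "m3", "gallon")))
  invisible(x)
}

#' Totals of an integrated footprint as a named vector
#'
#' @param x `integrated_footprint`.
#' @return named numeric vector (GHG, N, P, W) in the normalised units.
#' @export
footprint_totals <- function(x) {
  stopifnot(inherits(x, "integrated_footprint"))
  c(GHG = x$ghg_total, N = x$n_total, P = x$p_total, W = x$w_total)
}

#' Signed percent change between a baseline and a comparison value
#'
#' `(comparison - baseline) / baseline * 100`; reductions are negative
#' (a move from 100 to 62 is -38).
#'
#' @param baseline nonzero reference value.
#' @param comparison value to compare.
#' @return signed percent (vectorised).
#' @export
percent_change <- function(baseline, comparison) {
  if (any(baseline == 0))
    stop("percent change is undefined for a zero baseline", call. = FALSE)
  (comparison - baseline) / baseline * 100
}

#' Per-category breakdown of a footprint result
#'
#' @param result `footprint_result`.
#' @return list with `by_category` (named vector over the full category
#'   vocabulary, zeros for absent categories) and `total`.
#' @export
aggregate_by_category <- function(result) {
  stopifnot(inherits(result, "footprint_result"))
  list(by_category = result$by_category, total = result$total)
}

#' Serialize an integrated footprint to JSON
#'
#' Layout: `{label, year, footprints: {GHG: {total, units, by_category,
#' by_form}, ...}}`.
#'
#' @param x `integrated_footprint`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
footprint_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "integrated_footprint"))
  tot <- footprint_totals(x)
  obj <- list(label = x$label, year = x$year,
              footprints = lapply(stats::setNames(nm = names(tot)), function(fp)
                list(total = unname(tot[[fp]]), units = unname(x$units[[fp]]),
                     by_category = as.list(x$by_category[[fp]]),
                     by_form = as.list(x$by_form[[fp]]))))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
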