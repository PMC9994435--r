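#' @name report
#' @title Portfolio damage costing and report writing
NULL

#' Damage-cost comparison across a scenario portfolio
#'
#' For the base year, the BAU projection and each named strategy subset,
#' computes the GHG damage cost (footprint x social cost of carbon) and
#' the N damage cost (release profile x damage table), with percent
#' changes relative to BAU. The per-scenario impact-sector rollups are
#' attached as the `"by_sector"` attribute (rows = scenarios).
#'
#' @param baseline base-year `activity_ledger`.
#' @param drivers `growth_drivers`.
#' @param catalog strategy catalog.
#' @param subsets named list of strategy id vectors.
#' @param tables the four `factor_table`s.
#' @param damage_table `damage_cost_table` for N.
#' @param scc social cost of carbon, USD/MTCDE.
#' @param scheme virtual-N `apportionment_scheme`.
#' @param target_year BAU year (default 2025).
#' @return data.frame with columns `scenario`, `ghg_cost`, `n_cost`,
#'   `total_cost`, `ghg_cost_pct`, `n_cost_pct` (percent vs BAU).
#' @export
run_damage_portfolio <- function(baseline, drivers, catalog, subsets, tables,
                                 damage_table = default_damage_costs(),
                                 scc = 30, scheme = apportionment_scheme(),
                                 target_year = 2025L) {
  n_tab_of <- function(tabs) tabs[[which(vapply(tabs, function(t)
    attr(t, "footprint"), character(1)) == "N")]]
  cost_of <- function(ledger, tabs) {
    fp <- compute_integrated(ledger, tabs, warn_missing = FALSE)
    rel <- n_release_profile(ledger, n_tab_of(tabs), scheme = scheme)
    nd <- n_damage_cost(rel, damage_table, warn_missing = FALSE)
    list(ghg = ghg_damage_cost(fp$ghg_total, scc), n = nd$total,
         by_sector = nd$by_sector)
  }
  bau <- project_bau(baseline, drivers, target_year)
  scen <- list()
  scen[[paste0("baseline ", attr(baseline, "year"))]] <-
    cost_of(baseline, tables)
  scen[[paste0("BAU ", target_year)]] <- cost_of(bau, tables)
  for (nm in names(subsets)) {
    st <- scenario_state(bau, tables)
    st <- compose_strategies(st, catalog_subset(catalog, subsets[[nm]]))
    scen[[nm]] <- cost_of(st$ledger, st$tables)
  }
  bau_row <- scen[[2L]]
  out <- do.call(rbind, lapply(names(scen), function(nm) {
    s <- scen[[nm]]
    data.frame(scenario = nm, ghg_cost = s$ghg, n_cost = s$n,
               total_cost = s$ghg + s$n,
               ghg_cost_pct = percent_change(bau_row$ghg, s$ghg),
               n_cost_pct = percent_change(bau_row$n, s$n))
  }))
  rownames(out) <- NULL
  attr(out, "by_sector") <- do.call(rbind, lapply(scen, `[[`, "by_sector"))
  out
}

.portfolio_details <- function(baseline, drivers, catalog, subsets, tables,
                               target_year) {
  bau <- project_bau(baseline, drivers, target_year)
  det <- list()
  det[[paste0("baseline ", attr(baseline, "year"))]] <-
    compute_integrated(baseline, tables, warn_missing = FALSE)
  det[[paste0("BAU ", target_year)]] <-
    compute_integrated(bau, tables, warn_missing = FALSE)
  for (nm in names(subsets)) {
    st <- scenario_state(bau, tables)
    st <- compose_strategies(st, catalog_subset(catalog, subsets[[nm]]))
    det[[nm]] <- compute_integrated(st$ledger, st$tables, warn_missing = FALSE)
  }
  det
}

.stacked_footprint_figure <- function(details, portfolio, fp, path) {
  mat <- sapply(details, function(d) d$by_category[[fp]])
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  grDevices::png(path, width = 1200, height = 700, res = 110)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(9, 5, 3, 10), xpd = TRUE)
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  cols <- grDevices::hcl.colors(max(nrow(mat), 2L), "Spectral")[seq_len(nrow(mat))]
  bp <- graphics::barplot(mat, col = cols, las = 2,
                          ylab = footprint_units()[[fp]],
                          main = paste(fp, "footprint by category"),
                          names.arg = colnames(mat),
                          cex.names = 0.75)
  pct <- portfolio[[paste0(fp, "_pct")]]
  tot <- colSums(mat)
  graphics::text(bp, tot, labels = sprintf("%+.1f%%", pct), pos = 3,
                 cex = 0.8)
  graphics::legend("topright", inset = c(-0.18, 0), legend = rev(rownames(mat)),
                   fill = rev(cols), cex = 0.7, bty = "n")
  invisible(path)
}

.sector_damage_figure <- function(damage, path) {
  by_sector <- attr(damage, "by_sector")
  grDevices::png(path, width = 1200, height = 700, res = 110)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(9, 5, 3, 10), xpd = TRUE)
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  mat <- t(by_sector)
  cols <- grDevices::hcl.colors(nrow(mat), "Zissou 1")
  bp <- graphics::barplot(mat, col = cols, las = 2, ylab = "USD (2016)",
                          main = "N damage costs by impact sector",
                          cex.names = 0.75, beside = FALSE)
  graphics::text(bp, colSums(pmax(mat, 0)),
                 labels = sprintf("%+.1f%%", damage$n_cost_pct), pos = 3,
                 cex = 0.8)
  graphics::legend("topright", inset = c(-0.18, 0), legend = rev(rownames(mat)),
                   fill = rev(cols), cex = 0.7, bty = "n")
  invisible(path)
}

#' Write a self-contained scenario report
#'
#' Writes `results.csv` / `results.json` (the portfolio table),
#' `damage.csv` (damage-cost table with sector rollups), stacked-bar
#' figures per footprint and for damage costs by impact sector under
#' `figures/`, and `run_meta.yaml`. Percent labels in the figures are the
#' engine's percent-change values rendered to one decimal; CSV/JSON carry
#' full precision and are the canonical artifacts. Nothing in the report
#' depends on wall-clock time, so regeneration from the same inputs is
#' byte-stable.
#'
#' @param portfolio result of [run_portfolio()].
#' @param damage result of [run_damage_portfolio()] (or NULL to skip).
#' @param out output directory.
#' @param details optional list of per-scenario `integrated_footprint`s
#'   (from the same run) enabling stacked by-category figures; when NULL,
#'   figures fall back to totals-only bars.
#' @param meta named list merged into `run_meta.yaml` (e.g. input
#'   checksums).
#' @return `out`, invisibly.
#' @export
write_report <- function(portfolio, damage = NULL, out, details = NULL,
                         meta = list()) {
  dir.create(file.path(out, "figures"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(portfolio, file.path(out, "results.csv"),
                   row.names = FALSE, eol = "\n")
  json <- jsonlite::toJSON(portfolio, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, file.path(out, "results.json"))
  if (!is.null(damage)) {
    dmg <- cbind(damage, as.data.frame(attr(damage, "by_sector")))
    utils::write.csv(dmg, file.path(out, "damage.csv"), row.names = FALSE,
                     eol = "\n")
  }
  if (!is.null(details)) {
    for (fp in c("GHG", "N", "P", "W"))
      .stacked_footprint_figure(details, portfolio, fp,
                                file.path(out, "figures",
                                          paste0("footprint_", fp, ".png")))
  }
  if (!is.null(damage))
    .sector_damage_figure(damage, file.path(out, "figures",
                                            "damage_by_sector.png"))
  yaml::write_yaml(c(list(package = "campusfp",
                          version = as.character(utils::packageVersion("campusfp")),
                          scenarios = portfolio$scenario), meta),
                   file.path(out, "run_meta.yaml"))
  invisible(out)
}
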