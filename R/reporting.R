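#' Goal-level gapfill summary table
#'
#' One row per goal (and an Index row): unweighted mean and SD of the
#' per-region gapfill percents, and their EEZ-area-weighted counterparts —
#' the two column groups of the standard global summary. Percents are on
#' the 0-100 reporting scale.
#'
#' @param region_gapfill data frame with `region_id`, one column per goal
#'   code and an `Index` column, holding gapfill percents (0-100).
#' @param registry a `region_registry` supplying `eez_area_km2`.
#' @return Data frame `goal`, `mean_pct`, `sd_pct`, `wmean_pct`, `wsd_pct`.
#' @export
goal_summary_table <- function(region_gapfill, registry) {
  areas <- registry$eez_area_km2[match(region_gapfill$region_id,
                                       registry$region_id)]
  if (any(is.na(areas))) {
    ogf_stop("region in gapfill table missing from registry", "ogf_report_error")
  }
  cols <- setdiff(names(region_gapfill), "region_id")
  cols <- c("Index", setdiff(cols, "Index"))
  out <- do.call(rbind, lapply(cols, function(g) {
    v <- region_gapfill[[g]]
    data.frame(goal = g,
               mean_pct = mean(v, na.rm = TRUE),
               sd_pct = stats::sd(v, na.rm = TRUE),
               wmean_pct = compute_global(v, areas),
               wsd_pct = weighted_sd(v, areas),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-layer gapfill percentages and their histogram
#'
#' For each layer's ledger, the percent of records that were gapfilled, plus
#' counts over bins of width 5 covering 0-100 (`[0,5), [5,10), ...,
#' [95,100]`).
#'
#' @param ledgers named list of `gapfill_ledger`s.
#' @return List: `per_layer` (data frame `layer_id`, `pct_gapfilled`) and
#'   `bins` (data frame `lower`, `upper`, `count`; counts sum to the number
#'   of layers).
#' @export
dataset_gapfill_histogram <- function(ledgers) {
  ids <- names(ledgers)
  if (is.null(ids)) ids <- paste0("layer_", seq_along(ledgers))
  pct <- vapply(ledgers, function(l) 100 * mean(l$gapfilled), 1.0)
  lower <- seq(0, 95, by = 5)
  upper <- lower + 5
  bin <- pmin(findInterval(pct, lower), length(lower))  # [95,100] closed above
  count <- tabulate(bin, nbins = length(lower))
  list(per_layer = data.frame(layer_id = ids, pct_gapfilled = unname(pct),
                              stringsAsFactors = FALSE),
       bins = data.frame(lower = lower, upper = upper, count = count))
}

#' Regression of region gapfill on size and territorial status
#'
#' Fits the per-region index gapfill percent (0-100) on `ln(eez_area_km2)`
#' and territorial status, and also the territory-only model, reporting
#' coefficients, p-values and R-squared for both nested fits.
#'
#' @param region_gapfill data frame with `region_id` and an index gapfill
#'   percent column (named `Index` or `gapfill_pct`).
#' @param registry a `region_registry`.
#' @return List of two fits (`full`, `territory_only`), each with
#'   `coefficients` (data frame term/estimate/p_value) and `r_squared`.
#' @export
gapfill_predictor_regression <- function(region_gapfill, registry) {
  gcol <- intersect(c("Index", "gapfill_pct"), names(region_gapfill))[1]
  if (is.na(gcol)) ogf_stop("no Index/gapfill_pct column", "ogf_report_error")
  i <- match(region_gapfill$region_id, registry$region_id)
  dat <- data.frame(gf = region_gapfill[[gcol]],
                    ln_area = log(registry$eez_area_km2[i]),
                    is_territory = registry$is_territory[i])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 4) ogf_stop("fewer than 4 regions", "ogf_report_error")
  tidy_fit <- function(f) {
    fit <- stats::lm(f, data = dat)
    sm <- summary(fit)
    list(coefficients = data.frame(term = rownames(sm$coefficients),
                                   estimate = sm$coefficients[, "Estimate"],
                                   p_value = sm$coefficients[, "Pr(>|t|)"],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
         r_squared = sm$r.squared)
  }
  list(full = tidy_fit(gf ~ ln_area + is_territory),
       territory_only = tidy_fit(gf ~ is_territory))
}

#' Write the standard report files for an assessment run
#'
#' Emits the choropleth-ready `region_gapfill.csv` (region by goal gapfill
#' percents), `summary_table.csv` (goal-level means and SDs),
#' `layer_gapfill.csv` (per-layer gapfill percents) and
#' `gapfill_regression.txt` (the size/territory regression), all on the
#' 0-100 reporting scale.
#'
#' @param assessment a [synthetic_assessment()]-style result list.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reports <- function(assessment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(assessment$region_gapfill,
                   file.path(dir, "region_gapfill.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(assessment$summary_table,
                   file.path(dir, "summary_table.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(assessment$layer_histogram$per_layer,
                   file.path(dir, "layer_gapfill.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(assessment$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE, na = "")
  rg <- assessment$regression
  txt <- c("Gapfill percent ~ ln(eez_area_km2) + is_territory",
           sprintf("  R-squared: %.4f", rg$full$r_squared),
           sprintf("  %-20s %12.4f  p = %.3g",
                   rg$full$coefficients$term, rg$full$coefficients$estimate,
                   rg$full$coefficients$p_value),
           "Gapfill percent ~ is_territory",
           sprintf("  R-squared: %.4f", rg$territory_only$r_squared),
           sprintf("  %-20s %12.4f  p = %.3g",
                   rg$territory_only$coefficients$term,
                   rg$territory_only$coefficients$estimate,
                   rg$territory_only$coefficients$p_value))
  writeLines(txt, file.path(dir, "gapfill_regression.txt"))
  invisible(dir)
}
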