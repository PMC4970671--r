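#' Composite FAO commodity gapfilling recipe
#'
#' For commodity harvest data reported as paired tonnes and export-value
#' layers keyed by (region, commodity, year): where tonnes is missing but
#' export value is present, tonnes is predicted from value with the
#' regression model chosen by [select_gapfill_model()] over a
#' country / geopolitical-region / global candidate chain (year as an
#' optional predictor); where both tonnes and value are missing, tonnes is
#' gapfilled as zero. The ledger distinguishes the two routes
#' (`covariate:<scale>` vs `zero_fill`).
#'
#' @param tonnes_layer `layer_table` with keys `region_id`, `category`,
#'   `year` (the layer being gapfilled).
#' @param value_layer `layer_table` with the same keys (the driving
#'   covariate; export value).
#' @param registry a `region_registry` (provides the georegion groupings).
#' @param candidates optional list of [candidate_model()]s with response
#'   `"tonnes"` and predictor `"value"`; defaults to with/without-year
#'   candidates at entity, georegion_l2 and global scales, requiring 4
#'   complete rows per model parameter.
#' @param fallback_chain ordered scales, finest first.
#' @return A [fill_result]; `diagnostics$selection` holds the per-entity
#'   model selection table for each commodity.
#' @export
fao_commodity_fill <- function(tonnes_layer, value_layer, registry,
                               candidates = NULL,
                               fallback_chain = c("entity", "georegion_l2",
                                                  "global")) {
  keys <- layer_keys(tonnes_layer)
  stopifnot(all(c("region_id", "category", "year") %in% keys),
            identical(sort(keys), sort(layer_keys(value_layer))))
  tn <- as.data.frame(tonnes_layer)
  vl <- as.data.frame(value_layer)
  names(vl)[names(vl) == "value"] <- "covariate_value"
  dat <- merge(tn, vl, by = keys, all.x = TRUE, sort = FALSE)
  dat <- dat[match(key_string(tn, keys), key_string(dat, keys)), , drop = FALSE]
  names(dat)[names(dat) == "value"] <- "tonnes"
  names(dat)[names(dat) == "covariate_value"] <- "value"
  ri <- match(dat$region_id, registry$region_id)
  dat$georegion_l2 <- registry$georegion_l2[ri]
  dat$georegion_l1 <- registry$georegion_l1[ri]

  if (is.null(candidates)) {
    candidates <- list()
    for (sc in fallback_chain) {
      for (yr in c(FALSE, TRUE)) {
        np <- 2L + as.integer(yr)
        candidates[[length(candidates) + 1L]] <-
          candidate_model("tonnes", "value", include_year = yr, scale = sc,
                          min_n = 4L * np)
      }
    }
  }

  both_missing <- is.na(dat$tonnes) & is.na(dat$value)
  need_model <- is.na(dat$tonnes) & !is.na(dat$value)
  vr <- value_range(tonnes_layer)
  method <- rep("none", nrow(dat))
  method[both_missing] <- "zero_fill"
  dat$tonnes[both_missing] <- 0

  sel_tabs <- list()
  for (cm in unique(dat$category[need_model])) {
    sub <- which(dat$category == cm)
    res <- select_gapfill_model(dat[sub, , drop = FALSE], candidates,
                                fallback_chain = fallback_chain,
                                entity_col = "region_id")
    pr <- res$predictions
    tgt <- sub[match(key_string(pr, keys), key_string(dat[sub, ], keys))]
    dat$tonnes[tgt] <- clamp(pr$prediction, vr[1], vr[2])
    scl <- res$selection$scale_used[match(pr$region_id, res$selection$entity)]
    method[tgt] <- sprintf("covariate:%s", scl)
    sel_tabs[[as.character(cm)]] <- res$selection
  }

  out <- dat[c(keys)]
  out$value <- dat$tonnes
  led <- dat[keys]
  led$gapfilled <- as.integer(method != "none")
  led$method <- method
  led$error <- NA_real_
  filled <- layer_table(out, layer_id = layer_id(tonnes_layer), keys = keys,
                        value_range = vr,
                        dimension_tag = attr(tonnes_layer, "dimension_tag"))
  fill_result(filled, gapfill_ledger(led, keys = keys,
                                     layer_id = layer_id(tonnes_layer)),
              diagnostics = list(selection = sel_tabs),
              original = tonnes_layer)
}
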