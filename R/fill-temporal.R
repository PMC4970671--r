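#' Temporal gapfilling by per-entity linear regression
#'
#' For each entity (a region, or region x category combination) with at
#' least `min_years` observed years, missing years are predicted from an
#' ordinary-least-squares fit of value on year. Predictions outside the
#' entity's observed year span are made only when `allow_extrapolation` is
#' `TRUE`; otherwise those observations are left missing and listed in
#' `diagnostics$skipped`. Predictions are clamped to the layer's declared
#' value range.
#'
#' @param layer a `layer_table` whose keys include `year`.
#' @param min_years minimum observed years per entity (>= 2).
#' @param allow_extrapolation permit predictions outside the observed span?
#' @return A [fill_result] with `method = "temporal"` for each filled value.
#'   An entity with missing values but fewer than `min_years` observed years
#'   is an error, so the caller can route it to another method.
#' @export
temporal_fill <- function(layer, min_years = 2, allow_extrapolation = FALSE) {
  keys <- layer_keys(layer)
  if (!"year" %in% keys) {
    ogf_stop("temporal_fill requires a 'year' key column", "ogf_fill_error")
  }
  stopifnot(min_years >= 2)
  df <- as.data.frame(layer)
  ent_keys <- setdiff(keys, "year")
  ent <- key_string(df, ent_keys)
  vr <- value_range(layer)
  method <- rep(NA_character_, nrow(df))
  skipped <- character(0)
  fits <- list()

  for (e in unique(ent[is.na(df$value)])) {
    rows <- which(ent == e)
    obs <- rows[!is.na(df$value[rows])]
    mis <- rows[is.na(df$value[rows])]
    if (length(obs) < min_years) {
      ogf_stop(sprintf("entity (%s): %d observed year(s) < min_years = %d",
                       key_label(df, ent_keys, rows[1]), length(obs), min_years),
               "ogf_fill_error")
    }
    fit <- stats::lm(value ~ year, data = df[obs, , drop = FALSE])
    span <- range(df$year[obs])
    for (i in mis) {
      if (!allow_extrapolation && (df$year[i] < span[1] || df$year[i] > span[2])) {
        skipped <- c(skipped, key_label(df, keys, i))
        next
      }
      df$value[i] <- clamp(unname(stats::predict(fit, df[i, , drop = FALSE])),
                           vr[1], vr[2])
      method[i] <- "temporal"
    }
    fits[[e]] <- stats::coef(fit)
  }

  led <- as.data.frame(layer)[keys]
  done <- !is.na(method)
  led$gapfilled <- ifelse(done, 1L, 0L)
  led$method <- ifelse(done, "temporal", "none")
  led$error <- NA_real_
  filled <- layer_table(df, layer_id = layer_id(layer), keys = keys,
                        value_range = vr,
                        dimension_tag = attr(layer, "dimension_tag"))
  fill_result(filled, gapfill_ledger(led, keys = keys,
                                     layer_id = layer_id(layer)),
              diagnostics = list(coefficients = fits, skipped = skipped),
              original = layer)
}

#' Taxonomic gapfilling by nearest-ancestor averaging
#'
#' Each target tip with a missing value is filled with the unweighted mean
#' of the valued tips under its nearest ancestor that has at least one
#' valued descendant tip other than the target — first conspecific
#' populations, then congeners, and so on up the ranks.
#'
#' @param tree data frame with one row per tip: ordered rank columns from
#'   root to tip (e.g. `order`, `family`, `genus`, `species`) and a `value`
#'   column (real or missing). Tip paths must be unique.
#' @param targets integer row indices, or a character vector matched against
#'   the tip (last rank) column; defaults to all tips with missing values.
#' @return A list: `values` (data frame of tip path + filled value),
#'   `ledger` records with `method = "taxonomic"`, and `diagnostics$rank`
#'   naming the ancestor rank used per target.
#' @export
taxonomic_fill <- function(tree, targets = NULL) {
  ranks <- setdiff(names(tree), "value")
  stopifnot(length(ranks) >= 1)
  tip_col <- ranks[length(ranks)]
  path <- key_string(tree, ranks)
  if (anyDuplicated(path)) ogf_stop("tip paths must be unique", "ogf_fill_error")
  if (all(is.na(tree$value))) {
    ogf_stop("no valued tip anywhere in the tree", "ogf_fill_error")
  }
  if (is.null(targets)) targets <- which(is.na(tree$value))
  if (is.character(targets)) targets <- which(tree[[tip_col]] %in% targets)
  if (any(!is.na(tree$value[targets]))) {
    ogf_stop("targets must be tips with missing values", "ogf_fill_error")
  }

  out <- tree[targets, , drop = FALSE]
  rank_used <- character(length(targets))
  # fills are computed from the original values only, so results are
  # independent of target order and never use another fill as a donor
  for (j in seq_along(targets)) {
    i <- targets[j]
    filled <- FALSE
    for (d in rev(seq_along(ranks) - 1L)) {        # deepest shared prefix first
      if (d == 0L) {
        donors <- which(!is.na(tree$value))
        lev <- "root"
      } else {
        pre <- key_string(tree, ranks[seq_len(d)])
        donors <- which(!is.na(tree$value) & pre == pre[i])
        lev <- ranks[d]
      }
      donors <- setdiff(donors, i)
      if (length(donors)) {
        out$value[j] <- mean(tree$value[donors])
        rank_used[j] <- lev
        filled <- TRUE
        break
      }
    }
    if (!filled) {
      ogf_stop(sprintf("no donors for tip '%s'", tree[[tip_col]][i]),
               "ogf_fill_error")
    }
  }
  ledger <- data.frame(out[ranks], gapfilled = 1L, method = "taxonomic",
                       error = NA_real_, stringsAsFactors = FALSE)
  list(values = out,
       ledger = gapfill_ledger(ledger, keys = ranks),
       diagnostics = list(rank = stats::setNames(rank_used, out[[tip_col]])))
}
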