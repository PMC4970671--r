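#' Propagate gapfill fractions (and scores) through a weight level
#'
#' The single aggregation primitive behind every level of the score and
#' gapfill calculation: a weighted mean of the inputs with weights
#' normalized to sum to 1. Applying it to scores reproduces the score
#' aggregation; applying it to per-input gapfill fractions with the *same*
#' weights yields the share of the aggregate that rests on gapfilled data.
#'
#' @param fractions numeric inputs (gapfill fractions in `[0, 1]`, or
#'   scores).
#' @param weights nonnegative weights, positive total.
#' @return The normalized-weight mean.
#' @export
propagate_gapfill <- function(fractions, weights = rep(1, length(fractions))) {
  stopifnot(length(fractions) == length(weights))
  wmean(fractions, weights)
}

#' Collapse a keyed layer to one value and gapfill fraction per region
#'
#' Layers keyed by category and/or year are reduced to a single value per
#' region: the most recent year in scope is kept, then a weighted mean over
#' categories (default equal weights). The parallel gapfill fraction is the
#' same-weights share of ledger-gapfilled observations among those used.
#'
#' @param layer a `layer_table` with no missing values in scope.
#' @param ledger the layer's `gapfill_ledger`.
#' @param category_weights optional named nonnegative weights by category.
#' @param count_assumed_zero reclassify `assumed_zero` records as gapfilled
#'   (sensitivity switch; default `FALSE`, mirroring the decision that
#'   confident zero assumptions are not gapfilling).
#' @return Data frame `region_id`, `value`, `gapfill_fraction`. Regions
#'   whose observations are all missing are dropped (callers route them to
#'   gapfilling rather than scoring them silently).
#' @export
collapse_layer <- function(layer, ledger = empty_ledger(layer),
                           category_weights = NULL,
                           count_assumed_zero = FALSE) {
  keys <- layer_keys(layer)
  df <- as.data.frame(layer)
  led <- as.data.frame(ledger)
  gf <- led$gapfilled == 1L |
    (count_assumed_zero & sub(":.*$", "", led$method) == "assumed_zero")
  df$gf <- as.numeric(gf[match(key_string(df, keys), key_string(led, keys))])
  if ("year" %in% keys) {
    grp <- key_string(df, setdiff(keys, "year"))
    # keep each entity's most recent year that has a value
    keep <- rep(FALSE, nrow(df))
    for (g in unique(grp)) {
      rows <- which(grp == g & !is.na(df$value))
      if (length(rows)) keep[rows[which.max(df$year[rows])]] <- TRUE
    }
    df <- df[keep, , drop = FALSE]
  } else {
    df <- df[!is.na(df$value), , drop = FALSE]
  }
  w <- if ("category" %in% keys && !is.null(category_weights)) {
    ww <- category_weights[as.character(df$category)]
    if (any(is.na(ww))) ogf_stop("category without declared weight",
                                 "ogf_score_error")
    ww
  } else rep(1, nrow(df))
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$region_id),
    function(rows) data.frame(
      region_id = df$region_id[rows[1]],
      value = propagate_gapfill(df$value[rows], w[rows]),
      gapfill_fraction = propagate_gapfill(df$gf[rows], w[rows]))))
  out <- out[order(out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# weighted combination of several collapsed layers into one dimension
combine_collapsed <- function(collapsed_list, weights, lo, hi, what) {
  stopifnot(length(collapsed_list) == length(weights))
  if (!length(collapsed_list)) {
    ogf_stop(sprintf("no layers supplied for %s", what), "ogf_score_error")
  }
  ids <- sort(unique(unlist(lapply(collapsed_list, `[[`, "region_id"))))
  val <- gfr <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    v <- g <- w <- numeric(0)
    for (j in seq_along(collapsed_list)) {
      i <- match(ids[k], collapsed_list[[j]]$region_id)
      if (!is.na(i)) {
        v <- c(v, collapsed_list[[j]]$value[i])
        g <- c(g, collapsed_list[[j]]$gapfill_fraction[i])
        w <- c(w, weights[j])
      }
    }
    if (!length(v) || sum(w) <= 0) {
      ogf_stop(sprintf("region %s: no usable %s layer", ids[k], what),
               "ogf_score_error")
    }
    val[k] <- clamp(propagate_gapfill(v, w), lo, hi)
    gfr[k] <- propagate_gapfill(g, w)
  }
  data.frame(region_id = ids, value = val, gapfill_fraction = gfr)
}

#' Combine collapsed status layers into a per-region status score
#'
#' Weighted mean of the (pre-rescaled, 0-1) status layer values, clamped to
#' `[0, 1]`, with the gapfill fraction propagated through the same weights.
#'
#' @param collapsed_list list of [collapse_layer()] outputs.
#' @param weights nonnegative layer weights (default equal).
#' @return Data frame `region_id`, `value`, `gapfill_fraction`.
#' @export
compute_status <- function(collapsed_list,
                           weights = rep(1, length(collapsed_list))) {
  combine_collapsed(collapsed_list, weights, 0, 1, "status")
}

#' @rdname compute_status
#' @details `compute_dimension_aggregate` is the same combination applied to
#'   pressure or resilience layers (also on the 0-1 scale).
#' @export
compute_dimension_aggregate <- function(collapsed_list,
                                        weights = rep(1, length(collapsed_list))) {
  combine_collapsed(collapsed_list, weights, 0, 1, "pressure/resilience")
}

#' Trend: five-year status slope projected five years ahead
#'
#' Ordinary-least-squares slope of status (0-1 scale) on calendar year over
#' the five most recent years, multiplied by five, clamped to `[-1, 1]`.
#' The year regressor is centered on its mean (slope-identical, numerically
#' stable).
#'
#' @param status_series numeric status values (0-1).
#' @param years calendar years (default consecutive).
#' @return Trend in `[-1, 1]`.
#' @export
compute_trend <- function(status_series,
                          years = seq_along(status_series)) {
  stopifnot(length(status_series) == length(years))
  ok <- !is.na(status_series)
  status_series <- status_series[ok]
  years <- years[ok]
  if (length(status_series) < 5) {
    ogf_stop("trend needs at least 5 years of status", "ogf_score_error")
  }
  keep <- order(years, decreasing = TRUE)[1:5]
  y <- status_series[keep]
  x <- years[keep] - mean(years[keep])
  slope <- sum(x * y) / sum(x^2)
  clamp(5 * slope, -1, 1)
}

#' Goal score from its four dimensions
#'
#' The projected future state is
#' `status * (1 + beta * trend + (1 - beta) * (resilience - pressure))`,
#' clamped to `[0, 1]`; the goal score is the average of current status and
#' future state. The goal's gapfill fraction is the component-weight mean of
#' the four dimensions' gapfill fractions.
#'
#' @param status,trend,pressure,resilience per-region dimension scores
#'   (status/pressure/resilience on 0-1, trend on -1..1); vectors recycle.
#' @param beta trend balance in `[0, 1]`.
#' @param gf_status,gf_trend,gf_pressure,gf_resilience dimension gapfill
#'   fractions.
#' @param component_weights attribution weights over the four dimensions.
#' @return Data frame `status`, `future`, `score`, `gapfill_fraction`.
#' @export
compute_goal_score <- function(status, trend, pressure, resilience,
                               beta = 0.67,
                               gf_status = 0, gf_trend = 0, gf_pressure = 0,
                               gf_resilience = 0,
                               component_weights = default_component_weights(beta)) {
  if (any(is.na(c(status, trend, pressure, resilience)))) {
    ogf_stop("all four dimensions must be defined", "ogf_score_error")
  }
  future <- clamp(status * (1 + beta * trend +
                              (1 - beta) * (resilience - pressure)), 0, 1)
  score <- (status + future) / 2
  gf <- mapply(function(a, b, c, d)
    propagate_gapfill(c(a, b, c, d), component_weights),
    gf_status, gf_trend, gf_pressure, gf_resilience)
  data.frame(status = status, future = future, score = score,
             gapfill_fraction = as.numeric(gf))
}

#' Region index: weighted mean of goal scores
#'
#' Goals with zero weight (e.g. a goal excluded from an assessment) are
#' dropped symmetrically from both the score and the gapfill average.
#'
#' @param goal_scores numeric goal scores (0-1).
#' @param goal_gapfill goal gapfill fractions.
#' @param goal_weights nonnegative weights (default equal).
#' @return List with `index` and `gapfill_fraction`.
#' @export
compute_index <- function(goal_scores, goal_gapfill,
                          goal_weights = rep(1, length(goal_scores))) {
  keep <- goal_weights > 0
  if (!any(keep)) ogf_stop("no goals with positive weight", "ogf_score_error")
  list(index = propagate_gapfill(goal_scores[keep], goal_weights[keep]),
       gapfill_fraction = propagate_gapfill(goal_gapfill[keep],
                                            goal_weights[keep]))
}

#' EEZ-area-weighted global aggregate
#'
#' @param values per-region scores or gapfill percents.
#' @param areas per-region EEZ areas (km2); must be present wherever a value
#'   is.
#' @return The area-weighted mean.
#' @export
compute_global <- function(values, areas) {
  if (any(is.na(areas[!is.na(values)]))) {
    ogf_stop("EEZ area missing for a scored region", "ogf_score_error")
  }
  ok <- !is.na(values)
  wmean(values[ok], areas[ok])
}

#' Weighted standard deviation
#'
#' Population-style weighted SD, `sqrt(sum(w * (x - xbar_w)^2) / sum(w))`,
#' as used for the spread of EEZ-area-weighted scores.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, positive total.
#' @return Nonnegative scalar.
#' @export
weighted_sd <- function(values, weights = rep(1, length(values))) {
  ok <- !is.na(values)
  values <- values[ok]
  weights <- weights[ok]
  m <- wmean(values, weights)
  sqrt(sum(weights * (values - m)^2) / sum(weights))
}
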