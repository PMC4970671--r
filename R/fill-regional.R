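#' Regional-mean gapfilling with hierarchical fallback
#'
#' Fills each missing observation with the mean (or median) of the
#' non-missing values of donor regions sharing the same non-region keys
#' (category, year), walking an ordered chain of registry groupings — e.g.
#' neighbors, then the higher-resolution geopolitical region, then the
#' lower-resolution one, then global — and using the first level that has at
#' least `min_n` donors. The global level is always terminal: it fills from
#' any donor at all, and only a key with zero donors anywhere is an error.
#'
#' @param layer a `layer_table`.
#' @param registry a `region_registry`.
#' @param scale_chain ordered character vector of grouping levels, a subset
#'   of `c("neighbors", "georegion_l2", "georegion_l1", "global")`.
#'   `"global"` is appended if absent.
#' @param statistic `"mean"` or `"median"`.
#' @param min_n minimum donor count required at a non-global level.
#' @param weights optional named numeric vector of nonnegative per-region
#'   donor weights (names are region ids, e.g. habitat areas); only
#'   supported with `statistic = "mean"`.
#' @param donor_filter optional function `(donor_region_ids, target_region_id,
#'   registry) -> region_ids` restricting the donor pool (the donor-pool
#'   composition is configurable; e.g. drop sibling territories).
#'
#' @return A [fill_result]; the ledger method records the level used, e.g.
#'   `regional_mean:georegion_l2`, and `diagnostics$fills` reports the donor
#'   count and level per filled key.
#' @export
regional_stat_fill <- function(layer, registry,
                               scale_chain = c("georegion_l2", "georegion_l1",
                                               "global"),
                               statistic = c("mean", "median"), min_n = 3,
                               weights = NULL, donor_filter = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(min_n >= 1)
  bad_lv <- setdiff(scale_chain,
                    c("neighbors", "georegion_l2", "georegion_l1", "global"))
  if (length(bad_lv)) {
    ogf_stop(sprintf("unknown scale_chain level(s): %s",
                     paste(bad_lv, collapse = ", ")), "ogf_fill_error")
  }
  if (!"global" %in% scale_chain) scale_chain <- c(scale_chain, "global")
  if (!is.null(weights)) {
    if (statistic == "median") {
      ogf_stop("weights are only supported with statistic = 'mean'",
               "ogf_fill_error")
    }
    if (any(weights < 0)) ogf_stop("negative donor weight", "ogf_fill_error")
  }

  keys <- layer_keys(layer)
  other <- setdiff(keys, "region_id")
  df <- as.data.frame(layer)
  # stratum = the non-region key combination a donor must share
  stratum <- if (length(other)) key_string(df, other) else rep("", nrow(df))
  ridx <- match(df$region_id, registry$region_id)

  group_ids <- function(level, target_region) {
    i <- match(target_region, registry$region_id)
    ids <- switch(level,
      neighbors = registry$neighbors[[i]],
      georegion_l2 = registry$region_id[
        registry$georegion_l2 == registry$georegion_l2[i]],
      georegion_l1 = registry$region_id[
        registry$georegion_l1 == registry$georegion_l1[i]],
      global = registry$region_id)
    ids <- setdiff(ids, target_region)
    if (!is.null(donor_filter)) ids <- donor_filter(ids, target_region, registry)
    ids
  }

  miss_i <- which(is.na(df$value))
  fills <- vector("list", length(miss_i))
  method <- rep(NA_character_, nrow(df))
  for (j in seq_along(miss_i)) {
    i <- miss_i[j]
    filled <- FALSE
    for (level in scale_chain) {
      donors <- which(!is.na(df$value) & stratum == stratum[i] &
                        df$region_id %in% group_ids(level, df$region_id[i]))
      n_don <- length(donors)
      enough <- if (level == "global") n_don >= 1L else n_don >= min_n
      if (!enough) next
      v <- df$value[donors]
      est <- if (statistic == "median") {
        stats::median(v)
      } else if (is.null(weights)) {
        mean(v)
      } else {
        w <- weights[as.character(df$region_id[donors])]
        if (any(is.na(w))) {
          ogf_stop(sprintf("no donor weight for region(s) %s",
                           paste(df$region_id[donors][is.na(w)], collapse = ", ")),
                   "ogf_fill_error")
        }
        wmean(v, w)
      }
      df$value[i] <- est
      method[i] <- sprintf("regional_%s:%s", statistic, level)
      fills[[j]] <- data.frame(key = key_label(df, keys, i), level = level,
                               n_donors = n_don, estimate = est,
                               stringsAsFactors = FALSE)
      filled <- TRUE
      break
    }
    if (!filled) {
      ogf_stop(sprintf("no donors at any level for (%s)", key_label(df, keys, i)),
               "ogf_fill_error")
    }
  }

  led <- as.data.frame(layer)[keys]
  led$gapfilled <- ifelse(is.na(layer$value), 1L, 0L)
  led$method <- ifelse(is.na(layer$value), method, "none")
  led$error <- NA_real_
  filled_layer <- layer_table(df, layer_id = layer_id(layer), keys = keys,
                              value_range = value_range(layer),
                              dimension_tag = attr(layer, "dimension_tag"))
  fill_result(filled_layer,
              gapfill_ledger(led, keys = keys, layer_id = layer_id(layer)),
              diagnostics = list(fills = do.call(rbind, fills)),
              original = layer)
}

#' Disaggregate a group value to its member regions
#'
#' When a value is reported for a group of regions (e.g. a set of
#' territories previously scored together), either every member is assigned
#' the group value (`mode = "copy"`), or the group total is split
#' proportionally to the members' EEZ areas (`mode = "area_weighted"`, so
#' member shares sum to the group total).
#'
#' @param group_value the value reported for the group.
#' @param members subset of a `region_registry` (the member regions).
#' @param mode `"copy"` or `"area_weighted"`.
#' @param group_total_basis the total to split in `area_weighted` mode
#'   (defaults to `group_value`).
#' @return A list with `values` (data frame `region_id`, `value`) and
#'   `ledger` records with `method = "disaggregation"`.
#' @export
disaggregate_group <- function(group_value, members,
                               mode = c("copy", "area_weighted"),
                               group_total_basis = group_value) {
  mode <- match.arg(mode)
  if (nrow(members) == 0L) {
    ogf_stop("empty member list", "ogf_fill_error")
  }
  value <- if (mode == "copy") {
    rep(group_value, nrow(members))
  } else {
    a <- members$eez_area_km2
    if (any(is.na(a)) || any(a <= 0)) {
      ogf_stop("area_weighted disaggregation requires positive eez_area_km2",
               "ogf_fill_error")
    }
    group_total_basis * a / sum(a)
  }
  values <- data.frame(region_id = members$region_id, value = value)
  ledger <- data.frame(region_id = members$region_id, gapfilled = 1L,
                       method = "disaggregation", error = NA_real_)
  list(values = values,
       ledger = gapfill_ledger(ledger, keys = "region_id"))
}

#' Fill missing observations with zero
#'
#' Sets selected missing values to 0, either as explicit gapfilling
#' (`method = "zero_fill"`, `gapfilled = 1`) or as a confident assumption
#' that absence means zero (`as_gapfill = FALSE`:
#' `method = "assumed_zero"`, `gapfilled = 0`, not counted as gapfilling).
#'
#' @param layer a `layer_table`.
#' @param scope logical vector over rows, or a predicate function on the
#'   layer data frame, selecting the missing observations to fill; default
#'   selects every missing value. Selecting a non-missing observation is an
#'   error (zero-filling never overwrites data).
#' @param as_gapfill logical; count the fills as gapfilling?
#' @return A [fill_result].
#' @export
zero_fill <- function(layer, scope = NULL, as_gapfill = TRUE) {
  df <- as.data.frame(layer)
  sel <- if (is.null(scope)) is.na(df$value)
         else if (is.function(scope)) scope(df)
         else as.logical(scope)
  stopifnot(length(sel) == nrow(df))
  if (any(sel & !is.na(df$value))) {
    ogf_stop("zero_fill scope selects a non-missing observation",
             "ogf_fill_error")
  }
  keys <- layer_keys(layer)
  df$value[sel] <- 0
  led <- df[keys]
  led$gapfilled <- ifelse(sel & as_gapfill, 1L, 0L)
  led$method <- ifelse(sel, if (as_gapfill) "zero_fill" else "assumed_zero",
                       "none")
  led$error <- NA_real_
  vr <- value_range(layer)
  if (any(sel) && (vr[1] > 0 || vr[2] < 0)) {
    ogf_stop("value_range does not contain 0; zero_fill not applicable",
             "ogf_fill_error")
  }
  filled <- layer_table(df, layer_id = layer_id(layer), keys = keys,
                        value_range = vr,
                        dimension_tag = attr(layer, "dimension_tag"))
  fill_result(filled, gapfill_ledger(led, keys = keys,
                                     layer_id = layer_id(layer)),
              diagnostics = list(n_filled = sum(sel), as_gapfill = as_gapfill),
              original = layer)
}
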