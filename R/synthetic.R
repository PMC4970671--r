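#' Configuration for the synthetic-data generators
#'
#' One object collects every knob of the seeded generators. Defaults mirror
#' the shape of the global assessment the engine targets: 220 regions in
#' 22 higher- / 7 lower-resolution geopolitical regions, about 40%
#' territorial jurisdictions, log-normal EEZ areas with territories
#' systematically smaller, and territory-biased missingness.
#'
#' @param seed root integer seed; every generator derives its own substream
#'   from it by stable name hashing, so adding a generator never perturbs
#'   existing fixtures.
#' @param n_regions number of regions.
#' @param territory_fraction expected share of territorial jurisdictions.
#' @param n_georegions_l2,n_georegions_l1 counts of the nested geopolitical
#'   groupings (`l2 >= l1`).
#' @param area_meanlog,area_sdlog log-normal EEZ-area parameters (km2) for
#'   countries.
#' @param territory_area_shift added to `area_meanlog` for territories
#'   (negative: territories are smaller).
#' @param missing_mechanism `"random"`, `"territory_biased"` or
#'   `"size_biased"`.
#' @param missing_rate overall missingness rate (random / size-biased
#'   center).
#' @param missing_rate_territory,missing_rate_country rates for the
#'   territory-biased mechanism.
#' @param size_bias_strength log-odds of missingness added per SD decrease
#'   in log area (size-biased mechanism).
#' @param group_effect_sd SD of the georegion-level layer means.
#' @param noise_sd within-region observation noise SD on the 0-1 scale.
#' @param n_years years per status time series (>= 5).
#' @param slope_mean,slope_sd distribution of true per-region yearly status
#'   slopes.
#' @param cv_n_entities,cv_n_per_entity,cv_n_georegions size of the
#'   cross-validation dataset.
#' @param cv_slope_mean,cv_slope_sd,cv_intercept_sd coefficient
#'   distributions for the covariate-response relation.
#' @param cv_year_coef year effect on the response (0 = no year signal).
#' @param cv_noise_sd response noise SD (default well under 10% of the
#'   covariate signal).
#' @param cv_missing_rate share of rows per entity with a masked response.
#' @param grid_nrow,grid_ncol,grid_n_regions,grid_block size of the grid
#'   fixture and its contiguous missing block.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_regions = 220L,
                         territory_fraction = 0.4,
                         n_georegions_l2 = 22L, n_georegions_l1 = 7L,
                         area_meanlog = 11, area_sdlog = 1.8,
                         territory_area_shift = -2.5,
                         missing_mechanism = c("territory_biased", "random",
                                               "size_biased"),
                         missing_rate = 0.2,
                         missing_rate_territory = 0.5,
                         missing_rate_country = 0.1,
                         size_bias_strength = 1,
                         group_effect_sd = 0.15, noise_sd = 0.05,
                         n_years = 6L, slope_mean = 0, slope_sd = 0.02,
                         cv_n_entities = 20L, cv_n_per_entity = 12L,
                         cv_n_georegions = 5L,
                         cv_slope_mean = 1.5, cv_slope_sd = 0.5,
                         cv_intercept_sd = 1,
                         cv_year_coef = 0, cv_noise_sd = 0.3,
                         cv_missing_rate = 0.1,
                         grid_nrow = 10L, grid_ncol = 10L,
                         grid_n_regions = 4L, grid_block = c(2L, 2L)) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_georegions_l2 >= n_georegions_l1, n_years >= 5,
            territory_fraction >= 0, territory_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            missing_rate_territory >= 0, missing_rate_territory <= 1,
            missing_rate_country >= 0, missing_rate_country <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# derive a reproducible integer substream seed < 2^31 from seed + name
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

with_substream <- function(config, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config$seed, name))
  force(expr)
}

#' Generate a synthetic region registry
#'
#' Regions are spread over the configured geopolitical groupings (each
#' higher-resolution georegion gets at least one non-territory country, so
#' every territory can be administered from within its georegion); EEZ areas
#' are log-normal with territories shifted smaller; neighbors are the
#' adjacent regions within the same georegion.
#'
#' @param config a [synth_config()].
#' @return A `region_registry`.
#' @export
make_registry <- function(config) {
  with_substream(config, "registry", {
    n <- config$n_regions
    l2_codes <- sprintf("G%02d", seq_len(config$n_georegions_l2))
    l1_of_l2 <- sprintf("R%d", rep_len(seq_len(config$n_georegions_l1),
                                       config$n_georegions_l2))
    # one guaranteed country per l2, remaining regions spread at random
    l2 <- c(l2_codes, sample(l2_codes, n - length(l2_codes), replace = TRUE))
    is_terr <- c(rep(FALSE, length(l2_codes)),
                 stats::runif(n - length(l2_codes)) < config$territory_fraction)
    admin <- rep(NA_integer_, n)
    for (i in which(is_terr)) {
      countries <- which(!is_terr & l2 == l2[i])
      admin[i] <- if (length(countries) == 1L) countries else
        sample(countries, 1L)
    }
    area <- stats::rlnorm(n, config$area_meanlog +
                            ifelse(is_terr, config$territory_area_shift, 0),
                          config$area_sdlog)
    neighbors <- lapply(seq_len(n), function(i) {
      sibs <- setdiff(which(l2 == l2[i]), i)
      if (!length(sibs)) return(integer(0))
      ord <- sibs[order(abs(sibs - i))]
      utils::head(ord, 2L)
    })
    region_registry(seq_len(n),
                    name = sprintf("region_%03d", seq_len(n)),
                    is_territory = is_terr, admin_country_id = admin,
                    georegion_l2 = l2,
                    georegion_l1 = l1_of_l2[match(l2, l2_codes)],
                    eez_area_km2 = area, neighbors = neighbors)
  })
}

missingness_mask <- function(registry, config) {
  n <- nrow(registry)
  p <- switch(config$missing_mechanism,
    random = rep(config$missing_rate, n),
    territory_biased = ifelse(registry$is_territory,
                              config$missing_rate_territory,
                              config$missing_rate_country),
    size_biased = {
      z <- scale(log(registry$eez_area_km2))[, 1]
      stats::plogis(stats::qlogis(clamp(config$missing_rate, 1e-6, 1 - 1e-6)) -
                      config$size_bias_strength * z)
    })
  stats::runif(n) < p
}

#' Generate a synthetic data layer with known ground truth
#'
#' Values are a georegion-level mean plus noise on the 0-1 scale; the
#' missingness mask follows the configured mechanism. The complete ground
#' truth is returned alongside the masked layer so the recovery error of
#' any gapfilling method can be scored without external input.
#'
#' @param registry a `region_registry`.
#' @param config a [synth_config()].
#' @param layer_id name for the generated layer.
#' @param stream extra substream label, so multiple distinct layers can be
#'   drawn from one config.
#' @return List: `truth` (complete `layer_table`), `masked` (with values
#'   removed), `mask` (logical), `group_means` (named by georegion code).
#' @export
make_layer <- function(registry, config, layer_id = "synthetic_layer",
                       stream = layer_id) {
  with_substream(config, paste0("layer/", stream), {
    l2 <- sort(unique(registry$georegion_l2))
    means <- clamp(stats::rnorm(length(l2), 0.5, config$group_effect_sd),
                   0.05, 0.95)
    names(means) <- l2
    v <- clamp(means[registry$georegion_l2] +
                 stats::rnorm(nrow(registry), 0, config$noise_sd), 0, 1)
    truth <- layer_table(data.frame(region_id = registry$region_id,
                                    value = unname(v)),
                         layer_id = layer_id)
    mask <- missingness_mask(registry, config)
    masked_df <- as.data.frame(truth)
    masked_df$value[mask] <- NA_real_
    # a layer must retain at least one observation
    if (all(mask)) masked_df$value[1] <- v[1]
    list(truth = truth,
         masked = layer_table(masked_df, layer_id = layer_id),
         mask = mask, group_means = means)
  })
}

#' Generate per-region status time series with known slopes
#'
#' @param registry a `region_registry`.
#' @param config a [synth_config()]; `n_years`, `slope_mean`, `slope_sd`,
#'   `noise_sd` apply.
#' @param stream extra substream label.
#' @param start_year first calendar year.
#' @return List: `series` (data frame `region_id`, `year`, `value`) and
#'   `slopes` (true yearly slope per region).
#' @export
make_timeseries <- function(registry, config, stream = "timeseries",
                            start_year = 2010L) {
  with_substream(config, paste0("timeseries/", stream), {
    years <- start_year + seq_len(config$n_years) - 1L
    slopes <- stats::rnorm(nrow(registry), config$slope_mean, config$slope_sd)
    series <- do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
      v <- clamp(0.5 + slopes[i] * (years - mean(years)) +
                   stats::rnorm(length(years), 0, config$noise_sd), 0, 1)
      data.frame(region_id = registry$region_id[i], year = years, value = v)
    }))
    list(series = series,
         slopes = stats::setNames(slopes, registry$region_id))
  })
}

#' Generate a covariate/response dataset with a known generating scale
#'
#' The response is a linear function of the covariate whose coefficients
#' vary at the declared scale — per entity, per georegion, or not at all
#' (global) — plus an optional year effect and noise. A share of each
#' entity's responses is masked, and the ground truth is returned.
#'
#' @param config a [synth_config()].
#' @param true_scale `"entity"`, `"georegion"` or `"global"`.
#' @return List: `data` (with `region_id`, `georegion_l2`, `year`, `value`
#'   covariate and masked `tonnes` response), `truth` (unmasked responses),
#'   `coefficients` (the generating slopes/intercepts).
#' @export
make_cv_dataset <- function(config,
                            true_scale = c("entity", "georegion", "global")) {
  true_scale <- match.arg(true_scale)
  with_substream(config, paste0("cv/", true_scale), {
    ne <- config$cv_n_entities
    np <- config$cv_n_per_entity
    geo <- sprintf("G%02d", rep_len(seq_len(config$cv_n_georegions), ne))
    slopes <- switch(true_scale,
      entity = stats::rnorm(ne, config$cv_slope_mean, config$cv_slope_sd),
      georegion = stats::rnorm(config$cv_n_georegions, config$cv_slope_mean,
                               config$cv_slope_sd)[rep_len(
                                 seq_len(config$cv_n_georegions), ne)],
      global = rep(config$cv_slope_mean, ne))
    icepts <- switch(true_scale,
      entity = stats::rnorm(ne, 0, config$cv_intercept_sd),
      georegion = stats::rnorm(config$cv_n_georegions, 0,
                               config$cv_intercept_sd)[rep_len(
                                 seq_len(config$cv_n_georegions), ne)],
      global = rep(0, ne))
    dat <- do.call(rbind, lapply(seq_len(ne), function(i) {
      x <- stats::runif(np, 1, 10)
      year <- 2010L + (seq_len(np) - 1L) %% 4L
      y <- icepts[i] + slopes[i] * x +
        config$cv_year_coef * (year - 2012) +
        stats::rnorm(np, 0, config$cv_noise_sd)
      data.frame(region_id = i, georegion_l2 = geo[i], year = year,
                 value = x, tonnes = y, stringsAsFactors = FALSE)
    }))
    truth <- dat$tonnes
    n_mask <- max(1L, floor(np * config$cv_missing_rate))
    for (i in seq_len(ne)) {
      rows <- which(dat$region_id == i)
      dat$tonnes[sample(rows, n_mask)] <- NA_real_
    }
    list(data = dat, truth = truth,
         coefficients = data.frame(entity = seq_len(ne), slope = slopes,
                                   intercept = icepts))
  })
}

#' Generate a grid layer with a known missing block
#'
#' A smooth value surface over rectangular region strips, with one
#' contiguous missing block at a seeded location.
#'
#' @param config a [synth_config()].
#' @return List: `grid` (a [grid_layer()] with the block masked), `truth`
#'   (complete value matrix), `block` (row/col ranges of the mask).
#' @export
make_grid <- function(config) {
  with_substream(config, "grid", {
    nr <- config$grid_nrow
    nc <- config$grid_ncol
    vals <- outer(seq_len(nr), seq_len(nc), function(i, j) i + j / nc) +
      matrix(stats::rnorm(nr * nc, 0, 0.1), nr, nc)
    strip <- ceiling(seq_len(nc) / (nc / config$grid_n_regions))
    region_mask <- matrix(rep(pmin(strip, config$grid_n_regions), each = nr),
                          nr, nc)
    br <- config$grid_block[1]
    bc <- config$grid_block[2]
    r0 <- sample(seq_len(nr - br + 1L), 1L)
    c0 <- sample(seq_len(nc - bc + 1L), 1L)
    miss <- matrix(FALSE, nr, nc)
    miss[r0:(r0 + br - 1L), c0:(c0 + bc - 1L)] <- TRUE
    masked <- vals
    masked[miss] <- NA_real_
    list(grid = grid_layer(masked, miss, region_mask), truth = vals,
         block = list(rows = r0:(r0 + br - 1L), cols = c0:(c0 + bc - 1L)))
  })
}
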