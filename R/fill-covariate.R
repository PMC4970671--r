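#' Covariate gapfilling by ordinary least squares
#'
#' Fills missing layer values from an OLS regression on correlated
#' predictors (e.g. GDP with a geopolitical-region intercept), fit on the
#' complete rows and used to predict the missing ones. Predictions are
#' clamped to the layer's declared value range.
#'
#' @param layer a `layer_table`.
#' @param covariates data frame carrying the predictor columns, aligned to
#'   the layer by their shared key columns.
#' @param model_spec a formula of the form `value ~ predictors`, possibly
#'   including a categorical grouping term.
#' @param min_train_per_param minimum complete training rows required per
#'   model parameter (default 4).
#' @return A [fill_result] with `method = "covariate"`;
#'   `diagnostics` holds the coefficients, `r_squared` and training `n`.
#'   Errors: rank-deficient design (naming the collinear terms), a factor
#'   level present only among rows to predict, or too few training rows —
#'   all signalled so the caller can fall back to another method.
#' @export
covariate_fill <- function(layer, covariates, model_spec = value ~ .,
                           min_train_per_param = 4) {
  keys <- layer_keys(layer)
  df <- as.data.frame(layer)
  shared <- intersect(keys, names(covariates))
  if (!length(shared)) {
    ogf_stop("covariates share no key column with the layer", "ogf_fill_error")
  }
  dat <- merge(df, covariates, by = shared, all.x = TRUE, sort = FALSE)
  dat <- dat[match(key_string(df, keys), key_string(dat, keys)), , drop = FALSE]

  pred_vars <- setdiff(all.vars(model_spec), "value")
  if (identical(all.vars(model_spec), c("value", "."))) {
    pred_vars <- setdiff(names(covariates), shared)
    model_spec <- stats::reformulate(pred_vars, response = "value")
  }
  absent <- setdiff(pred_vars, names(dat))
  if (length(absent)) {
    ogf_stop(sprintf("predictor(s) not in covariates: %s",
                     paste(absent, collapse = ", ")), "ogf_fill_error")
  }
  mis <- is.na(dat$value)
  cov_miss <- mis & !stats::complete.cases(dat[pred_vars])
  if (any(cov_miss)) {
    ogf_stop(sprintf("covariates missing for targeted key (%s)",
                     key_label(dat, keys, which(cov_miss)[1])), "ogf_fill_error")
  }
  train <- dat[!mis & stats::complete.cases(dat[pred_vars]), , drop = FALSE]

  fit <- stats::lm(model_spec, data = train)
  p <- length(stats::coef(fit))
  if (fit$rank < p) {
    ogf_stop(sprintf("rank-deficient design; collinear term(s): %s",
                     paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                           collapse = ", ")), "ogf_fill_error")
  }
  if (nrow(train) < max(p + 2, min_train_per_param * p)) {
    ogf_stop(sprintf("too few complete training rows (%d) for %d parameters",
                     nrow(train), p), "ogf_fill_error")
  }
  # factor levels unseen in training cannot be predicted
  for (v in pred_vars) {
    if (is.character(dat[[v]]) || is.factor(dat[[v]])) {
      unseen <- setdiff(unique(as.character(dat[[v]][mis])),
                        unique(as.character(train[[v]])))
      if (length(unseen)) {
        ogf_stop(sprintf("level(s) of %s absent from training: %s", v,
                         paste(unseen, collapse = ", ")), "ogf_fill_error")
      }
    }
  }
  vr <- value_range(layer)
  df$value[mis] <- clamp(unname(stats::predict(fit, dat[mis, , drop = FALSE])),
                         vr[1], vr[2])

  led <- as.data.frame(layer)[keys]
  led$gapfilled <- ifelse(mis, 1L, 0L)
  led$method <- ifelse(mis, "covariate", "none")
  led$error <- NA_real_
  filled <- layer_table(df, layer_id = layer_id(layer), keys = keys,
                        value_range = vr,
                        dimension_tag = attr(layer, "dimension_tag"))
  fill_result(filled, gapfill_ledger(led, keys = keys,
                                     layer_id = layer_id(layer)),
              diagnostics = list(coefficients = stats::coef(fit),
                                 r_squared = summary(fit)$r.squared,
                                 n_train = nrow(train)),
              original = layer)
}

#' Grid layers and nearest-donor interpolation
#'
#' A grid layer is a small 2-D raster: a numeric value matrix, a logical
#' mask of unusable cells, and an integer matrix assigning each cell to a
#' region (0 = outside all regions).
#'
#' @param values numeric matrix.
#' @param missing_mask logical matrix, `TRUE` where the value is unusable.
#' @param region_mask integer matrix of region ids (0 outside all regions).
#' @return A `grid_layer` object.
#' @export
grid_layer <- function(values, missing_mask = is.na(values),
                       region_mask = matrix(1L, nrow(values), ncol(values))) {
  stopifnot(identical(dim(values), dim(missing_mask)),
            identical(dim(values), dim(region_mask)))
  structure(list(values = values, missing_mask = missing_mask,
                 region_mask = matrix(as.integer(region_mask), nrow(values))),
            class = "grid_layer")
}

#' Fill missing grid cells from the nearest valued cell
#'
#' Each masked cell takes the value of the nearest non-missing cell
#' (Euclidean distance on cell row/column indices; ties broken by the
#' row-major order of the donors), and the share of gapfilled cells is
#' summarized per region.
#'
#' @param grid a [grid_layer()].
#' @param method interpolation method; only `"nearest_donor"`.
#' @return A list: `filled` (the completed `grid_layer`) and `region_pct`
#'   (data frame `region_id`, `pct_gapfilled` = 100 x filled cells / cells
#'   of the region).
#' @export
grid_fill <- function(grid, method = "nearest_donor") {
  method <- match.arg(method)
  stopifnot(inherits(grid, "grid_layer"))
  m <- grid$missing_mask
  if (all(m)) ogf_stop("all grid cells missing", "ogf_fill_error")
  nr <- nrow(grid$values)
  # row-major donor enumeration fixes the tie-break order
  cell_rc <- function(idx) cbind((idx - 1L) %/% ncol(grid$values) + 1L,
                                 (idx - 1L) %% ncol(grid$values) + 1L)
  rowmajor <- which(t(!m)) # indices in row-major order
  donors <- cell_rc(rowmajor)
  vals <- grid$values
  for (idx in which(t(m))) {
    rc <- cell_rc(idx)
    d2 <- (donors[, 1] - rc[1])^2 + (donors[, 2] - rc[2])^2
    k <- which.min(d2)                       # first (row-major) donor wins ties
    vals[rc[1], rc[2]] <- grid$values[donors[k, 1], donors[k, 2]]
  }
  ids <- sort(setdiff(unique(as.vector(grid$region_mask)), 0L))
  pct <- vapply(ids, function(r) {
    in_r <- grid$region_mask == r
    100 * sum(m & in_r) / sum(in_r)
  }, 1.0)
  list(filled = grid_layer(vals, matrix(FALSE, nr, ncol(vals)),
                           grid$region_mask),
       region_pct = data.frame(region_id = ids, pct_gapfilled = pct))
}
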