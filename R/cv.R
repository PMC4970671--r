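#' Candidate gapfilling models
#'
#' A candidate model for regression-based gapfilling: the response, the
#' driving covariate(s), whether calendar year is included as a predictor,
#' and the spatial scale of the fit — per entity (country), per
#' geopolitical region (either resolution), or global.
#'
#' @param response response column name.
#' @param predictors character vector of predictor column names (nonempty).
#' @param include_year add `year` as a predictor?
#' @param scale one of `"entity"`, `"georegion_l2"`, `"georegion_l1"`,
#'   `"global"`.
#' @param min_n minimum complete rows in the scale unit's training pool;
#'   must be at least the number of model parameters + 1.
#' @param id optional candidate label.
#' @return A `candidate_model` object.
#' @export
candidate_model <- function(response, predictors, include_year = FALSE,
                            scale = c("entity", "georegion_l2",
                                      "georegion_l1", "global"),
                            min_n = NULL, id = NULL) {
  scale <- match.arg(scale)
  if (!length(predictors)) ogf_stop("predictors must be nonempty", "ogf_cv_error")
  # "1" denotes the intercept-only model
  n_par <- 1L + sum(predictors != "1") + as.integer(include_year)
  if (is.null(min_n)) min_n <- n_par + 1L
  if (min_n < n_par + 1L) {
    ogf_stop(sprintf("min_n (%d) must be >= parameters + 1 (%d)",
                     min_n, n_par + 1L), "ogf_cv_error")
  }
  if (is.null(id)) {
    id <- sprintf("%s~%s%s@%s", response, paste(predictors, collapse = "+"),
                  if (include_year) "+year" else "", scale)
  }
  structure(list(response = response, predictors = predictors,
                 include_year = include_year, scale = scale,
                 min_n = as.integer(min_n), n_par = n_par, id = id),
            class = "candidate_model")
}

candidate_formula <- function(candidate) {
  stats::reformulate(c(candidate$predictors,
                       if (candidate$include_year) "year"),
                     response = candidate$response)
}

#' Leave-one-out cross-validated RMSE of an OLS candidate
#'
#' Removes one case at a time, refits the model on the remaining cases, and
#' predicts the held-out case; errors are summarized as
#' `sqrt(mean(residual^2))`. For OLS the leave-one-out residual is computed
#' exactly from the full fit as `residual / (1 - hat value)`, identical to
#' literally refitting n times.
#'
#' @param dataset data frame holding the response and predictor columns;
#'   rows with a missing response or predictor are ignored.
#' @param candidate a [candidate_model()].
#' @return A `cv_result` list: `candidate`, `rmse`, `n_cases`, `residuals`,
#'   `predictions`.
#' @export
loocv_rmse <- function(dataset, candidate) {
  f <- candidate_formula(candidate)
  vars <- all.vars(f)
  dat <- dataset[stats::complete.cases(dataset[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  if (n < candidate$min_n) {
    ogf_stop(sprintf("only %d complete rows; candidate '%s' needs %d",
                     n, candidate$id, candidate$min_n), "ogf_cv_error")
  }
  fit <- stats::lm(f, data = dat)
  if (fit$rank < length(stats::coef(fit))) {
    ogf_stop(sprintf("rank-deficient fit for candidate '%s'", candidate$id),
             "ogf_cv_error")
  }
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  if (any(h > 1 - 1e-10)) {
    ogf_stop(sprintf(
      "leave-one-out fit is rank-deficient when case %d is removed",
      which(h > 1 - 1e-10)[1]), "ogf_cv_error")
  }
  res_loo <- stats::residuals(fit) / (1 - h)
  obs <- dat[[candidate$response]]
  structure(list(candidate = candidate,
                 rmse = sqrt(mean(res_loo^2)),
                 n_cases = n,
                 residuals = unname(res_loo),
                 predictions = unname(obs - res_loo)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: RMSE %.6g over %d cases\n",
              x$candidate$id, x$rmse, x$n_cases))
  invisible(x)
}

#' Hierarchical model selection for gapfilling
#'
#' For each entity with missing responses, walks the fallback chain of
#' spatial scales (finest first). A candidate is usable at a scale when the
#' entity's scale unit — the entity's own rows, its geopolitical region's
#' rows, or all rows — has at least `min_n` complete cases. At the finest
#' usable scale, the candidate with the lowest leave-one-out RMSE wins; ties
#' are broken by fewest parameters, then by candidate order. The winning
#' model (refit on the full pool) predicts the entity's missing responses,
#' and its LOOCV RMSE is kept as the error estimate.
#'
#' @param dataset data frame with an entity id column, grouping columns for
#'   any georegion scales used, the response (missing where it is to be
#'   gapfilled) and the predictors.
#' @param candidates list of [candidate_model()]s (at any mix of scales).
#' @param fallback_chain ordered scales, finest first.
#' @param entity_col name of the entity id column.
#' @return A list: `selection` (data frame `entity`, `scale_used`,
#'   `candidate_id`, `rmse`, `n_cases`), and `predictions` (data frame of
#'   the originally missing rows with a `prediction` column).
#' @export
select_gapfill_model <- function(dataset, candidates,
                                 fallback_chain = c("entity", "georegion_l2",
                                                    "global"),
                                 entity_col = "region_id") {
  stopifnot(length(candidates) >= 1)
  by_scale <- split(candidates,
                    vapply(candidates, function(cn) cn$scale, ""))
  response <- candidates[[1]]$response
  need <- which(is.na(dataset[[response]]))
  entities <- unique(dataset[[entity_col]][need])

  scale_rows <- function(scale, entity) {
    if (scale == "global") return(seq_len(nrow(dataset)))
    col <- if (scale == "entity") entity_col else scale
    if (!col %in% names(dataset)) {
      ogf_stop(sprintf("dataset lacks grouping column '%s'", col), "ogf_cv_error")
    }
    which(dataset[[col]] == dataset[[col]][match(entity, dataset[[entity_col]])])
  }

  cache <- new.env(parent = emptyenv())
  sel <- list()
  preds <- rep(NA_real_, nrow(dataset))
  for (e in entities) {
    chosen <- NULL
    for (scale in fallback_chain) {
      cands <- by_scale[[scale]]
      if (is.null(cands)) next
      rows <- scale_rows(scale, e)
      pool <- dataset[rows, , drop = FALSE]
      results <- list()
      for (cn in cands) {
        vars <- all.vars(candidate_formula(cn))
        n_ok <- sum(stats::complete.cases(pool[vars]))
        if (n_ok < cn$min_n) next
        ck <- paste(scale, if (scale == "global") "" else
                    dataset[[if (scale == "entity") entity_col else scale]][
                      match(e, dataset[[entity_col]])], cn$id)
        cv <- cache[[ck]]
        if (is.null(cv)) {
          cv <- loocv_rmse(pool, cn)
          cache[[ck]] <- cv
        }
        results[[length(results) + 1L]] <- cv
      }
      if (!length(results)) next
      rmses <- vapply(results, `[[`, 1.0, "rmse")
      pars <- vapply(results, function(r) r$candidate$n_par, 1L)
      ord <- order(rmses, pars, seq_along(results))
      chosen <- results[[ord[1]]]
      fit <- stats::lm(candidate_formula(chosen$candidate),
                       data = pool[stats::complete.cases(
                         pool[all.vars(candidate_formula(chosen$candidate))]),
                         , drop = FALSE])
      tgt <- need[dataset[[entity_col]][need] == e]
      preds[tgt] <- unname(stats::predict(fit, dataset[tgt, , drop = FALSE]))
      sel[[length(sel) + 1L]] <- data.frame(
        entity = e, scale_used = scale, candidate_id = chosen$candidate$id,
        rmse = chosen$rmse, n_cases = chosen$n_cases,
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(chosen)) {
      ogf_stop(sprintf("no usable candidate at any scale for entity %s", e),
               "ogf_cv_error")
    }
  }
  predictions <- dataset[need, , drop = FALSE]
  predictions$prediction <- preds[need]
  list(selection = do.call(rbind, sel), predictions = predictions)
}

#' One-way ANOVA check for group signal
#'
#' Before filling missing values with group (e.g. geopolitical-region)
#' means, the groups should differ significantly; otherwise a grand mean is
#' the more defensible donor pool. Runs a fixed-effects one-way analysis of
#' variance and flags `use_global_mean` when `p >= alpha`.
#'
#' @param values numeric vector.
#' @param groups grouping vector, same length.
#' @param alpha advisory significance threshold.
#' @return A list: `F`, `p`, `df`, `use_global_mean`.
#' @export
group_signal_test <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (nlevels(groups) < 2 || any(sizes < 2)) {
    ogf_stop("need >= 2 groups with >= 2 members each", "ogf_cv_error")
  }
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    ogf_stop("zero within-group variance everywhere; F undefined",
             "ogf_cv_error")
  }
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df = unname(ow$parameter),
       use_global_mean = unname(ow$p.value) >= alpha)
}
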