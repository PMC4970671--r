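#' Goal models
#'
#' A goal model declares how a goal's score is assembled: which layers feed
#' each of the four dimensions (status, trend, pressure, resilience) and
#' with what weights, the discount/trend balance `beta` of the projected
#' future state, the goal's weight in the region index, and the component
#' attribution weights used to propagate gapfill fractions from dimensions
#' to the goal. A goal may instead be composed of weighted subgoals, each
#' itself a goal model.
#'
#' @param goal_code short goal code, e.g. `"FP"`.
#' @param layers named list with elements `status`, `trend`, `pressure`,
#'   `resilience`, each a named numeric vector of nonnegative layer weights
#'   (names are layer ids). `trend` may be empty when the trend is computed
#'   from the status time series.
#' @param beta balance between trend and pressure/resilience in the
#'   projected future state, in `[0, 1]`.
#' @param component_weights nonnegative weights over
#'   `(status, trend, pressure, resilience)` summing to 1, used for gapfill
#'   attribution; defaults to [default_component_weights()].
#' @param goal_weight nonnegative weight of the goal in the region index.
#' @param subgoals optional list of `goal_model` objects.
#' @param subgoal_weights numeric weights for `subgoals` (default equal).
#'
#' @return A `goal_model` object.
#' @export
goal_model <- function(goal_code, layers = NULL, beta = 0.67,
                       component_weights = default_component_weights(beta),
                       goal_weight = 1, subgoals = NULL,
                       subgoal_weights = NULL) {
  stopifnot(is.character(goal_code), length(goal_code) == 1L)
  if (beta < 0 || beta > 1) ogf_stop("beta must lie in [0, 1]", "ogf_goal_error")
  component_weights <- as.numeric(component_weights)
  if (length(component_weights) != 4L || any(component_weights < 0)) {
    ogf_stop("component_weights must be a nonnegative 4-vector", "ogf_goal_error")
  }
  if (abs(sum(component_weights) - 1) > 1e-9) {
    ogf_stop("component_weights must sum to 1 (tolerance 1e-9)", "ogf_goal_error")
  }
  names(component_weights) <- c("status", "trend", "pressure", "resilience")
  if (goal_weight < 0) ogf_stop("goal_weight must be >= 0", "ogf_goal_error")
  if (!is.null(subgoals)) {
    stopifnot(all(vapply(subgoals, inherits, TRUE, "goal_model")))
    if (is.null(subgoal_weights)) subgoal_weights <- rep(1, length(subgoals))
    if (sum(subgoal_weights) <= 0) {
      ogf_stop("subgoal weights must sum > 0", "ogf_goal_error")
    }
  } else {
    dims <- c("status", "trend", "pressure", "resilience")
    if (is.null(layers)) ogf_stop("layers or subgoals required", "ogf_goal_error")
    layers <- layers[dims]
    names(layers) <- dims
    for (d in dims) {
      w <- layers[[d]]
      if (is.null(w)) {
        layers[[d]] <- numeric(0)
        next
      }
      if (any(w < 0)) {
        ogf_stop(sprintf("goal %s: negative layer weight in %s", goal_code, d),
                 "ogf_goal_error")
      }
      if (length(w) && sum(w) <= 0) {
        ogf_stop(sprintf("goal %s: %s layer weights sum to 0", goal_code, d),
                 "ogf_goal_error")
      }
    }
    if (length(layers$status) == 0L) {
      ogf_stop(sprintf("goal %s: at least one status layer required", goal_code),
               "ogf_goal_error")
    }
  }
  structure(list(goal_code = goal_code, layers = layers, beta = beta,
                 component_weights = component_weights,
                 goal_weight = goal_weight, subgoals = subgoals,
                 subgoal_weights = subgoal_weights),
            class = "goal_model")
}

#' Default component attribution weights
#'
#' Status carries 88.3% of the index-level attribution; the remaining 11.7%
#' is split among trend, pressure and resilience in proportion
#' `beta : (1 - beta)/2 : (1 - beta)/2`, mirroring the internal weighting of
#' the projected-future-state formula.
#'
#' @param beta trend balance of the future-state formula.
#' @param status_share share of attribution carried by current status.
#' @return Named numeric 4-vector summing to 1.
#' @export
default_component_weights <- function(beta = 0.67, status_share = 0.883) {
  rest <- 1 - status_share
  c(status = status_share,
    trend = rest * beta,
    pressure = rest * (1 - beta) / 2,
    resilience = rest * (1 - beta) / 2)
}

#' Read goal models from a YAML configuration file
#'
#' The file declares a top-level `goals:` list; each entry gives
#' `goal_code`, optional `goal_weight`, `beta`, `component_weights`,
#' and either `layers:` (maps dimension -> {layer_id: weight}) or
#' `subgoals:` (list of nested goal entries, each with an optional
#' `weight`).
#'
#' @param path YAML file path.
#' @return Named list of `goal_model` objects.
#' @export
read_goal_models <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$goals)) ogf_stop("config has no 'goals' entry", "ogf_goal_error")
  models <- lapply(cfg$goals, parse_goal_entry)
  names(models) <- vapply(models, function(g) g$goal_code, "")
  models
}

parse_goal_entry <- function(entry) {
  lay <- NULL
  sub <- NULL
  subw <- NULL
  if (!is.null(entry$subgoals)) {
    sub <- lapply(entry$subgoals, parse_goal_entry)
    subw <- vapply(entry$subgoals,
                   function(e) if (is.null(e$weight)) 1 else as.numeric(e$weight),
                   1.0)
  } else {
    lay <- lapply(entry$layers, function(d) unlist(d))
  }
  beta <- if (is.null(entry$beta)) 0.67 else as.numeric(entry$beta)
  cw <- if (is.null(entry$component_weights)) default_component_weights(beta)
        else unlist(entry$component_weights)
  goal_model(entry$goal_code, layers = lay, beta = beta,
             component_weights = cw,
             goal_weight = if (is.null(entry$goal_weight)) 1
                           else as.numeric(entry$goal_weight),
             subgoals = sub, subgoal_weights = subw)
}

#' @export
print.goal_model <- function(x, ...) {
  cat(sprintf("<goal_model> %s (weight %g, beta %g)\n",
              x$goal_code, x$goal_weight, x$beta))
  if (!is.null(x$subgoals)) {
    cat("  subgoals:", paste(vapply(x$subgoals, `[[`, "", "goal_code"),
                             collapse = ", "), "\n")
  } else {
    for (d in names(x$layers)) {
      if (length(x$layers[[d]]))
        cat(sprintf("  %s: %s\n", d,
                    paste(sprintf("%s=%g", names(x$layers[[d]]), x$layers[[d]]),
                          collapse = ", ")))
    }
  }
  invisible(x)
}

#' Cross-validate a bundle of inputs
#'
#' Checks a registry, a list of layers (with optional ledgers) and a list of
#' goal models for mutual consistency and returns a report data frame; an
#' empty report means the bundle is consistent. Checked: layer region ids
#' unknown to the registry; layers referenced by goal models but absent from
#' the bundle; degenerate (all-zero) dimension weight vectors.
#'
#' @param registry a `region_registry`.
#' @param layers named list of `layer_table`s.
#' @param goal_models list of `goal_model`s.
#' @return Data frame with columns `scope`, `id`, `problem` (0 rows when
#'   consistent).
#' @export
validate_inputs <- function(registry, layers, goal_models = list()) {
  probs <- list()
  add <- function(scope, id, problem) {
    probs[[length(probs) + 1L]] <<- data.frame(
      scope = scope, id = as.character(id), problem = problem,
      stringsAsFactors = FALSE)
  }
  for (ly in layers) {
    unknown <- setdiff(unique(ly$region_id), registry$region_id)
    for (u in unknown) add("layer", layer_id(ly),
                           sprintf("unknown region_id %s", u))
  }
  have <- vapply(layers, layer_id, "")
  walk_goal <- function(g) {
    if (!is.null(g$subgoals)) {
      lapply(g$subgoals, walk_goal)
      return(invisible())
    }
    for (d in names(g$layers)) {
      w <- g$layers[[d]]
      absent <- setdiff(names(w), have)
      for (a in absent) add("goal", g$goal_code,
                            sprintf("references absent layer '%s' (%s)", a, d))
      if (length(w) && sum(w) == 0)
        add("goal", g$goal_code, sprintf("all-zero %s layer weights", d))
    }
  }
  lapply(goal_models, walk_goal)
  if (length(probs)) do.call(rbind, probs)
  else data.frame(scope = character(0), id = character(0),
                  problem = character(0), stringsAsFactors = FALSE)
}
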