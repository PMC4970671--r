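#' Gapfilling ledgers
#'
#' A gapfilling ledger holds exactly one record per observation of a layer
#' (same key columns), describing 1) whether the value was gapfilled, 2) the
#' gapfilling method, and 3) a place-holder for the estimated error due to
#' gapfilling. Methods come from a closed vocabulary; a `:detail` suffix
#' (e.g. `regional_mean:georegion_l1` for the fallback level used) is
#' allowed after any base token. `assumed_zero` records a confident zero
#' assumption that is deliberately *not* counted as gapfilling
#' (`gapfilled = 0`); [collapse_layer()] can reclassify it for sensitivity
#' analysis.
#'
#' @name gapfill_ledger
NULL

#' Closed vocabulary of ledger method tokens
#' @return character vector of base method tokens.
#' @export
ledger_methods <- function() {
  c("none", "assumed_zero", "regional_mean", "regional_median",
    "disaggregation", "zero_fill", "temporal", "taxonomic", "covariate",
    "grid_interp")
}

#' Construct a gapfilling ledger
#'
#' @param df data frame with the layer's key columns plus `gapfilled`
#'   (0/1), `method` (see [ledger_methods()]) and `error` (numeric
#'   place-holder, may be all `NA`).
#' @param keys key column names (must match the layer's).
#' @param layer_id the layer this ledger describes.
#' @return A `gapfill_ledger` data frame.
#' @export
gapfill_ledger <- function(df, keys = "region_id", layer_id = NULL) {
  miss <- setdiff(c(keys, "gapfilled", "method"), names(df))
  if (length(miss)) {
    ogf_stop(sprintf("ledger missing columns: %s", paste(miss, collapse = ", ")),
             "ogf_ledger_error")
  }
  df <- as.data.frame(df)
  if (!"error" %in% names(df)) df$error <- NA_real_
  df <- df[, c(keys, "gapfilled", "method", "error")]
  df$gapfilled <- as.integer(df$gapfilled)
  df$method <- as.character(df$method)
  df$error <- as.numeric(df$error)
  attr(df, "keys") <- keys
  attr(df, "layer_id") <- layer_id
  class(df) <- c("gapfill_ledger", "data.frame")
  validate_ledger(df)
}

#' @rdname gapfill_ledger
#' @param ledger a candidate ledger.
#' @param layer optional `layer_table`; when given, the key sets must be in
#'   bijection.
#' @export
validate_ledger <- function(ledger, layer = NULL) {
  if (any(is.na(ledger$gapfilled)) || !all(ledger$gapfilled %in% c(0L, 1L))) {
    ogf_stop("ledger gapfilled must be 0 or 1", "ogf_ledger_error")
  }
  if (any(is.na(ledger$method)) || any(!nzchar(ledger$method))) {
    ogf_stop("ledger method must be present for every record", "ogf_ledger_error")
  }
  base <- sub(":.*$", "", ledger$method)
  unknown <- setdiff(unique(base), ledger_methods())
  if (length(unknown)) {
    ogf_stop(sprintf("unknown ledger method token(s): %s",
                     paste(unknown, collapse = ", ")), "ogf_ledger_error")
  }
  bad0 <- ledger$gapfilled == 0L & !base %in% c("none", "assumed_zero")
  if (any(bad0)) {
    ogf_stop(sprintf("gapfilled=0 requires method none/assumed_zero (got %s)",
                     ledger$method[bad0][1]), "ogf_ledger_error")
  }
  if (any(ledger$gapfilled == 1L & base == "none")) {
    ogf_stop("gapfilled=1 requires a real method, not 'none'", "ogf_ledger_error")
  }
  keys <- attr(ledger, "keys")
  kt <- do.call(paste, c(unname(as.data.frame(ledger)[keys]), sep = "\r"))
  if (anyDuplicated(kt)) {
    ogf_stop("duplicate key tuple in ledger", "ogf_ledger_error")
  }
  if (!is.null(layer)) {
    lk <- do.call(paste,
                  c(unname(as.data.frame(layer)[layer_keys(layer)]), sep = "\r"))
    orphan <- setdiff(kt, lk)
    missing <- setdiff(lk, kt)
    if (length(orphan) || length(missing)) {
      ogf_stop(sprintf(
        "ledger/layer key mismatch: %d orphan ledger key(s) [%s], %d uncovered layer key(s) [%s]",
        length(orphan), gsub("\r", ",", paste(utils::head(orphan, 3), collapse = "; ")),
        length(missing), gsub("\r", ",", paste(utils::head(missing, 3), collapse = "; "))),
        "ogf_ledger_error")
    }
  }
  ledger
}

#' An all-clean ledger for a layer
#'
#' One record per layer observation with `gapfilled = 0`, `method = "none"`.
#'
#' @param layer a `layer_table`.
#' @return A `gapfill_ledger`.
#' @export
empty_ledger <- function(layer) {
  keys <- layer_keys(layer)
  df <- as.data.frame(layer)[keys]
  df$gapfilled <- 0L
  df$method <- "none"
  df$error <- NA_real_
  gapfill_ledger(df, keys = keys, layer_id = layer_id(layer))
}

#' Read / write gapfilling ledgers
#'
#' CSV round-trips are exact, including empty `error` place-holders (written
#' as empty cells).
#'
#' @param path CSV path.
#' @param keys key column names.
#' @param layer_id optional layer name.
#' @return [read_ledger()]: a `gapfill_ledger`; [write_ledger()]: `path`,
#'   invisibly.
#' @export
read_ledger <- function(path, keys = "region_id", layer_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "NaN"))
  gapfill_ledger(raw, keys = keys, layer_id = layer_id)
}

#' @rdname read_ledger
#' @param ledger a `gapfill_ledger`.
#' @param layer optional layer to validate the key bijection against before
#'   writing.
#' @export
write_ledger <- function(ledger, path, layer = NULL) {
  validate_ledger(ledger, layer = layer)
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.gapfill_ledger <- function(x, ...) {
  cat(sprintf("<gapfill_ledger>%s %d records, %d gapfilled (%.1f%%)\n",
              if (is.null(attr(x, "layer_id"))) "" else
                paste0(" '", attr(x, "layer_id"), "'"),
              nrow(x), sum(x$gapfilled),
              if (nrow(x)) 100 * mean(x$gapfilled) else 0))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
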