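#' Gapfilling results
#'
#' Every gapfilling estimator returns a `fill_result`: the layer with its
#' targeted missing values filled, the ledger delta describing each filled
#' value (method token, fallback level where relevant), and per-method
#' diagnostics (donor counts, model coefficients, fits skipped).
#'
#' @param filled_layer the `layer_table` after filling.
#' @param ledger a `gapfill_ledger` covering every observation of the layer.
#' @param diagnostics method-specific summary (list or data frame).
#' @param original the layer before filling, used to verify the ledger
#'   accounting invariant: exactly the observations that changed from
#'   missing to non-missing carry `gapfilled = 1` (records pre-existing in
#'   `ledger` are allowed to keep their flags).
#' @return A `fill_result` list.
#' @export
fill_result <- function(filled_layer, ledger, diagnostics = list(),
                        original = NULL) {
  validate_ledger(ledger, layer = filled_layer)
  if (!is.null(original)) {
    keys <- layer_keys(filled_layer)
    newly <- is.na(original$value[match(key_string(filled_layer, keys),
                                        key_string(original, keys))]) &
      !is.na(filled_layer$value)
    meth <- ledger$method[match(key_string(filled_layer, keys),
                                key_string(ledger, keys))]
    if (any(newly & meth == "none")) {
      ogf_stop("ledger accounting: a filled observation has method 'none'",
               "ogf_fill_error")
    }
    if (any(!newly & ledger$gapfilled[match(key_string(filled_layer, keys),
                                            key_string(ledger, keys))] == 1L &
              is.na(filled_layer$value))) {
      ogf_stop("ledger accounting: a still-missing observation is flagged",
               "ogf_fill_error")
    }
  }
  structure(list(filled_layer = filled_layer, ledger = ledger,
                 diagnostics = diagnostics),
            class = "fill_result")
}

#' @export
print.fill_result <- function(x, ...) {
  cat(sprintf("<fill_result> layer '%s': %d obs, %d flagged gapfilled\n",
              layer_id(x$filled_layer), nrow(x$filled_layer),
              sum(x$ledger$gapfilled)))
  invisible(x)
}

# paste key columns into a single comparable string per row
key_string <- function(df, keys) {
  do.call(paste, c(unname(as.data.frame(df)[keys]), sep = "\r"))
}

# pretty form of one key tuple for error messages
key_label <- function(df, keys, i) {
  paste(sprintf("%s=%s", keys, unlist(as.data.frame(df)[i, keys])),
        collapse = ", ")
}
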