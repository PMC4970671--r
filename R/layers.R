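#' Layer tables
#'
#' A layer table holds one data layer of the assessment: one observation per
#' key tuple (`region_id`, optionally `category` — commodity, species,
#' habitat, stock — and optionally `year`) with a `value` column that may be
#' missing. The declared closed `value_range` bounds every non-missing value
#' and is used to clamp model-based gapfill predictions.
#'
#' @param df data frame with the key columns and a `value` column.
#' @param layer_id character scalar naming the layer.
#' @param keys character vector of key column names; must include
#'   `"region_id"`.
#' @param value_range numeric length-2 closed interval for valid values.
#' @param dimension_tag optional: one of `"status"`, `"trend"`, `"pressure"`,
#'   `"resilience"` when the layer is bound to a goal model.
#'
#' @return A `layer_table` data frame with attributes `layer_id`, `keys`,
#'   `value_range`, `dimension_tag`.
#' @export
layer_table <- function(df, layer_id, keys = "region_id",
                        value_range = c(0, 1), dimension_tag = NULL) {
  stopifnot(is.data.frame(df), "region_id" %in% keys)
  miss <- setdiff(c(keys, "value"), names(df))
  if (length(miss)) {
    ogf_stop(sprintf("layer '%s' missing columns: %s", layer_id,
                     paste(miss, collapse = ", ")), "ogf_layer_error")
  }
  if (!is.null(dimension_tag)) {
    dimension_tag <- match.arg(dimension_tag,
                               c("status", "trend", "pressure", "resilience"))
  }
  df <- as.data.frame(df)[, c(keys, "value")]
  df$value <- as.numeric(df$value)
  attr(df, "layer_id") <- layer_id
  attr(df, "keys") <- keys
  attr(df, "value_range") <- as.numeric(value_range)
  attr(df, "dimension_tag") <- dimension_tag
  class(df) <- c("layer_table", "data.frame")
  validate_layer(df)
}

#' @rdname layer_table
#' @param layer a candidate `layer_table`.
#' @export
validate_layer <- function(layer) {
  keys <- layer_keys(layer)
  kt <- do.call(paste, c(unname(as.data.frame(layer)[keys]), sep = "\r"))
  if (anyDuplicated(kt)) {
    dup <- kt[duplicated(kt)][1]
    ogf_stop(sprintf("layer '%s': duplicate key tuple (%s)",
                     layer_id(layer), gsub("\r", ", ", dup)),
             "ogf_layer_error")
  }
  v <- layer$value
  if (all(is.na(v))) {
    ogf_stop(sprintf("layer '%s': all values missing", layer_id(layer)),
             "ogf_layer_error")
  }
  vr <- value_range(layer)
  bad <- !is.na(v) & (v < vr[1] | v > vr[2])
  if (any(bad)) {
    ogf_stop(sprintf("layer '%s': %d value(s) outside [%g, %g], first = %g",
                     layer_id(layer), sum(bad), vr[1], vr[2], v[bad][1]),
             "ogf_layer_error")
  }
  layer
}

#' @rdname layer_table
#' @export
layer_id <- function(layer) attr(layer, "layer_id")

#' @rdname layer_table
#' @export
layer_keys <- function(layer) attr(layer, "keys")

#' @rdname layer_table
#' @export
value_range <- function(layer) attr(layer, "value_range")

#' Read a data layer from CSV
#'
#' @param path CSV path; columns must be the declared keys plus `value`.
#'   Missing values are empty cells (the strings `NA`/`NaN` are also
#'   accepted on read).
#' @param layer_id layer name; defaults to the file name without extension.
#' @param keys key column declaration (see [layer_table()]).
#' @param value_range declared closed interval.
#' @param dimension_tag optional dimension binding.
#' @return A validated `layer_table`.
#' @export
read_layer <- function(path, layer_id = sub("\\.csv$", "", basename(path)),
                       keys = "region_id", value_range = c(0, 1),
                       dimension_tag = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "NaN"))
  layer_table(raw, layer_id = layer_id, keys = keys,
              value_range = value_range, dimension_tag = dimension_tag)
}

#' Write a data layer to CSV
#'
#' Missing values are always written as empty cells, so write/read
#' round-trips are exact.
#'
#' @param layer a `layer_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  utils::write.csv(as.data.frame(layer), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.layer_table <- function(x, ...) {
  vr <- value_range(x)
  cat(sprintf("<layer_table> '%s' keys=(%s) range=[%g, %g] %d obs, %d missing\n",
              layer_id(x), paste(layer_keys(x), collapse = ", "),
              vr[1], vr[2], nrow(x), sum(is.na(x$value))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
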