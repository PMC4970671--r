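#' Region registry
#'
#' A region registry is a data frame describing every reporting region of an
#' assessment: countries and the territorial jurisdictions they administer,
#' the two nested UN-style geopolitical groupings used as donor pools for
#' regional-mean gapfilling, and the EEZ area used to weight regions in
#' global averages.
#'
#' @param region_id integer vector of unique positive region identifiers
#'   (0 is reserved for "outside all regions" in grids and is forbidden here).
#' @param name character region names.
#' @param is_territory logical; is the region administered by another country?
#' @param admin_country_id integer; the administering country's `region_id`
#'   for territories, `NA` otherwise.
#' @param georegion_l2 higher-resolution geopolitical region code
#'   (22 classes in a global registry).
#' @param georegion_l1 lower-resolution geopolitical region code (7 classes);
#'   each `georegion_l2` code must map to exactly one `georegion_l1` code.
#' @param eez_area_km2 positive EEZ area in square kilometres.
#' @param neighbors optional list of integer vectors of adjacent region ids.
#'
#' @return A `region_registry` data frame.
#' @seealso [read_region_registry()]
#' @export
region_registry <- function(region_id, name, is_territory, admin_country_id,
                            georegion_l2, georegion_l1, eez_area_km2,
                            neighbors = NULL) {
  n <- length(region_id)
  if (is.null(neighbors)) neighbors <- rep(list(integer(0)), n)
  reg <- data.frame(
    region_id = as.integer(region_id),
    name = as.character(name),
    is_territory = as.logical(is_territory),
    admin_country_id = as.integer(admin_country_id),
    georegion_l2 = as.character(georegion_l2),
    georegion_l1 = as.character(georegion_l1),
    eez_area_km2 = as.numeric(eez_area_km2),
    stringsAsFactors = FALSE
  )
  reg$neighbors <- neighbors
  class(reg) <- c("region_registry", "data.frame")
  validate_registry(reg)
}

#' @rdname region_registry
#' @param reg a candidate registry data frame.
#' @export
validate_registry <- function(reg) {
  if (anyDuplicated(reg$region_id)) {
    dup <- unique(reg$region_id[duplicated(reg$region_id)])
    ogf_stop(sprintf("duplicate region_id: %s", paste(dup, collapse = ", ")),
             "ogf_registry_error")
  }
  if (any(reg$region_id == 0L)) {
    ogf_stop("region_id 0 is reserved for cells outside all regions",
             "ogf_registry_error")
  }
  if (any(!is.finite(reg$eez_area_km2)) || any(reg$eez_area_km2 <= 0)) {
    ogf_stop("eez_area_km2 must be positive for every region",
             "ogf_registry_error")
  }
  terr <- reg$is_territory
  if (any(terr & is.na(reg$admin_country_id))) {
    bad <- reg$region_id[terr & is.na(reg$admin_country_id)]
    ogf_stop(sprintf("territory without admin_country_id: %s",
                     paste(bad, collapse = ", ")), "ogf_registry_error")
  }
  if (any(terr & reg$admin_country_id == reg$region_id, na.rm = TRUE)) {
    ogf_stop("a territory cannot administer itself", "ogf_registry_error")
  }
  # each l2 code must belong to exactly one l1 code
  map <- unique(reg[, c("georegion_l2", "georegion_l1")])
  if (anyDuplicated(map$georegion_l2)) {
    bad <- map$georegion_l2[duplicated(map$georegion_l2)]
    ogf_stop(sprintf("georegion_l2 %s maps to more than one georegion_l1",
                     paste(unique(bad), collapse = ", ")),
             "ogf_registry_error")
  }
  attr(reg, "l2_map") <- map[order(map$georegion_l2), , drop = FALSE]
  reg
}

#' Read a region registry from CSV
#'
#' Expected columns: `region_id,name,is_territory,admin_country_id,
#' georegion_l2,georegion_l1,eez_area_km2[,neighbors]`, with `neighbors` a
#' `;`-separated list of region ids. Empty cells, `NA` and `NaN` are read as
#' missing.
#'
#' @param path path to a CSV file.
#' @return A validated `region_registry`.
#' @export
read_region_registry <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "NaN"))
  need <- c("region_id", "name", "is_territory", "admin_country_id",
            "georegion_l2", "georegion_l1", "eez_area_km2")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    ogf_stop(sprintf("registry file missing columns: %s",
                     paste(miss, collapse = ", ")), "ogf_registry_error")
  }
  nb <- NULL
  if ("neighbors" %in% names(raw)) {
    nb <- lapply(raw$neighbors, function(s) {
      if (is.na(s) || !nzchar(s)) integer(0)
      else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  region_registry(raw$region_id, raw$name, as.logical(raw$is_territory),
                  raw$admin_country_id, raw$georegion_l2, raw$georegion_l1,
                  raw$eez_area_km2, neighbors = nb)
}

#' Write a region registry to CSV
#'
#' Inverse of [read_region_registry()]; missing values are written as empty
#' cells and neighbor lists as `;`-separated ids.
#'
#' @param reg a `region_registry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_registry <- function(reg, path) {
  out <- as.data.frame(reg[, setdiff(names(reg), "neighbors")])
  out$neighbors <- vapply(reg$neighbors, paste, "", collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.region_registry <- function(x, ...) {
  cat(sprintf("<region_registry> %d regions (%d territories), %d/%d georegions\n",
              nrow(x), sum(x$is_territory),
              length(unique(x$georegion_l2)), length(unique(x$georegion_l1))))
  print(utils::head(as.data.frame(x[, setdiff(names(x), "neighbors")])), ...)
  invisible(x)
}
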