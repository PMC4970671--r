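# Small in-code fixtures shared across test files.

# six regions, two higher-resolution georegions (A, B) in one l1 region,
# region 3 a territory of region 1
tiny_registry <- function() {
  region_registry(
    region_id = 1:6,
    name = paste0("r", 1:6),
    is_territory = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    admin_country_id = c(NA, NA, 1L, NA, NA, NA),
    georegion_l2 = c("A", "A", "A", "B", "B", "B"),
    georegion_l1 = rep("X", 6),
    eez_area_km2 = c(100, 200, 10, 300, 50, 400),
    neighbors = list(2L, c(1L, 3L), 2L, 5L, c(4L, 6L), 5L)
  )
}

tiny_layer <- function(values, ids = seq_along(values), range = c(0, 1),
                       id = "test_layer") {
  layer_table(data.frame(region_id = ids, value = values),
              layer_id = id, value_range = range)
}

# brute-force leave-one-out oracle: literally refit n times
loocv_oracle <- function(dataset, candidate) {
  f <- ohigapfill:::candidate_formula(candidate)
  vars <- all.vars(f)
  dat <- dataset[stats::complete.cases(dataset[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- stats::lm(f, data = dat[-i, , drop = FALSE])
    pred[i] <- unname(stats::predict(fit, dat[i, , drop = FALSE]))
  }
  obs <- dat[[candidate$response]]
  list(rmse = sqrt(mean((obs - pred)^2)), predictions = pred)
}

# closed-form OLS slope oracle
ols_slope <- function(x, y) {
  xm <- x - mean(x)
  sum(xm * (y - mean(y))) / sum(xm^2)
}
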