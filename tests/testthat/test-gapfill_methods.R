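test_that("regional mean fills from the first chain level with enough donors", {
  reg <- tiny_registry()
  # georegion A donors: regions 1, 2 (region 3 missing)
  ly <- tiny_layer(c(0.2, 0.4, NA, 0.1, 0.3, 0.8))
  fr <- regional_stat_fill(ly, reg, min_n = 2)
  expect_equal(fr$filled_layer$value[3], 0.3)
  expect_equal(fr$ledger$method[3], "regional_mean:georegion_l2")
  expect_equal(fr$ledger$gapfilled, c(0L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(fr$diagnostics$fills$n_donors, 2)

  # only one donor left in A -> falls back to l1 (donors 0.1, 0.3, 0.8 + 0.2)
  ly2 <- tiny_layer(c(0.2, NA, NA, 0.1, 0.3, 0.8))
  fr2 <- regional_stat_fill(ly2, reg, min_n = 2)
  expect_equal(fr2$ledger$method[2], "regional_mean:georegion_l1")
  expect_equal(fr2$filled_layer$value[2], mean(c(0.2, 0.1, 0.3, 0.8)))
  # untouched observations are unchanged bit-for-bit
  expect_identical(fr2$filled_layer$value[c(1, 4, 5, 6)],
                   c(0.2, 0.1, 0.3, 0.8))
})

test_that("regional median and weighted mean variants", {
  reg <- tiny_registry()
  ly <- tiny_layer(c(0.1, 0.2, NA, 0.9, 0.9, 0.9))
  fr <- regional_stat_fill(ly, reg, statistic = "median", min_n = 2,
                           scale_chain = c("georegion_l1"))
  expect_equal(fr$filled_layer$value[3], median(c(0.1, 0.2, 0.9, 0.9, 0.9)))
  expect_equal(fr$ledger$method[3], "regional_median:georegion_l1")

  # habitat-area weighted mean: donors 1 (w 3, 0.4) and 2 (w 1, 0.8)
  ly2 <- tiny_layer(c(0.4, 0.8, NA), ids = 1:3)
  fr2 <- regional_stat_fill(ly2, reg, min_n = 2,
                            weights = c(`1` = 3, `2` = 1, `3` = 1))
  expect_equal(fr2$filled_layer$value[3], 0.5)

  expect_error(regional_stat_fill(ly2, reg, min_n = 2,
                                  weights = c(`1` = -1, `2` = 1, `3` = 1)),
               "negative", class = "ogf_fill_error")
})

test_that("regional fill with chain [global] and mean equals the grand donor mean", {
  reg <- tiny_registry()
  ly <- tiny_layer(c(0.15, NA, 0.35, NA, 0.55, 0.95))
  fr <- regional_stat_fill(ly, reg, scale_chain = "global")
  donors <- c(0.15, 0.35, 0.55, 0.95)
  expect_equal(fr$filled_layer$value[c(2, 4)], rep(mean(donors), 2))
  # a filled value is never its own donor: fills are identical regardless of
  # how many targets there are (leave-target-out everywhere)
  ly_one <- tiny_layer(c(0.15, NA, 0.35, 0.2, 0.55, 0.95))
  expect_equal(regional_stat_fill(ly_one, reg,
                                  scale_chain = "global")$filled_layer$value[2],
               mean(c(0.15, 0.35, 0.2, 0.55, 0.95)))
})

test_that("regional fill respects category/year strata and errors with no donors", {
  reg <- tiny_registry()
  df <- data.frame(region_id = c(1, 2, 3, 1, 2, 3),
                   year = rep(2013:2014, each = 3),
                   value = c(0.2, 0.4, NA, 0.6, 0.8, NA))
  ly <- layer_table(df, "yr", keys = c("region_id", "year"))
  fr <- regional_stat_fill(ly, reg, min_n = 2)
  expect_equal(fr$filled_layer$value[3], 0.3)   # 2013 donors only
  expect_equal(fr$filled_layer$value[6], 0.7)   # 2014 donors only

  df2 <- data.frame(region_id = 1:3, year = c(2013, 2013, 2014),
                    value = c(0.2, 0.4, NA))
  ly2 <- layer_table(df2, "yr2", keys = c("region_id", "year"))
  expect_error(regional_stat_fill(ly2, reg, min_n = 2),
               "no donors at any level", class = "ogf_fill_error")
})

test_that("territorial disaggregation copies or splits by EEZ area", {
  reg <- tiny_registry()
  members <- reg[reg$region_id %in% c(1, 2, 3), ]
  cp <- disaggregate_group(0.5, members, mode = "copy")
  expect_equal(cp$values$value, rep(0.5, 3))
  expect_true(all(cp$ledger$method == "disaggregation"))

  aw <- disaggregate_group(100, reg[reg$region_id %in% c(4, 5), ],
                           mode = "area_weighted")   # areas 300 : 50
  expect_equal(aw$values$value, c(300, 50) / 350 * 100)
  expect_equal(sum(aw$values$value), 100)

  single <- reg[reg$region_id == 6, ]
  expect_equal(disaggregate_group(0.7, single, "copy")$values$value, 0.7)
  expect_equal(disaggregate_group(0.7, single, "area_weighted")$values$value,
               0.7)
  expect_error(disaggregate_group(0.5, reg[0, ]), "empty member",
               class = "ogf_fill_error")
})

test_that("zero_fill fills missing values as gapfilled or as assumed zeros", {
  ly <- tiny_layer(c(NA, 0.4, NA), ids = 1:3)
  fr <- zero_fill(ly)
  expect_equal(fr$filled_layer$value, c(0, 0.4, 0))
  expect_equal(fr$ledger$gapfilled, c(1L, 0L, 1L))
  expect_equal(fr$ledger$method, c("zero_fill", "none", "zero_fill"))

  fr0 <- zero_fill(ly, as_gapfill = FALSE)
  expect_equal(fr0$ledger$gapfilled, c(0L, 0L, 0L))
  expect_equal(fr0$ledger$method[1], "assumed_zero")

  # empty scope: identity, ledger delta empty
  fre <- zero_fill(ly, scope = rep(FALSE, 3))
  expect_equal(fre$filled_layer$value, ly$value)
  expect_equal(sum(fre$ledger$gapfilled), 0)
  # never overwrites data
  expect_error(zero_fill(ly, scope = c(TRUE, TRUE, TRUE)),
               "non-missing", class = "ogf_fill_error")
})

test_that("temporal fill predicts missing years by per-entity OLS", {
  df <- data.frame(region_id = 1, year = 2010:2014,
                   value = c(1, 2, 3, NA, 5))
  ly <- layer_table(df, "ts", keys = c("region_id", "year"),
                    value_range = c(0, 10))
  fr <- temporal_fill(ly)
  expect_equal(fr$filled_layer$value[4], 4)
  expect_equal(fr$ledger$method[4], "temporal")

  cst <- layer_table(data.frame(region_id = 1, year = 2010:2013,
                                value = c(7, 7, NA, 7)),
                     "cst", keys = c("region_id", "year"),
                     value_range = c(0, 10))
  expect_equal(temporal_fill(cst)$filled_layer$value[3], 7)

  # extrapolation beyond the span matches the closed-form OLS prediction
  ext <- layer_table(data.frame(region_id = 1, year = c(2011:2014, 2015),
                                value = c(2, 3, 5, 4, NA)),
                     "ext", keys = c("region_id", "year"),
                     value_range = c(0, 100))
  sl <- ols_slope(2011:2014, c(2, 3, 5, 4))
  pred <- mean(c(2, 3, 5, 4)) + sl * (2015 - mean(2011:2014))
  expect_equal(temporal_fill(ext,
                             allow_extrapolation = TRUE)$filled_layer$value[5],
               pred)
  # without permission the out-of-span year stays missing and is reported
  fr_no <- temporal_fill(ext, allow_extrapolation = FALSE)
  expect_true(is.na(fr_no$filled_layer$value[5]))
  expect_length(fr_no$diagnostics$skipped, 1)

  few <- layer_table(data.frame(region_id = 1, year = 2010:2012,
                                value = c(1, NA, NA)),
                     "few", keys = c("region_id", "year"))
  expect_error(temporal_fill(few, min_years = 2), "min_years",
               class = "ogf_fill_error")
})

test_that("taxonomic fill averages the nearest valued relatives", {
  tree <- data.frame(
    family = c("F1", "F1", "F1", "F1", "F2"),
    genus = c("g1", "g1", "g1", "g2", "g3"),
    species = c("s1", "s2", "s3", "s4", "s5"),
    value = c(0.6, 0.8, NA, 0.3, NA))
  out <- taxonomic_fill(tree)
  expect_equal(out$values$value[out$values$species == "s3"], 0.7)
  expect_equal(unname(out$diagnostics$rank["s3"]), "genus")
  # s5 has no congeners or family relatives with data -> root average
  expect_equal(out$values$value[out$values$species == "s5"],
               mean(c(0.6, 0.8, 0.3)))
  expect_equal(unname(out$diagnostics$rank["s5"]), "root")

  # single family donor
  tree2 <- data.frame(family = c("F1", "F1"), genus = c("g1", "g2"),
                      species = c("s1", "s2"), value = c(0.3, NA))
  out2 <- taxonomic_fill(tree2)
  expect_equal(out2$values$value, 0.3)
  expect_equal(unname(out2$diagnostics$rank), "family")

  # two missing tips sharing donors fill identically, in either target order
  tree3 <- data.frame(family = "F1", genus = "g1",
                      species = c("s1", "s2", "s3", "s4"),
                      value = c(0.2, 0.4, NA, NA))
  a <- taxonomic_fill(tree3, targets = c("s3", "s4"))
  b <- taxonomic_fill(tree3, targets = c("s4", "s3"))
  expect_equal(sort(a$values$value), sort(b$values$value))
  expect_equal(a$values$value, rep(0.3, 2))

  expect_error(taxonomic_fill(data.frame(genus = "g", species = "s",
                                         value = NA_real_)),
               "no valued tip", class = "ogf_fill_error")
})

test_that("covariate fill reproduces exact linear relations and obeys contracts", {
  ly <- tiny_layer(c(2, 4, 6, 8, NA), ids = 1:5, range = c(0, 100))
  cov <- data.frame(region_id = 1:5, x = c(1, 2, 3, 4, 5))
  fr <- covariate_fill(ly, cov, value ~ x, min_train_per_param = 1)
  expect_equal(fr$filled_layer$value[5], 10)
  expect_equal(fr$ledger$method[5], "covariate")
  expect_gt(fr$diagnostics$r_squared, 0.999)

  # group-intercept model: within-group y = x, group B offset +1
  df <- data.frame(region_id = 1:9,
                   value = c(1, 2, 3, 4, 3, 4, 5, 6, NA))
  cov2 <- data.frame(region_id = 1:9,
                     x = c(1, 2, 3, 4, 2, 3, 4, 5, 3),
                     grp = c(rep("A", 4), rep("B", 4), "B"))
  fr2 <- covariate_fill(layer_table(df, "g", value_range = c(0, 100)),
                        cov2, value ~ x + grp, min_train_per_param = 1)
  # OLS oracle with dummy coding
  oracle <- stats::lm(value ~ x + grp, data = merge(df[1:8, ], cov2[1:8, ]))
  expect_equal(fr2$filled_layer$value[9],
               unname(predict(oracle, data.frame(x = 3, grp = "B"))))
  expect_equal(fr2$filled_layer$value[9], 4, tolerance = 1e-10)

  # unseen level at prediction is an error (caller falls back)
  cov3 <- cov2; cov3$grp[9] <- "C"
  expect_error(covariate_fill(layer_table(df, "g", value_range = c(0, 100)),
                              cov3, value ~ x + grp, min_train_per_param = 1),
               "absent from training", class = "ogf_fill_error")

  # collinear design is refused with the offending term named
  cov4 <- data.frame(region_id = 1:5, x = 1:5, x2 = 2 * (1:5))
  expect_error(covariate_fill(ly, cov4, value ~ x + x2,
                              min_train_per_param = 1),
               "collinear", class = "ogf_fill_error")

  # predictions are clamped to the declared range
  ly5 <- tiny_layer(c(0.1, 0.2, 0.3, 0.4, NA), ids = 1:5, range = c(0, 0.5))
  cov5 <- data.frame(region_id = 1:5, x = c(1, 2, 3, 4, 10))
  fr5 <- covariate_fill(ly5, cov5, value ~ x, min_train_per_param = 1)
  expect_equal(fr5$filled_layer$value[5], 0.5)     # 1.0 clamped to the range
})

test_that("grid fill takes the nearest donor and reports per-region percentages", {
  vals <- matrix(1:16, 4, 4)
  miss <- matrix(FALSE, 4, 4)
  miss[1, 1] <- TRUE; miss[2, 1] <- TRUE
  vals[miss] <- NA
  region <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)   # region 1 = left half
  out <- grid_fill(grid_layer(vals, miss, region))
  expect_equal(out$region_pct$pct_gapfilled[out$region_pct$region_id == 1], 25)
  expect_equal(out$region_pct$pct_gapfilled[out$region_pct$region_id == 2], 0)
  expect_false(any(is.na(out$filled$values)))

  # single missing cell takes its unique nearest donor's value
  v2 <- matrix(c(NA, 5), 2, 1)
  out2 <- grid_fill(grid_layer(v2))
  expect_equal(out2$filled$values[1, 1], 5)

  # equidistant donors resolve by row-major donor order
  v3 <- matrix(c(3, NA, 8), 1, 3)
  expect_equal(grid_fill(grid_layer(v3))$filled$values[1, 2], 3)

  # nothing missing: identity, all-zero percentages
  v4 <- matrix(1:4, 2, 2)
  out4 <- grid_fill(grid_layer(v4))
  expect_equal(out4$filled$values, v4)
  expect_true(all(out4$region_pct$pct_gapfilled == 0))

  expect_error(grid_fill(grid_layer(matrix(NA_real_, 2, 2))),
               "all grid cells missing", class = "ogf_fill_error")
})

test_that("FAO commodity recipe: zero-fill when both missing, model fill otherwise", {
  reg <- tiny_registry()
  grid <- expand.grid(region_id = 1:6, category = "coral", year = 2012:2014)
  set.seed(5)
  grid$value <- round(runif(nrow(grid), 10, 100), 1)
  tonnes <- grid
  tonnes$value <- 0.5 * grid$value          # exact relation
  tonnes$value[tonnes$region_id == 3 & tonnes$year == 2014] <- NA
  # region 4, 2014: both missing
  both <- tonnes$region_id == 4 & tonnes$year == 2014
  tonnes$value[both] <- NA
  value_df <- grid
  value_df$value[both] <- NA

  tl <- layer_table(tonnes, "np_tonnes", keys = c("region_id", "category", "year"),
                    value_range = c(0, 1e6))
  vl <- layer_table(value_df, "np_value", keys = c("region_id", "category", "year"),
                    value_range = c(0, 1e6))
  fr <- fao_commodity_fill(tl, vl, reg)

  i_zero <- which(fr$filled_layer$region_id == 4 & fr$filled_layer$year == 2014)
  expect_equal(fr$filled_layer$value[i_zero], 0)
  expect_equal(fr$ledger$method[i_zero], "zero_fill")

  i_mod <- which(fr$filled_layer$region_id == 3 & fr$filled_layer$year == 2014)
  expect_equal(fr$filled_layer$value[i_mod],
               0.5 * value_df$value[value_df$region_id == 3 &
                                      value_df$year == 2014],
               tolerance = 1e-8)
  expect_match(fr$ledger$method[i_mod], "^covariate:")
  expect_true(!is.null(fr$diagnostics$selection$coral))
})

test_that("ledger accounting holds across fill methods", {
  reg <- tiny_registry()
  ly <- tiny_layer(c(0.2, NA, 0.4, NA, 0.3, 0.8))
  for (fr in list(regional_stat_fill(ly, reg, min_n = 2), zero_fill(ly))) {
    expect_equal(sum(fr$ledger$gapfilled),
                 sum(is.na(ly$value)) - sum(is.na(fr$filled_layer$value)))
    expect_false(any(is.na(fr$filled_layer$value)))
  }
})
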