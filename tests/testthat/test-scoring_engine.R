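test_that("propagate_gapfill is a normalized-weight mean with guarded weights", {
  expect_equal(propagate_gapfill(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(propagate_gapfill(c(1, 1, 1), c(0.2, 5, 3)), 1)
  expect_error(propagate_gapfill(c(1, 0), c(-1, 2)), "negative",
               class = "ogf_weight_error")
  expect_error(propagate_gapfill(c(1, 0), c(0, 0)), "zero total",
               class = "ogf_weight_error")
})

test_that("collapse_layer yields weighted gapfill shares per region", {
  df <- data.frame(region_id = c(1, 1, 2), category = c("a", "b", "a"),
                   value = c(0.2, 0.6, 0.5))
  ly <- layer_table(df, "cl", keys = c("region_id", "category"))
  led <- empty_ledger(ly)
  led$gapfilled[1] <- 1L; led$method[1] <- "temporal"
  out <- collapse_layer(ly, led)
  expect_equal(out$gapfill_fraction[out$region_id == 1], 0.5)
  expect_equal(out$value[out$region_id == 1], 0.4)
  expect_equal(out$gapfill_fraction[out$region_id == 2], 0)

  # single gapfilled observation -> fraction 1
  led2 <- led; led2$gapfilled[3] <- 1L; led2$method[3] <- "zero_fill"
  expect_equal(collapse_layer(ly, led2)$gapfill_fraction[2], 1)

  # weights 3:1 with only the minor category gapfilled -> 0.25
  led3 <- empty_ledger(ly); led3$gapfilled[2] <- 1L; led3$method[2] <- "temporal"
  out3 <- collapse_layer(ly, led3, category_weights = c(a = 3, b = 1))
  expect_equal(out3$gapfill_fraction[out3$region_id == 1], 0.25)
})

test_that("collapse_layer keeps the most recent valued year and can reclassify assumed zeros", {
  df <- data.frame(region_id = 1, year = 2012:2014, value = c(0.2, 0.4, NA))
  ly <- layer_table(df, "yl", keys = c("region_id", "year"))
  out <- collapse_layer(ly)
  expect_equal(out$value, 0.4)    # 2014 has no value; 2013 is used

  df2 <- data.frame(region_id = 1, value = 0)
  ly2 <- layer_table(df2, "az")
  led2 <- empty_ledger(ly2); led2$method <- "assumed_zero"
  expect_equal(collapse_layer(ly2, led2)$gapfill_fraction, 0)
  expect_equal(collapse_layer(ly2, led2,
                              count_assumed_zero = TRUE)$gapfill_fraction, 1)
})

test_that("status combination: the two-variable worked example and weighting", {
  two <- function(gf1, gf2) compute_status(list(
    data.frame(region_id = 1, value = 0.6, gapfill_fraction = gf1),
    data.frame(region_id = 1, value = 0.8, gapfill_fraction = gf2)))
  expect_equal(two(1, 0)$gapfill_fraction, 0.5)
  expect_equal(two(1, 1)$gapfill_fraction, 1)
  expect_equal(two(0, 0)$gapfill_fraction, 0)

  wt <- compute_status(list(
    data.frame(region_id = 1, value = 1, gapfill_fraction = 0),
    data.frame(region_id = 1, value = 0, gapfill_fraction = 0)),
    weights = c(0.7, 0.3))
  expect_equal(wt$value, 0.7)

  expect_error(compute_status(list()), "no layers", class = "ogf_score_error")
})

test_that("trend is five times the OLS slope of the five most recent years, clamped", {
  expect_equal(compute_trend(c(0.50, 0.52, 0.54, 0.56, 0.58), 2010:2014), 0.1)
  expect_equal(compute_trend(rep(0.4, 5), 2010:2014), 0)
  expect_equal(compute_trend(c(0.0, 0.3, 0.6, 0.9, 0.9), 2010:2014), 1)  # clamp
  # only the five most recent years enter
  expect_equal(compute_trend(c(0.9, 0.50, 0.52, 0.54, 0.56, 0.58), 2009:2014),
               0.1)
  expect_error(compute_trend(c(0.1, 0.2, 0.3, 0.4), 2011:2014),
               "at least 5", class = "ogf_score_error")
})

test_that("goal score follows the future-state formula and attributes gapfill", {
  gs <- compute_goal_score(0.8, 0.1, 0.4, 0.5, beta = 0.67)
  expect_equal(gs$future, 0.88, tolerance = 1e-12)
  expect_equal(gs$score, 0.84, tolerance = 1e-12)

  # fixed point: no trend, pressure = resilience
  expect_equal(compute_goal_score(0.62, 0, 0.3, 0.3)$score, 0.62)

  # fully gapfilled status, clean elsewhere: default component weights
  expect_equal(compute_goal_score(0.8, 0.1, 0.4, 0.5,
                                  gf_status = 1)$gapfill_fraction, 0.883)
  expect_error(compute_goal_score(0.8, NA, 0.4, 0.5), "must be defined",
               class = "ogf_score_error")
})

test_that("index and global aggregation behave as weighted means", {
  expect_equal(compute_index(c(0.8, 0.6), c(0, 0))$index, 0.7)
  expect_equal(compute_index(c(0.8, 0.6), c(0, 0))$gapfill_fraction, 0)
  expect_equal(compute_index(c(0.8, 0.6), c(1, 0))$gapfill_fraction, 0.5)
  # zero-weight goals drop from both averages symmetrically
  r <- compute_index(c(0.8, 0.6, 0.1), c(1, 0, 1), goal_weights = c(1, 1, 0))
  expect_equal(r$index, 0.7)
  expect_equal(r$gapfill_fraction, 0.5)
  expect_error(compute_index(0.5, 0, goal_weights = 0), "positive weight",
               class = "ogf_score_error")

  expect_equal(compute_global(c(80, 60), c(3, 1)), 75)
  expect_equal(compute_global(c(80, 60), c(2, 2)), 70)
  expect_equal(compute_global(42, 7), 42)
  expect_error(compute_global(c(80, 60), c(3, NA)), "area missing",
               class = "ogf_score_error")
})

test_that("weighted SD matches hand computations", {
  expect_equal(weighted_sd(rep(3.3, 5)), 0)
  expect_equal(weighted_sd(c(0, 10)), 5)
  expect_equal(weighted_sd(c(0, 10), c(3, 1)), sqrt(18.75))
  expect_error(weighted_sd(c(1, 2), c(0, 0)), "zero total",
               class = "ogf_weight_error")
})

test_that("propagation bounds and monotonicity hold over random trees", {
  set.seed(9)
  for (k in 1:200) {
    n <- sample(2:8, 1)
    f <- runif(n)
    w <- runif(n)
    out <- propagate_gapfill(f, w)
    expect_gte(out, 0); expect_lte(out, 1)
    i <- sample(n, 1)
    f2 <- f; f2[i] <- 1                       # flip one flag upward
    expect_gte(propagate_gapfill(f2, w), out - 1e-12)
  }
  # 0 iff all positively weighted inputs are 0; 1 iff all are 1
  expect_equal(propagate_gapfill(c(0, 1), c(1, 0)), 0)
  expect_equal(propagate_gapfill(c(1, 0), c(1, 0)), 1)
})

test_that("staged propagation equals single-pass propagation with product weights", {
  set.seed(10)
  for (k in 1:50) {
    n_goal <- sample(2:4, 1)
    leaves <- lapply(seq_len(n_goal), function(g) {
      n <- sample(2:5, 1)
      list(f = runif(n), w = runif(n) + 0.01)
    })
    W <- runif(n_goal) + 0.01
    staged <- propagate_gapfill(
      vapply(leaves, function(l) propagate_gapfill(l$f, l$w), 1.0), W)
    flat_f <- unlist(lapply(leaves, `[[`, "f"))
    flat_w <- unlist(lapply(seq_len(n_goal), function(g)
      W[g] * leaves[[g]]$w / sum(leaves[[g]]$w)))
    expect_equal(staged, propagate_gapfill(flat_f, flat_w),
                 tolerance = 1e-12)
  }
})

test_that("one propagation path serves scores and gapfill alike", {
  # feeding the scores themselves through the propagation primitive
  # reproduces the score aggregation
  sc <- c(0.8, 0.6, 0.4)
  w <- c(2, 1, 1)
  expect_equal(propagate_gapfill(sc, w), sum(sc * w) / sum(w))
  expect_equal(compute_index(sc, sc, w)$index,
               compute_index(sc, sc, w)$gapfill_fraction)
})
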