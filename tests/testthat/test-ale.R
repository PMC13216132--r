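test_that("a model that ignores the feature has an identically zero curve", {
  df <- make_driver_samples(300, driver = "slope", coef = 5, seed = 71)
  ignore_model <- function(d) 0.3 + 0.4 * (d$slope > 0)
  cv <- ale_curve(ignore_model, df, "TPI_50m", n_bins = 10)
  expect_equal(cv$ale, rep(0, length(cv$ale)))
  expect_false(cv$degenerate)
})

test_that("ALE of a linear probability model recovers the slope", {
  set.seed(72)
  n <- 2000
  df <- data.frame(x = runif(n, 0, 50), z = rnorm(n))
  lin <- function(d) 0.2 + 0.01 * d$x
  cv <- ale_curve(lin, df, "x", n_bins = 10)
  fit <- lm(cv$ale ~ cv$centers)
  expect_lt(abs(coef(fit)[2] - 0.01) / 0.01, 0.05)
})

test_that("ale_curve matches the definition-level double-loop oracle", {
  # closed-form nonlinear model
  set.seed(73)
  df <- data.frame(x = rnorm(200), y = runif(200))
  nonlin <- function(d) plogis(d$x^2 - 2 * d$y)
  cv <- ale_curve(nonlin, df, "x", n_bins = 12)
  expect_lt(max(abs(cv$ale - oracle_ale(nonlin, df, "x", 12))), 1e-12)

  # fitted random forest, both features, up to 500 rows
  samp <- make_driver_samples(500, driver = "TPI_500m", coef = -4,
                              noise = 1, seed = 74)
  m <- fit_cover_model(samp, model_config(seed = 75))
  predfun <- function(d) predict_closed_prob(m, d)
  for (f in c("TPI_500m", "slope")) {
    cv <- ale_curve(m, samp, f, n_bins = 20)
    expect_lt(max(abs(cv$ale - oracle_ale(predfun, samp, f, 20))), 1e-12)
    # weights count every row exactly once
    expect_identical(sum(cv$weights), 500L)
  }
})

test_that("curves are weight-centred and edges strictly increasing", {
  for (s in 1:5) {
    df <- make_driver_samples(200, coef = -3, noise = 1, seed = 80 + s)
    m <- fit_cover_model(df, model_config(seed = 90 + s))
    cv <- ale_curve(m, df, "TPI_500m", n_bins = 15)
    expect_lt(abs(sum(cv$weights * cv$ale) / sum(cv$weights)), 1e-10)
    expect_true(all(diff(cv$edges) > 0))
    expect_length(cv$ale, length(cv$edges) - 1L)
  }
})

test_that("heavily tied features merge duplicate quantile edges", {
  set.seed(76)
  df <- data.frame(x = sample(c(0, 0, 0, 1, 5), 300, replace = TRUE),
                   y = rnorm(300))
  mod <- function(d) plogis(d$x - d$y)
  cv <- ale_curve(mod, df, "x", n_bins = 20)
  expect_true(all(diff(cv$edges) > 0))
  expect_lt(length(cv$ale), 20)
  expect_lt(max(abs(cv$ale - oracle_ale(mod, df, "x", 20))), 1e-12)
})

test_that("a constant feature yields a flagged zero curve", {
  df <- data.frame(x = rep(2.5, 50), y = rnorm(50))
  cv <- ale_curve(function(d) plogis(d$y), df, "x")
  expect_true(cv$degenerate)
  expect_equal(cv$ale, 0)
  expect_identical(as.numeric(effect_direction(cv)), 0)
  expect_true(attr(effect_direction(cv), "degenerate"))
})

test_that("effect direction reads sign and monotonicity off the curve", {
  up <- structure(list(feature = "f", edges = 0:10, centers = 1:10 - 0.5,
                       ale = seq(-0.1, 0.1, length.out = 10),
                       weights = rep(10, 10), degenerate = FALSE),
                  class = "ale_curve")
  expect_equal(as.numeric(effect_direction(up)), 1)
  down <- up; down$ale <- rev(up$ale)
  expect_equal(as.numeric(effect_direction(down)), -1)
  # symmetric V centred at zero: no signed direction, strong |x| effect
  vshape <- up
  vshape$centers <- seq(-4.5, 4.5, by = 1)
  vshape$ale <- abs(vshape$centers) / 10 - 0.25
  dir_v <- as.numeric(effect_direction(vshape))
  expect_equal(dir_v, cor(vshape$centers, vshape$ale, method = "spearman"))
  expect_lt(abs(dir_v), 0.2)
  expect_equal(as.numeric(abs_effect_direction(vshape)), 1)
  # positive-support feature: |x| = x, so both directions coincide
  expect_equal(as.numeric(abs_effect_direction(up)),
               as.numeric(effect_direction(up)))
})

test_that("ALE recovers additive components up to a constant", {
  set.seed(77)
  n <- 5000
  df <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  g <- function(x) 0.15 * sin(pi * x)
  h <- function(x) 0.1 * x^3
  mod <- function(d) 0.5 + g(d$x1) + h(d$x2)
  cv <- ale_curve(mod, df, "x1", n_bins = 20)
  # for an additive model the accumulated value of bin k equals g at the
  # bin's upper edge, up to the centring constant
  target <- g(cv$edges[-1])
  target <- target - sum(cv$weights * target) / sum(cv$weights)
  expect_lt(max(abs(cv$ale - target)), 0.05 * diff(range(g(df$x1))))
})

test_that("a permuted label-irrelevant feature carries no real effect", {
  # its ALE amplitude is dwarfed by the driver's, and its direction has no
  # systematic sign across seeds
  stats <- vapply(1:20, function(s) {
    df <- make_driver_samples(300, driver = "TPI_5000m", coef = 5,
                              noise = 0.5, seed = 500 + s)
    set.seed(600 + s)
    df$aspect_sin <- sample(df$aspect_sin)   # model-irrelevant, permuted
    m <- fit_cover_model(df, model_config(seed = 700 + s))
    perm <- ale_curve(m, df, "aspect_sin", 10)
    drv <- ale_curve(m, df, "TPI_5000m", 10)
    c(as.numeric(effect_direction(perm)),
      diff(range(perm$ale)) / diff(range(drv$ale)))
  }, numeric(2))
  expect_lt(abs(mean(stats[1, ])), 0.25)
  expect_lt(mean(stats[2, ]), 0.2)
})

test_that("curves serialize to a tidy per-bin table", {
  df <- make_driver_samples(100, coef = 2, seed = 78)
  cv <- ale_curve(function(d) plogis(d$TPI_500m), df, "TPI_500m", 8)
  tab <- as.data.frame(cv)
  expect_named(tab, c("feature", "edge_lo", "edge_hi", "center", "ale",
                      "weight"))
  expect_identical(nrow(tab), length(cv$ale))
  expect_true(all(tab$edge_hi > tab$edge_lo))
})
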