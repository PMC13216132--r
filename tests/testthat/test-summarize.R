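# shared small synthetic scene: 6 mosaic tiles of 48x48, single negative
# TPI_500m driver, noise-free
scene <- local({
  el <- generate_elevation(terrain_spec(c(96, 144), amplitude = 15,
                                        seed = 81))
  veg <- generate_vegetation(el, vegetation_spec(c(TPI_500m = -5),
                                                 noise_sd = 0, seed = 82))
  list(el = el, veg = veg,
       feats = feature_stack(el),
       lt = landscape_table(veg$labels, elev = el, tile_size = 48))
})

test_that("composition subsets partition the mosaic tiles", {
  lt <- data.frame(tile_id = 1:5,
                   fraction_closed = c(0.1, 0.5, 0.9, 0.34, 0.7),
                   landscape_class = factor(rep("mosaic", 5)))
  ss <- composition_subsets(lt)
  expect_identical(ss$mostly_open, 1L)
  expect_setequal(ss$balanced, c(2L, 4L))
  expect_setequal(ss$mostly_closed, c(3L, 5L))
  expect_setequal(unlist(ss), lt$tile_id)
})

test_that("regional model recovers a single noise-free driver", {
  reg <- run_regional(scene$veg$labels, scene$feats, scene$lt,
                      model_config(seed = 83), seed = 84, n_per_class = 50)
  expect_gte(reg$accuracy, 0.9)
  expect_identical(reg$top_feature, "TPI_500m")
  expect_lt(reg$directions[["TPI_500m"]], -0.8)
  expect_equal(sum(reg$importance), 1, tolerance = 1e-9)
  expect_named(reg$subsets, c("mostly_open", "balanced", "mostly_closed"))
})

test_that("opposing drivers in two regions cancel in the pooled model", {
  el <- generate_elevation(terrain_spec(c(48, 96), amplitude = 15, seed = 85))
  # west half: closed in valleys; east half: closed on crests
  west <- mt_raster(el$values[, 1:48], cell_size = 30)
  east <- mt_raster(el$values[, 49:96], cell_size = 30)
  vw <- generate_vegetation(west, vegetation_spec(c(TPI_500m = -4),
                                                  noise_sd = 0.5, seed = 86))
  ve <- generate_vegetation(east, vegetation_spec(c(TPI_500m = 4),
                                                  noise_sd = 0.5, seed = 87))
  lab <- mt_raster(cbind(vw$labels$values, ve$labels$values), cell_size = 30)
  feats <- feature_stack(el)
  lt <- landscape_table(lab, elev = el, tile_size = 48)
  samples <- sample_regional(lab, feats, lt, n_per_class = 200, seed = 88)
  fit_dir <- function(rows, seed) {
    sp <- split_train_test(rows, 0.8, seed)
    m <- fit_cover_model(sp$train, model_config(seed = seed))
    as.numeric(effect_direction(ale_curve(m, sp$train, "TPI_500m", 20)))
  }
  pooled <- fit_dir(samples, 89)
  d1 <- fit_dir(samples[samples$tile_id == 1, ], 90)
  d2 <- fit_dir(samples[samples$tile_id == 2, ], 91)
  expect_lt(abs(pooled), abs(d1))
  expect_lt(abs(pooled), abs(d2))
  expect_lt(d1 * d2, 0)   # opposite signs recovered per region
})

test_that("local models recover the driver tile by tile", {
  loc <- run_local(scene$veg$labels, scene$feats, scene$lt,
                   model_config(seed = 92), seed = 93, n_total = 1000)
  expect_identical(nrow(loc), 6L)
  expect_true(all(!loc$skipped))
  expect_true(all(loc$accuracy > 0.9))
  expect_true(all(loc$top_feature == "TPI_500m"))
  expect_true(all(loc$dir_TPI_500m < -0.8))
  s <- attr(loc, "summary")
  expect_equal(s$n_fitted, 6L)
  expect_equal(s$mean_accuracy, mean(loc$accuracy))
  # full determinism of the per-landscape table
  loc2 <- run_local(scene$veg$labels, scene$feats, scene$lt,
                    model_config(seed = 92), seed = 93, n_total = 1000)
  expect_identical(loc, loc2)
})

test_that("an empty mosaic set yields an empty result with a warning", {
  lt <- scene$lt
  lt$landscape_class[] <- "homogeneous_open"
  expect_warning(out <- run_local(scene$veg$labels, scene$feats, lt,
                                  model_config(), seed = 1), "no mosaic")
  expect_identical(nrow(out), 0L)
})

test_that("2-d binning masks sparse bins and conserves landscapes", {
  set.seed(94)
  tb <- data.frame(x = c(rep(0.1, 9), rep(0.9, 10)),
                   y = c(rep(0.1, 9), rep(0.9, 10)),
                   fraction_closed = c(runif(9), rep(0.4, 10)))
  b <- bin_2d(tb, "x", "y", n_bins = 2, min_count = 10)
  expect_true(is.na(b$stat[1, 1]))          # 9 landscapes -> masked
  expect_equal(b$stat[2, 2], 0.4)           # 10 identical -> their value
  expect_equal(sum(b$count), nrow(tb))
})

test_that("relate reports exact binned means and a rank correlation", {
  tb <- data.frame(acc = c(rep(0.6, 6), rep(0.8, 6)),
                   rough = c(rep(1, 6), rep(9, 6)))
  r <- relate(tb, "acc", "rough", n_bins = 2)
  expect_equal(r$bins$mean, c(0.6, 0.8))
  expect_equal(r$bins$n, c(6L, 6L))
  expect_gt(as.numeric(r$rho), 0)
  # constructed negative relation
  set.seed(95)
  tb2 <- data.frame(acc = 0.9 - 0.03 * (1:30) + rnorm(30, 0, 0.01),
                    rough = 1:30)
  expect_lt(as.numeric(relate(tb2, "acc", "rough")$rho), -0.9)
  # independent covariate stays near zero across seeds
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    as.numeric(relate(data.frame(acc = runif(40), rough = runif(40)),
                      "acc", "rough")$rho)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)
  # constant covariate is degenerate
  const <- relate(data.frame(acc = runif(12), rough = rep(2, 12)),
                  "acc", "rough")
  expect_true(is.na(const$rho))
  expect_true(attr(const$rho, "degenerate"))
})
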