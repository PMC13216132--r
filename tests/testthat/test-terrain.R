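test_that("TPI matches hand-computed values on degenerate grids", {
  flat <- mt_raster(matrix(7, 9, 9), cell_size = 30)
  for (r in c(50, 500, 5000))
    expect_equal(tpi(flat, r)$values, matrix(0, 9, 9))

  # single raised cell (+10 m) in a flat 9x9 grid, 3x3 window
  peak <- mt_raster(matrix(0, 9, 9), cell_size = 30)
  peak$values[5, 5] <- 10
  expect_equal(tpi(peak, 30)$values[5, 5], 10 - 10 / 9)
  expect_equal(tpi(peak, 30)$values[5, 4], 0 - 10 / 9)
  expect_error(tpi(peak, 10), "radius")
})

test_that("TPI equals the literal windowed-mean oracle at all radii", {
  set.seed(21)
  m <- matrix(rnorm(50 * 50, 500, 40), 50, 50)
  r50 <- mt_raster(m, cell_size = 30)
  for (radius in c(50, 500)) {
    expect_equal(tpi(r50, radius)$values, oracle_tpi(m, 30, radius),
                 tolerance = 1e-9)
  }
  # 5000 m radius: window much wider than the grid, multi-fold reflection
  m2 <- matrix(rnorm(20 * 20, 500, 40), 20, 20)
  r20 <- mt_raster(m2, cell_size = 30)
  expect_equal(tpi(r20, 5000)$values, oracle_tpi(m2, 30, 5000),
               tolerance = 1e-9)
})

test_that("TPI excludes nodata from the neighbourhood mean", {
  set.seed(22)
  m <- matrix(rnorm(20 * 20), 20, 20)
  m[sample(400, 30)] <- NA
  r <- mt_raster(m, cell_size = 30)
  expect_equal(tpi(r, 90)$values, oracle_tpi(m, 30, 90), tolerance = 1e-9)
})

test_that("TPI is linear in elevation and has near-zero grid mean", {
  set.seed(23)
  m <- matrix(rnorm(40 * 40, 0, 10), 40, 40)
  r <- mt_raster(m, cell_size = 30)
  t1 <- tpi(r, 150)$values
  r2 <- mt_raster(3.5 * m + 100, cell_size = 30)
  expect_equal(tpi(r2, 150)$values, 3.5 * t1, tolerance = 1e-9)
  expect_lt(abs(mean(t1)), 1e-6 * sd(as.vector(m)))
})

test_that("slope and aspect match analytic planes", {
  n <- 12
  # z = -3 per column step of 30 m: descends eastward at 0.1 m/m
  east <- mt_raster(outer(rep(0, n), seq_len(n)) +
                      matrix(rep(-3 * seq_len(n), each = n), n, n),
                    cell_size = 30)
  sl <- horn_slope(east)$values
  expect_equal(sl[2:(n - 1), 2:(n - 1)],
               matrix(atan(0.1) * 180 / pi, n - 2, n - 2),
               tolerance = 1e-9)
  asp <- aspect_components(east)
  expect_equal(asp$aspect_sin$values[2:(n - 1), 2:(n - 1)],
               matrix(1, n - 2, n - 2), tolerance = 1e-12)
  expect_equal(asp$aspect_cos$values[2:(n - 1), 2:(n - 1)],
               matrix(0, n - 2, n - 2), tolerance = 1e-12)

  # descending northward: row index grows southward, so z increasing with
  # row descends toward the top (north)
  north <- mt_raster(matrix(rep(3 * seq_len(n), times = n), n, n),
                     cell_size = 30)
  aspn <- aspect_components(north)
  expect_equal(aspn$aspect_sin$values[2:(n - 1), 2:(n - 1)],
               matrix(0, n - 2, n - 2), tolerance = 1e-12)
  expect_equal(aspn$aspect_cos$values[2:(n - 1), 2:(n - 1)],
               matrix(1, n - 2, n - 2), tolerance = 1e-12)

  # flat grid: zero slope, sentinel aspect
  flat <- mt_raster(matrix(5, n, n), cell_size = 30)
  expect_equal(horn_slope(flat)$values, matrix(0, n, n))
  af <- aspect_components(flat)
  expect_equal(af$aspect_sin$values, matrix(0, n, n))
  expect_equal(af$aspect_cos$values, matrix(0, n, n))
})

test_that("doubling the cell size halves the slope tangent", {
  set.seed(24)
  m <- matrix(rnorm(15 * 15, 0, 5), 15, 15)
  s1 <- horn_slope(mt_raster(m, cell_size = 30))$values
  s2 <- horn_slope(mt_raster(m, cell_size = 60))$values
  expect_equal(tan(s2 * pi / 180), tan(s1 * pi / 180) / 2, tolerance = 1e-12)
})

test_that("slope and aspect match the literal Horn stencil oracle", {
  set.seed(25)
  m <- matrix(rnorm(50 * 50, 100, 20), 50, 50)
  r <- mt_raster(m, cell_size = 30)
  o <- oracle_slope_aspect(m, 30)
  expect_equal(horn_slope(r)$values, o$slope, tolerance = 1e-9)
  asp <- aspect_components(r)
  expect_equal(asp$aspect_sin$values, o$aspect_sin, tolerance = 1e-9)
  expect_equal(asp$aspect_cos$values, o$aspect_cos, tolerance = 1e-9)
  # unit circle identity wherever slope > 0
  pos <- horn_slope(r)$values > 0
  expect_equal(asp$aspect_sin$values[pos]^2 + asp$aspect_cos$values[pos]^2,
               rep(1, sum(pos)), tolerance = 1e-12)
  # invariance to a constant elevation shift
  r2 <- mt_raster(m + 1000, cell_size = 30)
  expect_equal(horn_slope(r2)$values, o$slope, tolerance = 1e-9)
  expect_error(horn_slope(mt_raster(matrix(1, 2, 2))), "3x3")
})

test_that("tile roughness is the population standard deviation", {
  expect_equal(tile_roughness(mt_raster(matrix(4, 10, 10))), 0)
  two <- mt_raster(matrix(c(0, 10), 4, 4))
  expect_equal(tile_roughness(two), 5)
  set.seed(26)
  m <- matrix(rnorm(64, 50, 12), 8, 8)
  expect_equal(tile_roughness(mt_raster(m)),
               sqrt(mean((m - mean(m))^2)))
  # windowed form
  r <- mt_raster(m)
  w <- data.frame(row0 = 1, row1 = 4, col0 = 1, col1 = 4)
  sub <- m[1:4, 1:4]
  expect_equal(tile_roughness(r, w), sqrt(mean((sub - mean(sub))^2)))
  # fewer than two valid cells is undefined
  nearly <- mt_raster(matrix(NA_real_, 3, 3)); nearly$values[1, 1] <- 5
  expect_warning(out <- tile_roughness(nearly), "fewer than 2")
  expect_true(is.na(out))
})

test_that("feature_stack produces the six canonical predictors", {
  set.seed(27)
  el <- mt_raster(matrix(rnorm(400, 0, 10), 20, 20), cell_size = 30)
  fs <- feature_stack(el)
  expect_named(fs, TOPO_FEATURES)
  ft <- feature_table(fs)
  expect_identical(nrow(ft), 400L)
  expect_true(all(TOPO_FEATURES %in% names(ft)))
  expect_equal(ft$TPI_500m[ft$row == 3 & ft$col == 7],
               fs$TPI_500m$values[3, 7])
})
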