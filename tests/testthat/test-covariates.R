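test_that("Horn slope is exact on planar surfaces (interior cells)", {
  flat <- matrix(123.4, 6, 8)
  expect_true(all(slope_percent(flat, 50) == 0))

  # plane z = 0.1 x: 10% grade regardless of cell size
  for (cs in c(10, 50, 1000)) {
    z <- outer(seq_len(7), seq_len(9), function(r, co) 0.1 * cs * co)
    s <- slope_percent(z, cs)
    expect_equal(s[2:6, 2:8], matrix(10, 5, 7), tolerance = 1e-9)
  }

  # plane z = 0.3 x + 0.4 y -> 50%
  z <- outer(seq_len(7), seq_len(9),
             function(r, co) 0.3 * 50 * co + 0.4 * 50 * r)
  expect_equal(slope_percent(z, 50)[2:6, 2:8], matrix(50, 5, 7),
               tolerance = 1e-9)

  # random planes match the analytic gradient magnitude
  set.seed(7)
  for (i in 1:10) {
    a <- runif(1, -0.5, 0.5); b <- runif(1, -0.5, 0.5)
    z <- outer(seq_len(6), seq_len(6),
               function(r, co) a * 25 * co + b * 25 * r)
    expect_equal(slope_percent(z, 25)[2:5, 2:5],
                 matrix(100 * sqrt(a^2 + b^2), 4, 4), tolerance = 1e-9)
  }
  expect_error(slope_percent(matrix(0, 2, 5), 10), "3 x 3")
})

test_that("block-mean aggregation handles no-data and partial blocks", {
  expect_true(all(aggregate_mean(matrix(7, 6, 6), 3) == 7))
  expect_equal(aggregate_mean(matrix(c(0, 0, 2, 2), 2, 2), 2),
               matrix(1, 1, 1))
  # mean over valid cells only
  expect_equal(aggregate_mean(matrix(c(1, NA, 3, NA), 2, 2), 2),
               matrix(2, 1, 1))
  expect_true(is.na(aggregate_mean(matrix(NA_real_, 2, 2), 2)[1, 1]))

  # 5x5 with factor 2: trailing blocks averaged over available cells
  m <- matrix(seq_len(25), 5, 5)
  expect_message(cg <- aggregate_mean(m, 2), "partial")
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    rows <- intersect((2 * i - 1):(2 * i), 1:5)
    cols <- intersect((2 * j - 1):(2 * j), 1:5)
    oracle[i, j] <- mean(m[rows, cols])
  }
  expect_equal(cg, oracle)

  # commutes with affine rescaling
  set.seed(11)
  m <- matrix(rnorm(64), 8, 8)
  expect_equal(aggregate_mean(3 * m + 2, 4), 3 * aggregate_mean(m, 4) + 2,
               tolerance = 1e-12)
  expect_error(aggregate_mean(m, 0), "positive integer")
})

test_that("line density equals clipped length over cell area exactly", {
  g1 <- grid_spec(0, 0, 10000, 1, 1)
  expect_true(all(line_density(line_feature_set(list(), "road"),
                               g1)$values == 0))

  horiz <- line_feature_set(list(cbind(c(0, 10000), c(5000, 5000))), "road")
  expect_equal(line_density(horiz, g1)$values[1, 1], 0.1)

  diag <- line_feature_set(list(cbind(c(0, 10000), c(0, 10000))), "road")
  expect_equal(line_density(diag, g1)$values[1, 1], 10 * sqrt(2) / 100,
               tolerance = 1e-12)

  # a segment crossing three cells leaves 10 km in each
  g3 <- grid_spec(0, 0, 10000, 1, 3)
  across <- line_feature_set(list(cbind(c(0, 30000), c(2000, 2000))), "road")
  expect_equal(as.vector(line_density(across, g3)$values), rep(0.1, 3))

  # additive over feature sets
  both <- line_feature_set(list(cbind(c(0, 10000), c(5000, 5000)),
                                cbind(c(0, 10000), c(0, 10000))), "road")
  expect_equal(line_density(both, g1)$values,
               line_density(horiz, g1)$values + line_density(diag, g1)$values,
               tolerance = 1e-12)

  # invariant to vertex subdivision
  set.seed(3)
  g <- grid_spec(0, 0, 5000, 4, 4)
  p1 <- runif(2, 0, 20000); p2 <- runif(2, 0, 20000)
  whole <- line_feature_set(list(rbind(p1, p2)), "path")
  ts <- sort(runif(5))
  pts <- rbind(p1, t(sapply(ts, function(t) p1 + t * (p2 - p1))), p2)
  split <- line_feature_set(list(pts), "path")
  expect_equal(line_density(whole, g)$values, line_density(split, g)$values,
               tolerance = 1e-12)
  expect_equal(line_density(whole, g)$name, "path_density")
})

test_that("population density conserves people and weights by overlap area", {
  g <- grid_spec(0, 0, 1000, 2, 2)
  cell_km2 <- 1

  # one polygon covering the whole grid: uniform density P/A
  whole <- population_polygons(
    list(cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000))), 400)
  pd <- population_density(whole, g)
  expect_true(all(pd$values == 100))

  # polygon covering exactly half of one cell: d/2 there, 0 elsewhere
  half <- population_polygons(
    list(cbind(c(0, 1000, 1000, 0), c(0, 0, 500, 500))), 50)
  # density d = 50 / 0.5 km2 = 100 people/km2; cell mean = 100 * 0.5 = 50
  pd <- population_density(half, g)
  expect_equal(pd$values[1, 1], 50)
  expect_equal(sum(pd$values), 50)

  expect_true(all(population_density(population_polygons(list(), numeric(0)),
                                     g)$values == 0))

  # conservation on random triangles inside the grid
  set.seed(21)
  g4 <- grid_spec(0, 0, 1000, 4, 4)
  for (i in 1:8) {
    tri <- matrix(runif(6, 200, 3800), 3, 2)
    pop <- runif(1, 10, 5000)
    pd <- population_density(population_polygons(list(tri), pop), g4)
    expect_equal(sum(pd$values) * 1, pop, tolerance = 1e-6)
  }

  # zero-area polygons are skipped with a warning
  degen <- population_polygons(
    list(cbind(c(0, 1000, 2000), c(0, 1000, 2000))), 10)
  expect_warning(pd <- population_density(degen, g), "zero-area")
  expect_true(all(pd$values == 0))
})

test_that("log transform uses ln(value + offset) with a sane default offset", {
  g <- grid_spec(0, 0, 1000, 1, 3)
  layer <- covariate_layer(g, matrix(c(0, exp(1) - 1, 10), 1, 3),
                           "population_density", "people/km2")
  lg <- log_density(layer, offset = 1)
  expect_equal(lg$values[1, 1], 0)
  expect_equal(lg$values[1, 2], 1)
  expect_equal(lg$name, "log_population_density")

  # default offset: smallest positive value
  layer2 <- covariate_layer(g, matrix(c(0, 0.25, 4), 1, 3), "pop", "")
  expect_equal(log_density(layer2)$values[1, 1], log(0.25))

  # order preserved
  set.seed(5)
  v <- matrix(rexp(12), 3, 4)
  l3 <- covariate_layer(grid_spec(0, 0, 1, 3, 4), v, "x", "")
  expect_equal(order(log_density(l3)$values), order(v))

  expect_error(log_density(layer, offset = 0), "positive")
  expect_error(log_density(covariate_layer(g, matrix(-1, 1, 3), "x", "")),
               "nonnegative")
})
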