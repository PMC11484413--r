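test_that("digitization grid reproduces the worked resolution examples", {
  m300 <- machine_spec(n_leaf_pairs = 30L, leaf_widths = rep(10, 30),
                       field_height = 400)
  g <- build_grid(m300, 0.1)
  expect_identical(g$n_leaf_index, 3000L)
  expect_identical(g$n_position_index, 4000L)

  # one-pixel axis degenerate case
  m1 <- machine_spec(n_leaf_pairs = 1L, leaf_widths = 10,
                     field_height = 10)
  expect_identical(build_grid(m1, 10)$n_leaf_index, 1L)

  expect_error(build_grid(m300, -1), "positive")
  expect_error(build_grid(m300, 0.3), "divide|partition")
})

test_that("grid row ranges partition the leaf axis", {
  g <- build_grid(tiny_machine(), 2)
  expect_equal(length(g$row_of_pair), g$n_leaf_index)
  expect_equal(as.integer(table(g$row_of_pair)), rep(5L, 4))
  expect_equal(unname(g$row_ranges["first", 1]), 1L)
  expect_equal(unname(g$row_ranges["last", 4]), g$n_leaf_index)
})

test_that("rasterizer matches the brute-force pixel oracle on random CPs", {
  grid <- build_grid(tiny_machine(), 2)  # 20 x 20
  set.seed(123)
  for (i in 1:100) {
    ctr <- runif(4, -10, 10); w <- runif(4, 0, 25)
    cp <- list(left_positions = pmax(ctr - w / 2, -20),
               right_positions = pmin(ctr + w / 2, 20))
    a <- rasterize_aperture(cp, grid, cp_index = i)
    expect_identical(a$values, oracle_rasterize(cp, grid))
    expect_true(all(a$values %in% c(0, 1)))
  }
})

test_that("closed pairs produce no open pixels; a 10 mm opening at 1 mm
           resolution opens exactly 100 pixels", {
  grid <- build_grid(tiny_machine(), 1)  # 40 x 40
  closed <- list(left_positions = rep(3, 4), right_positions = rep(3, 4))
  expect_true(all(rasterize_aperture(closed, grid)$values == 0))

  # one pair open (-5, 5): 10 rows x 10 open columns
  cp <- list(left_positions = c(-5, 3, 3, 3),
             right_positions = c(5, 3, 3, 3))
  a <- rasterize_aperture(cp, grid)
  expect_equal(sum(a$values), 100)
  expect_identical(a$values, oracle_rasterize(cp, grid))
})

test_that("intensity maps scale the aperture by dose", {
  grid <- build_grid(tiny_machine(), 2)
  cp <- list(left_positions = rep(-6, 4), right_positions = rep(6, 4))
  a <- rasterize_aperture(cp, grid)
  expect_true(all(intensity_from_aperture(a, 0)$values == 0))
  i2 <- intensity_from_aperture(a, 2)
  expect_equal(i2$values, 2 * a$values)
  expect_equal(max(i2$values), 2)
  expect_error(intensity_from_aperture(a, -1), "non-negative")
})

test_that("featurizing a two-arc 90-CP plan yields 180 per-CP maps", {
  cfg <- sim_config(n_regular = 1, n_anomalous = 0, seed = 5)
  plan <- simulate_regular_plan(cfg, seed = 5)
  grid <- build_grid(cfg$machine, 1.25)
  ft <- featurize_plan(plan, grid, c(64, 64))
  expect_equal(dim(ft$apertures), c(64, 64, 180))
  expect_equal(dim(ft$intensities), c(64, 64, 180))
  expect_equal(length(ft$doses), 180L)
})

test_that("downsampling conserves intensity area and is the identity at
           full resolution", {
  cfg <- tiny_sim_config()
  plan <- simulate_regular_plan(cfg, seed = 9)
  grid <- build_grid(cfg$machine, 1)  # 40 x 40
  full <- featurize_plan(plan, grid)  # identity resize
  k <- 7L
  cp <- control_point(plan, k)
  a <- rasterize_aperture(cp, grid)
  expect_equal(full$apertures[, , k], unname(a$values),
               ignore_attr = TRUE)
  expect_equal(full$intensities[, , k], cp$dose * a$values,
               ignore_attr = TRUE)

  ds <- featurize_plan(plan, grid, c(8, 8))
  # analytic open fraction from the leaf intervals (pixel-center count)
  centers <- grid$centers_x
  for (k in c(1L, 7L, 15L)) {
    cp <- control_point(plan, k)
    open_px <- sum(vapply(seq_len(4), function(p)
      10 * sum(centers > cp$left_positions[p] &
                 centers < cp$right_positions[p]), numeric(1)))
    frac <- open_px / (40 * 40)
    expect_equal(mean(ds$intensities[, , k]), cp$dose * frac,
                 tolerance = 1e-6)
    expect_equal(mean(full$intensities[, , k]), cp$dose * frac,
                 tolerance = 1e-6)
  }
})

test_that("widening a leaf gap never decreases the open pixel count", {
  grid <- build_grid(tiny_machine(), 1)
  set.seed(4)
  for (i in 1:20) {
    ctr <- runif(4, -8, 8); w <- runif(4, 0, 15)
    cp1 <- list(left_positions = ctr - w / 2, right_positions = ctr + w / 2)
    grow <- runif(1, 0, 5)
    cp2 <- list(left_positions = cp1$left_positions - grow,
                right_positions = cp1$right_positions + grow)
    expect_gte(sum(rasterize_aperture(cp2, grid)$values),
               sum(rasterize_aperture(cp1, grid)$values))
  }
})

test_that("featurization is deterministic and validates its inputs", {
  cfg <- tiny_sim_config()
  plan <- simulate_regular_plan(cfg, seed = 2)
  grid <- build_grid(cfg$machine, 1)
  f1 <- featurize_plan(plan, grid, c(8, 8))
  f2 <- featurize_plan(plan, grid, c(8, 8))
  expect_identical(f1, f2)
  expect_error(featurize_plan(plan, grid, c(80, 80)), "larger")
  expect_error(featurize_plan(plan, grid, c(7, 7)), "multiples")
})
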