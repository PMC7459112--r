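test_that("block-mean aggregation: constants, block means, mean preservation", {
  const <- elev_raster(matrix(3, 8, 8), cell_size = 0.2)
  agg <- aggregate_dem(const, 2)
  expect_equal(agg$cell_size, 0.4)
  expect_true(all(agg$values == 3))

  tiny <- elev_raster(matrix(c(1, 3, 2, 4), 2, 2), cell_size = 1)
  expect_equal(as.vector(aggregate_dem(tiny, 2)$values), 2.5)

  set.seed(3)
  r <- elev_raster(matrix(rnorm(24 * 36), 24, 36), cell_size = 0.5)
  for (f in c(2, 3, 4, 6)) {
    expect_equal(mean(aggregate_dem(r, f)$values), mean(r$values),
                 tolerance = 1e-12)
  }
  expect_error(aggregate_dem(r, 1), "factor")
})

test_that("aggregation propagates missingness blockwise", {
  m <- matrix(1, 4, 4)
  m[1:2, 1:2] <- NA       # one all-missing block
  m[1, 3] <- NA           # one partially-missing block
  agg <- aggregate_dem(elev_raster(m, 1), 2)
  expect_true(is.na(agg$values[1, 1]))
  expect_equal(agg$values[1, 2], 1)  # mean over available cells
})

test_that("smoothing: constant invariance, impulse response, edge renorm", {
  const <- elev_raster(matrix(5, 10, 10), cell_size = 1)
  for (k in c("box", "gaussian")) {
    expect_equal(smooth_dem(const, k, 3)$values, const$values,
                 tolerance = 1e-12)
  }
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  sm <- smooth_dem(elev_raster(imp, 1), "box", 3)
  expect_equal(sm$values[4:6, 4:6], matrix(1 / 9, 3, 3), tolerance = 1e-12)
  expect_equal(sm$values[1, 1], 0)
  # a corner cell of a constant field still averages to the constant
  expect_equal(smooth_dem(const, "box", 5)$values[1, 1], 5, tolerance = 1e-12)
  expect_error(smooth_dem(const, "box", 4), "odd")
})

test_that("flat terrain has zero slope, TPI and SD and malt = elevation", {
  flat <- elev_raster(matrix(7, 12, 15), cell_size = 0.2)
  att <- compute_attributes(flat)
  expect_equal(att$sl$values, matrix(0, 12, 15))
  expect_equal(att$tpi$values, matrix(0, 12, 15), tolerance = 1e-12)
  expect_equal(att$sd$values, matrix(0, 12, 15), tolerance = 1e-12)
  expect_equal(att$malt$values, matrix(7, 12, 15), tolerance = 1e-12)
  expect_equal(att$north$values, matrix(0, 12, 15))
  expect_equal(att$east$values, matrix(0, 12, 15))
})

test_that("an east-rising plane gives the analytic slope and west aspect", {
  # z = 0.01 x: gradient 0.01 eastward, downslope faces west
  r <- plane_raster(nrow = 10, ncol = 12, cell_size = 1, ax = 0.01)
  att <- compute_attributes(r)
  interior <- att$sl$values[2:9, 2:11]
  expect_equal(interior, matrix(atan(0.01) * 180 / pi, 8, 10),
               tolerance = 1e-9)
  expect_equal(atan(0.01) * 180 / pi, 0.5729, tolerance = 1e-4)
  expect_equal(att$east$values[2:9, 2:11], matrix(-1, 8, 10),
               tolerance = 1e-12)
  expect_equal(att$north$values[2:9, 2:11], matrix(0, 8, 10),
               tolerance = 1e-12)
  # a north-rising plane faces south: north = -1
  rn <- plane_raster(nrow = 10, ncol = 12, cell_size = 1, ay = 0.02)
  attn <- compute_attributes(rn)
  expect_equal(attn$north$values[2:9, 2:11], matrix(-1, 8, 10),
               tolerance = 1e-12)
})

test_that("TPI is positive at a local peak and negative at its neighbours", {
  m <- matrix(0, 7, 7); m[4, 4] <- 1
  att <- compute_attributes(elev_raster(m, 1))
  expect_equal(att$tpi$values[4, 4], 1)
  expect_true(all(att$tpi$values[3:5, 3:5][-5] < 0))
})

test_that("northness/easterness form a unit vector wherever slope > 0", {
  sim <- small_sim()
  att <- compute_attributes(aggregate_dem(sim$dem, 4))
  sl <- att$sl$values
  norm2 <- att$north$values^2 + att$east$values^2
  expect_true(all(abs(norm2[sl > 0] - 1) < 1e-9))
  expect_true(all(norm2[sl == 0] == 0))
  expect_true(all(att$sd$values >= 0))
})

test_that("disaggregation replicates cells and inverts block structure", {
  one <- elev_raster(matrix(7, 1, 1), cell_size = 2)
  out <- disaggregate(one, 1)
  expect_equal(out$values, matrix(7, 2, 2))

  const <- elev_raster(matrix(2.5, 4, 6), cell_size = 1)
  round_trip <- disaggregate(aggregate_dem(const, 2), 1)
  expect_equal(round_trip$values, const$values)

  set.seed(9)
  r <- elev_raster(matrix(rnorm(48), 6, 8), cell_size = 1)
  dis <- disaggregate(r, 0.5)
  # block means of the fine raster reproduce the coarse values
  back <- aggregate_dem(dis, 2)
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_error(disaggregate(r, 0.3), "integer")
})

test_that("pyramid reports the study resolutions and matches a step-by-step oracle", {
  sim <- small_sim()
  # laser-scan base resolution over a 32 m square
  base <- generate_terrain(terrain_config(nx = 160, ny = 160, cell_size = 0.2,
                                          correlation_length = 6, seed = 2))
  pyr <- build_pyramid(base, max_level = 7, level7_resolution = 10)
  expect_equal(purrr::map_dbl(pyr$levels, "resolution"),
               c(0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 10))

  pyr02 <- build_pyramid(sim$dem, max_level = 3)
  expect_equal(purrr::map_dbl(pyr02$levels, "resolution"), c(0.5, 1, 2))

  # level-3 attributes equal attributes computed independently on the
  # twice-aggregated dem, disaggregated to base
  dem3 <- aggregate_dem(aggregate_dem(sim$dem, 2), 2)
  oracle <- purrr::map(compute_attributes(dem3), disaggregate,
                       target_cell_size = sim$dem$cell_size)
  for (att in names(oracle)) {
    expect_equal(pyr02$levels[[3]]$attributes_base[[att]]$values,
                 oracle[[att]]$values, tolerance = 1e-12)
  }

  # constant dem: every level flat, slope/TPI/SD all zero
  flat <- elev_raster(matrix(1.2, 40, 40), cell_size = 1)
  pf <- build_pyramid(flat, max_level = 5)
  for (L in pf$levels) {
    expect_true(all(abs(L$attributes$sl$values) < 1e-9))
    expect_true(all(abs(L$attributes$tpi$values) < 1e-9))
    expect_true(all(abs(L$attributes$sd$values) < 1e-6))
  }
  expect_error(build_pyramid(elev_raster(matrix(1, 8, 8), 0.2), max_level = 7),
               "too small|at least")
})

test_that("smoothing monotonicity: elevation variance never increases with level", {
  sim <- small_sim()  # 160 x 128 cells: evenly divisible through level 6
  pyr <- build_pyramid(sim$dem, max_level = 6)
  pop_var <- function(v) mean((v - mean(v))^2)
  vars <- purrr::map_dbl(pyr$levels, function(L) pop_var(as.vector(L$dem$values)))
  expect_true(all(diff(vars) <= 1e-12))
})

test_that("TPI has near-zero mean over interior cells of a random field", {
  set.seed(11)
  r <- elev_raster(matrix(rnorm(50 * 60), 50, 60), cell_size = 1)
  tpi <- compute_attributes(r)$tpi$values[5:46, 5:56]
  expect_lt(abs(mean(tpi)), 0.05 * sd(r$values))
})

test_that("terrain extraction matches manual indexing and has contract shape", {
  sim <- small_sim()
  pyr <- build_pyramid(sim$dem, max_level = 5)
  terr <- extract_terrain(pyr, sim$positions)
  expect_equal(nrow(terr), nrow(sim$positions) * 5 * 6)
  wide <- terrain_wide(terr)
  expect_equal(nrow(wide), 78)
  expect_equal(ncol(wide), 1 + 30)

  set.seed(5)
  pick <- sample(nrow(sim$positions), 5)
  for (i in pick) {
    p <- sim$positions[i, ]
    rast <- pyr$levels[[3]]$attributes_base$tpi
    manual <- rast$values[
      nrow(rast$values) - floor(p$y / rast$cell_size),
      floor(p$x / rast$cell_size) + 1
    ]
    got <- terr$value[terr$position_id == p$position_id &
                        terr$level == 3 & terr$attribute == "tpi"]
    expect_equal(got, manual)
  }

  expect_error(
    extract_terrain(pyr, tibble::tibble(position_id = "X", x = -5, y = 2)),
    "outside"
  )
})
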