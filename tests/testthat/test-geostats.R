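test_that("empirical variogram: constants, two-point case, O(n^2) oracle", {
  set.seed(2)
  xy <- tibble::tibble(x = runif(12, 0, 10), y = runif(12, 0, 10))

  const <- dplyr::mutate(xy, value = 4.2)
  g0 <- empirical_variogram(const, value)
  expect_true(all(g0$gamma == 0))

  # two points, values 0 and 2, a single bin spanning their distance:
  # gamma = (0 - 2)^2 / (2 * 1) = 2
  two <- tibble::tibble(x = c(0, 0, 3, 3, 0, 1, 2, 3, 1, 2, 0.5, 2.5),
                        y = c(0, 1, 0, 1, 2, 2, 2, 2, 3, 3, 4, 4),
                        value = rep(c(0, 2), 6))
  # (use >= 10 points for the contract; check one specific bin against hand
  # arithmetic below with the full oracle instead)

  set.seed(3)
  dat <- dplyr::mutate(xy, value = rnorm(12))
  emp <- empirical_variogram(dat, value, n_bins = 6)
  # brute-force double loop over all pairs
  max_lag <- attr(emp, "max_lag")
  breaks <- seq(0, max_lag, length.out = 7)
  acc <- matrix(0, 6, 2)
  for (i in 1:11) for (j in (i + 1):12) {
    d <- sqrt((dat$x[i] - dat$x[j])^2 + (dat$y[i] - dat$y[j])^2)
    if (d > max_lag) next
    b <- findInterval(d, breaks, rightmost.closed = TRUE)
    if (b >= 1 && b <= 6) {
      acc[b, 1] <- acc[b, 1] + (dat$value[i] - dat$value[j])^2
      acc[b, 2] <- acc[b, 2] + 1
    }
  }
  kept <- which(acc[, 2] > 0)
  expect_equal(emp$n_pairs, as.integer(acc[kept, 2]))
  expect_equal(emp$gamma, acc[kept, 1] / (2 * acc[kept, 2]), tolerance = 1e-12)
  expect_error(empirical_variogram(dat[1:5, ], value), "10 points")
})

test_that("variogram fitting: perfect input, nugget limit, model recovery", {
  # perfect model curve as empirical input -> E = 1, SSErr = 0
  h <- seq(2, 40, length.out = 10)
  emp <- tibble::tibble(lag = h,
                        gamma = variogram_value(h, "spherical", 0.2, 1, 25),
                        n_pairs = rep(50L, 10))
  class(emp) <- c("empirical_variogram", class(emp))
  fit <- fit_variogram_model(emp, "spherical")
  expect_equal(fit$e, 1, tolerance = 1e-6)
  expect_lt(fit$sserr, 1e-8)
  expect_equal(fit$nugget, 0.2, tolerance = 1e-3)
  expect_equal(fit$psill, 1, tolerance = 1e-3)
  expect_equal(fit$range_par, 25, tolerance = 1e-2)

  # flat (pure nugget) input: partial sill collapses regardless of family
  flat <- tibble::tibble(lag = h, gamma = rep(0.8, 10), n_pairs = rep(30L, 10))
  class(flat) <- c("empirical_variogram", class(flat))
  for (fam in c("exponential", "gaussian", "spherical")) {
    f <- fit_variogram_model(flat, fam)
    expect_lt(f$psill, 0.01)
    expect_equal(f$nugget + f$psill, 0.8, tolerance = 1e-3)
  }

  # simulated spherical field, n = 200: recovered fit explains the
  # empirical variogram well
  set.seed(10)
  coords <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  z <- sim_gaussian_field(coords, nugget = 0, psill = 1, range_par = 30,
                          family = "spherical", seed = 10)
  dat <- tibble::tibble(x = coords[, 1], y = coords[, 2], value = z)
  emp2 <- empirical_variogram(dat, value, n_bins = 12)
  fit2 <- fit_variogram_model(emp2, "spherical")
  expect_gt(fit2$e, 0.9)
})

test_that("model selection enforces efficiency and range criteria", {
  mk <- function(e, sserr, fam = "spherical", range_par = 30) {
    structure(list(family = fam, nugget = 0, psill = 1, range_par = range_par,
                   practical_range = practical_range <- range_par,
                   sserr = sserr, e = e, n_bins = 10),
              class = "variogram_model")
  }
  # E = 0.4 candidate discarded
  sel <- select_variogram(list(mk(0.9, 2), mk(0.4, 1)), study_diagonal = 100)
  expect_equal(sel$e, 0.9)
  # all below the efficiency bar -> rejection
  rej <- select_variogram(list(mk(0.3, 1), mk(0.5, 1)), study_diagonal = 100)
  expect_s3_class(rej, "variogram_rejection")
  # ranges reaching the site scale are invalid
  rej2 <- select_variogram(list(mk(0.9, 1, range_par = 150)),
                           study_diagonal = 100)
  expect_s3_class(rej2, "variogram_rejection")
  # among survivors the smallest residual sum of squares wins
  sel2 <- select_variogram(list(mk(0.8, 2), mk(0.7, 1)), study_diagonal = 100)
  expect_equal(sel2$sserr, 1)
  expect_error(select_variogram(list(), 100), "Empty")
})

ok_model <- structure(
  list(family = "exponential", nugget = 0, psill = 2, range_par = 15,
       practical_range = 45, sserr = 0, e = 1, n_bins = 10),
  class = "variogram_model")

test_that("ordinary kriging: exactness, constancy, weight normalization", {
  set.seed(6)
  dat <- tibble::tibble(x = runif(8, 0, 20), y = runif(8, 0, 20),
                        value = rnorm(8, 10))
  # prediction at the data points reproduces them with zero variance
  at_data <- krige_ok(dat, value, dat[, c("x", "y")], ok_model)
  expect_equal(at_data$pred, dat$value, tolerance = 1e-8)
  expect_true(all(at_data$var < 1e-8))
  # weights sum to one at every target
  grid <- tidyr::expand_grid(x = seq(1, 19, 3), y = seq(1, 19, 3))
  km <- krige_ok(dat, value, grid, ok_model)
  w <- attr(km, "weights")
  expect_true(all(abs(colSums(w) - 1) < 1e-9))
  expect_true(all(km$var >= 0))
  # constant data predict the constant everywhere
  constd <- dplyr::mutate(dat, value = 7.5)
  kmc <- krige_ok(constd, value, grid, ok_model)
  expect_equal(kmc$pred, rep(7.5, nrow(grid)), tolerance = 1e-9)
  # duplicate locations are reported
  dup <- dplyr::bind_rows(dat, dat[3, ])
  expect_error(krige_ok(dup, value, grid, ok_model), "Duplicate")
})

test_that("OK predictions match a hand-assembled dense solve (5 points)", {
  dat <- tibble::tibble(x = c(0, 10, 3, 7, 5), y = c(0, 0, 8, 2, 5),
                        value = c(1.2, 3.4, 2.2, 0.7, 1.9))
  targets <- tibble::tibble(x = c(4, 8), y = c(4, 6))
  gm <- function(h) variogram_value(h, "exponential", 0, 2, 15)
  for (t in 1:2) {
    # assemble the bordered system explicitly, point by point
    A <- matrix(0, 6, 6)
    for (i in 1:5) for (j in 1:5) {
      A[i, j] <- gm(sqrt((dat$x[i] - dat$x[j])^2 + (dat$y[i] - dat$y[j])^2))
    }
    A[6, 1:5] <- 1; A[1:5, 6] <- 1
    b <- c(sapply(1:5, function(i) gm(sqrt((dat$x[i] - targets$x[t])^2 +
                                             (dat$y[i] - targets$y[t])^2))), 1)
    sol <- solve(A, b)
    pred_oracle <- sum(sol[1:5] * dat$value)
    var_oracle <- sum(sol[1:5] * b[1:5]) + sol[6]
    km <- krige_ok(dat, value, targets[t, ], ok_model)
    expect_equal(km$pred, pred_oracle, tolerance = 1e-10)
    expect_equal(km$var, var_oracle, tolerance = 1e-10)
  }
})

test_that("external-drift kriging: pure-drift limit, OK equivalence, oracle", {
  set.seed(12)
  dat <- tibble::tibble(x = runif(6, 0, 20), y = runif(6, 0, 20),
                        f = runif(6, 1, 3))
  dat$value <- 2 * dat$f
  grid <- tibble::tibble(x = c(5, 12, 18), y = c(5, 9, 14))
  gf <- c(1.5, 2.0, 2.8)
  # values an exact multiple of the drift, nugget 0 -> predictions = 2 * drift
  km <- krige_ked(dat, value, f, grid, gf, ok_model)
  expect_equal(km$pred, 2 * gf, tolerance = 1e-8)

  # constant drift reduces to ordinary kriging
  set.seed(13)
  dat2 <- dplyr::mutate(dat, value = rnorm(6), f = 4)
  expect_message(
    km2 <- krige_ked(dat2, value, f, grid, rep(4, 3), ok_model),
    "reduces to ordinary")
  km_ok <- krige_ok(dat2, value, grid, ok_model)
  expect_equal(km2$pred, km_ok$pred, tolerance = 1e-8)

  # 6-point dense augmented-system oracle
  dat3 <- dplyr::mutate(dat, value = 2 * f + c(0.1, -0.2, 0.05, 0, 0.3, -0.1))
  gm <- function(h) variogram_value(h, "exponential", 0, 2, 15)
  A <- matrix(0, 8, 8)
  for (i in 1:6) for (j in 1:6) {
    A[i, j] <- gm(sqrt((dat3$x[i] - dat3$x[j])^2 + (dat3$y[i] - dat3$y[j])^2))
  }
  A[7, 1:6] <- 1; A[1:6, 7] <- 1
  A[8, 1:6] <- dat3$f; A[1:6, 8] <- dat3$f
  for (t in 1:3) {
    b <- c(sapply(1:6, function(i) gm(sqrt((dat3$x[i] - grid$x[t])^2 +
                                             (dat3$y[i] - grid$y[t])^2))),
           1, gf[t])
    sol <- solve(A, b)
    pred_oracle <- sum(sol[1:6] * dat3$value)
    km3 <- krige_ked(dat3, value, f, grid[t, ], gf[t], ok_model)
    expect_equal(km3$pred, pred_oracle, tolerance = 1e-10)
  }
})

test_that("leave-one-out cross-validation matches hand arithmetic (6 points)", {
  dat <- tibble::tibble(x = c(0, 10, 3, 7, 5, 9), y = c(0, 0, 8, 2, 5, 7),
                        value = c(1.2, 3.4, 2.2, 0.7, 1.9, 2.8))
  cv <- loo_cross_validate(dat, value, ok_model, "ok")
  # manual leave-one-out with krige_ok on each reduced dataset
  manual <- sapply(1:6, function(i) {
    krige_ok(dat[-i, ], value, dat[i, c("x", "y")], ok_model)$pred
  })
  err <- manual - dat$value
  expect_equal(cv$mean_err, mean(err), tolerance = 1e-10)
  expect_equal(cv$nrmse, sqrt(mean(err^2)) / (max(dat$value) - min(dat$value)),
               tolerance = 1e-10)
  expect_error(
    loo_cross_validate(dplyr::mutate(dat, value = 1), value, ok_model, "ok"),
    "span")
})

test_that("MSDR is near one for a well-specified model (simulation)", {
  set.seed(20)
  coords <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  z <- sim_gaussian_field(coords, nugget = 0.1, psill = 1, range_par = 30,
                          family = "exponential", seed = 21)
  dat <- tibble::tibble(x = coords[, 1], y = coords[, 2], value = z)
  model <- structure(
    list(family = "exponential", nugget = 0.1, psill = 1, range_par = 30,
         practical_range = 90, sserr = 0, e = 1, n_bins = 10),
    class = "variogram_model")
  cv <- loo_cross_validate(dat, value, model, "ok")
  expect_lt(abs(cv$msdr - 1), 0.3)
  expect_lt(abs(cv$mean_err), 0.05)
})
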