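#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by separation distance and computes
#' \eqn{\gamma(h) = \frac{1}{2N(h)} \sum (z_i - z_j)^2} per bin.
#'
#' @param data Data frame with coordinate and value columns.
#' @param value Column with the variable (tidy-eval).
#' @param x,y Coordinate columns (tidy-eval; default `x`, `y`).
#' @param n_bins Number of equal-width lag bins.
#' @param max_lag Maximum lag (m); default half the maximum pairwise distance.
#' @return An `empirical_variogram` tibble: `lag` (bin center), `gamma`,
#'   `n_pairs`; attribute `max_lag`.
#' @export
empirical_variogram <- function(data, value, x = x, y = y,
                                n_bins = 10, max_lag = NULL) {
  xs <- dplyr::pull(data, {{ x }})
  ys <- dplyr::pull(data, {{ y }})
  zs <- dplyr::pull(data, {{ value }})
  keep <- stats::complete.cases(xs, ys, zs)
  xs <- xs[keep]; ys <- ys[keep]; zs <- zs[keep]
  n <- length(zs)
  if (n < 10) stop("At least 10 points are required.", call. = FALSE)
  d <- as.vector(stats::dist(cbind(xs, ys)))
  if (max(d) <= 0) stop("All positions are coincident.", call. = FALSE)
  g <- as.vector(stats::dist(zs))^2 / 2
  max_lag <- max_lag %||% (max(d) / 2)
  if (max_lag > max(d)) {
    stop("`max_lag` exceeds the maximum pairwise distance.", call. = FALSE)
  }
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  keep_pair <- !is.na(bin)
  agg <- tibble::tibble(bin = bin[keep_pair], g = g[keep_pair]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(gamma = mean(.data$g), n_pairs = dplyr::n(),
                     .groups = "drop")
  out <- tibble::tibble(
    lag = (breaks[agg$bin] + breaks[agg$bin + 1]) / 2,
    gamma = agg$gamma,
    n_pairs = as.integer(agg$n_pairs)
  )
  attr(out, "max_lag") <- max_lag
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Theoretical variogram families
#'
#' Semivariance \eqn{\gamma(h)} for the exponential, Gaussian and spherical
#' models with nugget `c0`, partial sill `c` and range parameter `r`
#' (`gamma(0) = 0` by convention). The practical (autocorrelation) range is
#' `3r` for the exponential, `sqrt(3) r` for the Gaussian and `r` for the
#' spherical model.
#'
#' @param h Lag distances (m).
#' @param family `"exponential"`, `"gaussian"` or `"spherical"`.
#' @param nugget,psill,range_par Model parameters.
#' @return Numeric vector of semivariances.
#' @export
variogram_value <- function(h, family, nugget, psill, range_par) {
  stopifnot(range_par > 0)
  s <- switch(
    family,
    exponential = 1 - exp(-h / range_par),
    gaussian = 1 - exp(-(h / range_par)^2),
    spherical = ifelse(h < range_par,
                       1.5 * h / range_par - 0.5 * (h / range_par)^3, 1),
    stop("Unknown variogram family: ", family, call. = FALSE)
  )
  ifelse(h <= 0, 0, nugget + psill * s)
}

practical_range <- function(family, range_par) {
  switch(family,
         exponential = 3 * range_par,
         gaussian = sqrt(3) * range_par,
         spherical = range_par)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares over the lag bins, weights equal to the pair counts,
#' via Levenberg-Marquardt with box constraints (`nugget >= 0`,
#' `psill >= 0`). Reports the weighted residual sum of squares (`sserr`) and
#' the Nash-Sutcliffe efficiency `e = 1 - SS_res/SS_tot` computed unweighted
#' on the binned semivariances.
#'
#' @param emp An [empirical_variogram()].
#' @param family Model family (see [variogram_value()]).
#' @return A `variogram_model` list: `family`, `nugget`, `psill`, `range_par`,
#'   `practical_range`, `sserr`, `e`, `n_bins`.
#' @export
fit_variogram_model <- function(emp, family = c("exponential", "gaussian",
                                                "spherical")) {
  family <- match.arg(family)
  if (nrow(emp) < 4) stop("At least 4 variogram bins are required.", call. = FALSE)
  df <- tibble::tibble(h = emp$lag, g = emp$gamma, w = emp$n_pairs)

  # for a fixed range the model is linear in (nugget, psill): profile the
  # range over a grid with non-negative WLS, then polish the best iterate
  # with Levenberg-Marquardt
  nnls2 <- function(s) {
    X <- cbind(1, s)
    # pure-nugget candidate first so flat curves resolve to nugget, not a
    # sub-lag-range sill
    fits <- list(
      c(max(0, stats::weighted.mean(df$g, df$w)), 0),
      tryCatch(stats::lm.wfit(X, df$g, df$w)$coefficients,
               error = function(e) NULL),
      c(0, max(0, sum(df$w * df$g * s) / sum(df$w * s^2)))
    )
    if (!is.null(fits[[2]]) &&
        (anyNA(fits[[2]]) || any(fits[[2]] < 0))) fits[2] <- list(NULL)
    best <- NULL; best_ss <- Inf
    for (cf in fits) {
      if (is.null(cf)) next
      ss <- sum(df$w * (df$g - X %*% cf)^2)
      if (ss < best_ss) { best <- cf; best_ss <- ss }
    }
    list(coef = best, ss = best_ss)
  }
  hmax <- max(df$h)
  grid <- exp(seq(log(hmax / 50), log(3 * hmax), length.out = 40))
  prof <- lapply(grid, function(r) {
    s <- variogram_value(df$h, family, 0, 1, r)
    c(nnls2(s), list(range_par = r))
  })
  best <- prof[[which.min(purrr::map_dbl(prof, "ss"))]]
  p <- list(nugget = best$coef[1], psill = best$coef[2],
            range_par = best$range_par)
  polish <- tryCatch(
    minpack.lm::nlsLM(
      g ~ variogram_value(h, family, nugget, psill, range_par),
      data = df, start = p, weights = df$w,
      lower = c(nugget = 0, psill = 0, range_par = hmax * 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(polish)) {
    cf <- as.list(stats::coef(polish))
    ss_polish <- sum(df$w * (df$g - variogram_value(
      df$h, family, cf$nugget, cf$psill, cf$range_par))^2)
    if (ss_polish < best$ss - 1e-12 * max(best$ss, 1)) p <- cf
  }
  if (any(!is.finite(unlist(p)))) {
    stop("Variogram fit did not converge for the ", family,
         " model (last iterate: nugget=", signif(p$nugget, 4),
         ", psill=", signif(p$psill, 4),
         ", range=", signif(p$range_par, 4), ").", call. = FALSE)
  }
  pred <- variogram_value(df$h, family, p$nugget, p$psill, p$range_par)
  sserr <- sum(df$w * (df$g - pred)^2)
  ss_tot <- sum((df$g - mean(df$g))^2)
  e <- if (ss_tot > 0) 1 - sum((df$g - pred)^2) / ss_tot else NA_real_
  structure(
    list(family = family, nugget = p$nugget, psill = p$psill,
         range_par = p$range_par,
         practical_range = practical_range(family, p$range_par),
         sserr = sserr, e = e, n_bins = nrow(df)),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model> %s: nugget %.4g, psill %.4g, range %.4g (practical %.4g m)\n  SSErr %.4g, E %.3f\n",
    x$family, x$nugget, x$psill, x$range_par, x$practical_range, x$sserr, x$e))
  invisible(x)
}

#' Select a variogram model by efficiency, range and residual criteria
#'
#' Candidates are rejected when the Nash-Sutcliffe efficiency is <= `e_min`
#' or the practical autocorrelation range reaches the spatial scale of the
#' site (the diagonal of the rectangle spanning the data). Among survivors the
#' fit with the smallest residual sum of squares wins. When nothing survives a
#' `variogram_rejection` is returned, signalling that no valid variogram
#' exists and mapping should fall back to external-drift kriging only.
#'
#' @param fits List of [fit_variogram_model()] results.
#' @param study_diagonal Diagonal of the data bounding rectangle (m).
#' @param e_min Efficiency threshold (default 0.5).
#' @return The winning `variogram_model`, or a `variogram_rejection`.
#' @export
select_variogram <- function(fits, study_diagonal, e_min = 0.5) {
  if (!length(fits)) stop("Empty candidate list.", call. = FALSE)
  ok <- purrr::map_lgl(fits, function(f) {
    !is.na(f$e) && f$e > e_min && f$practical_range < study_diagonal
  })
  if (!any(ok)) {
    return(structure(
      list(candidates = purrr::map_chr(fits, "family"),
           e = purrr::map_dbl(fits, "e"),
           practical_range = purrr::map_dbl(fits, "practical_range"),
           reason = sprintf("no candidate with E > %.2f and range < %.1f m",
                            e_min, study_diagonal)),
      class = "variogram_rejection"
    ))
  }
  surv <- fits[ok]
  surv[[which.min(purrr::map_dbl(surv, "sserr"))]]
}

#' @export
print.variogram_rejection <- function(x, ...) {
  cat("<variogram_rejection>", x$reason, "\n")
  invisible(x)
}

#' Diagonal of the bounding rectangle of point locations
#'
#' @param data Data frame with coordinate columns.
#' @param x,y Coordinate columns (tidy-eval).
#' @return Length of the diagonal (m).
#' @export
study_diagonal <- function(data, x = x, y = y) {
  xs <- dplyr::pull(data, {{ x }}); ys <- dplyr::pull(data, {{ y }})
  sqrt(diff(range(xs))^2 + diff(range(ys))^2)
}

# Solve the (universal) kriging system in semivariance form.
# basis_data: n x p matrix of trend basis functions at the data (first column
# must be the intercept); basis_target: m x p at the targets.
krige_solve <- function(coords, z, model, targets, basis_data, basis_target) {
  n <- nrow(coords)
  dup <- duplicated(coords)
  if (any(dup)) {
    stop("Duplicate data locations would make the kriging system singular: ",
         paste(sprintf("(%g, %g)", coords[dup, 1], coords[dup, 2]),
               collapse = ", "), call. = FALSE)
  }
  gmat <- function(d) variogram_value(d, model$family, model$nugget,
                                      model$psill, model$range_par)
  dmat <- as.matrix(stats::dist(coords))
  G <- gmat(dmat)
  p <- ncol(basis_data)
  A <- rbind(cbind(G, basis_data),
             cbind(t(basis_data), matrix(0, p, p)))
  d0 <- sqrt(outer(targets[, 1], coords[, 1], "-")^2 +
               outer(targets[, 2], coords[, 2], "-")^2)
  G0 <- gmat(d0)                       # m x n
  B <- rbind(t(G0), t(basis_target))   # (n+p) x m
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop("Kriging system is singular: ", conditionMessage(e), call. = FALSE)
  })
  W <- sol[seq_len(n), , drop = FALSE]        # weights, n x m
  L <- sol[n + seq_len(p), , drop = FALSE]    # Lagrange multipliers, p x m
  pred <- as.vector(crossprod(W, z))
  var <- colSums(W * t(G0)) + colSums(L * t(basis_target))
  list(pred = pred, var = pmax(var, 0), weights = W, lagrange = L)
}

as_target_matrix <- function(grid) {
  if (inherits(grid, "elev_raster")) {
    tb <- as_tibble.elev_raster(grid)
    cbind(tb$x, tb$y)
  } else {
    cbind(grid$x, grid$y)
  }
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction under a constant unknown mean: per target
#' cell the weights solve the semivariance system with a sum-to-one
#' constraint. With a zero nugget the predictor interpolates the data exactly
#' (zero kriging variance at data points). All data points are used (global
#' neighbourhood).
#'
#' @param data Data frame with coordinates and values.
#' @param value Value column (tidy-eval).
#' @param grid Prediction locations: a data frame with `x`, `y`, or an
#'   [elev_raster] (cell centers are used).
#' @param model A [fit_variogram_model()] result.
#' @param x,y Coordinate columns in `data`.
#' @return A `kriged_map` tibble: `x`, `y`, `pred`, `var`; attributes
#'   `method`, `model`, and `weights` (n data x m targets).
#' @export
krige_ok <- function(data, value, grid, model, x = x, y = y) {
  stopifnot(inherits(model, "variogram_model"))
  xs <- dplyr::pull(data, {{ x }}); ys <- dplyr::pull(data, {{ y }})
  zs <- dplyr::pull(data, {{ value }})
  keep <- stats::complete.cases(xs, ys, zs)
  coords <- cbind(xs[keep], ys[keep]); zs <- zs[keep]
  if (nrow(coords) < 3) stop("At least 3 data points are required.", call. = FALSE)
  tg <- as_target_matrix(grid)
  res <- krige_solve(coords, zs, model, tg,
                     basis_data = matrix(1, nrow(coords), 1),
                     basis_target = matrix(1, nrow(tg), 1))
  out <- tibble::tibble(x = tg[, 1], y = tg[, 2],
                        pred = res$pred, var = res$var)
  attr(out, "method") <- "OK"
  attr(out, "model") <- model
  attr(out, "weights") <- res$weights
  class(out) <- c("kriged_map", class(out))
  out
}

#' Kriging with external drift
#'
#' Universal kriging with one exhaustively-known external covariate (e.g. a
#' 10 m local-mean-elevation surface): the trend basis is (intercept, drift).
#' With an exactly constant drift the drift column is redundant and the
#' system reduces to ordinary kriging (done automatically, with a message);
#' a non-constant drift that is collinear with the intercept raises an error.
#'
#' @inheritParams krige_ok
#' @param drift Drift column in `data` (tidy-eval).
#' @param grid_drift Numeric vector of drift values at the prediction
#'   locations (same order as `grid` rows / raster cells).
#' @return A `kriged_map` tibble (attribute `method` = `"KED"`).
#' @export
krige_ked <- function(data, value, drift, grid, grid_drift, model,
                      x = x, y = y) {
  stopifnot(inherits(model, "variogram_model"))
  xs <- dplyr::pull(data, {{ x }}); ys <- dplyr::pull(data, {{ y }})
  zs <- dplyr::pull(data, {{ value }})
  fs <- dplyr::pull(data, {{ drift }})
  keep <- stats::complete.cases(xs, ys, zs, fs)
  coords <- cbind(xs[keep], ys[keep]); zs <- zs[keep]; fs <- fs[keep]
  tg <- as_target_matrix(grid)
  if (length(grid_drift) != nrow(tg)) {
    stop("`grid_drift` must have one value per prediction location.",
         call. = FALSE)
  }
  if (stats::sd(fs) == 0) {
    message("Constant drift: external-drift kriging reduces to ordinary kriging.")
    out <- krige_ok(dplyr::tibble(x = coords[, 1], y = coords[, 2], z = zs),
                    value = z, grid = grid, model = model)
    attr(out, "method") <- "KED"
    attr(out, "drift_name") <- "constant"
    return(out)
  }
  res <- krige_solve(coords, zs, model, tg,
                     basis_data = cbind(1, fs),
                     basis_target = cbind(1, grid_drift))
  out <- tibble::tibble(x = tg[, 1], y = tg[, 2],
                        pred = res$pred, var = res$var)
  attr(out, "method") <- "KED"
  attr(out, "model") <- model
  attr(out, "weights") <- res$weights
  class(out) <- c("kriged_map", class(out))
  out
}

#' Convert a kriged map on a regular grid to rasters
#'
#' @param km A `kriged_map` whose targets came from an [elev_raster] grid.
#' @param template The raster used as the prediction grid.
#' @return List of two [elev_raster]s: `pred` and `var`.
#' @export
kriged_to_raster <- function(km, template) {
  stopifnot(inherits(template, "elev_raster"))
  ny <- nrow(template$values); nx <- ncol(template$values)
  if (nrow(km) != ny * nx) {
    stop("Kriged map size does not match the template raster.", call. = FALSE)
  }
  mk <- function(v) elev_raster(matrix(v, ny, nx), template$cell_size,
                                template$xll, template$yll)
  list(pred = mk(km$pred), var = mk(km$var))
}

#' Leave-one-out cross-validation of a kriging configuration
#'
#' Each observation is predicted from all the others with the given variogram
#' model (and drift, for KED). Reports the mean error, the root-mean-squared
#' error normalized by the observation span (nRMSE), and the mean squared
#' deviation ratio MSDR = mean((pred - obs)^2 / kriging variance), which is
#' close to 1 when the variance model is well calibrated.
#'
#' @inheritParams krige_ok
#' @param method `"ok"` or `"ked"`.
#' @param drift Drift column (KED only).
#' @return A `cv_report` list: `mean_err`, `nrmse`, `msdr`, `n`, and the
#'   per-point tibble `details`.
#' @export
loo_cross_validate <- function(data, value, model, method = c("ok", "ked"),
                               drift = NULL, x = x, y = y) {
  method <- match.arg(method)
  xs <- dplyr::pull(data, {{ x }}); ys <- dplyr::pull(data, {{ y }})
  zs <- dplyr::pull(data, {{ value }})
  fs <- if (method == "ked") dplyr::pull(data, {{ drift }}) else NULL
  keep <- if (is.null(fs)) stats::complete.cases(xs, ys, zs) else
    stats::complete.cases(xs, ys, zs, fs)
  xs <- xs[keep]; ys <- ys[keep]; zs <- zs[keep]
  if (!is.null(fs)) fs <- fs[keep]
  n <- length(zs)
  if (n < 5) stop("At least 5 observations are required.", call. = FALSE)
  if (diff(range(zs)) <= 0) {
    stop("Zero observation span: nRMSE is undefined.", call. = FALSE)
  }
  preds <- vars <- numeric(n)
  for (i in seq_len(n)) {
    coords <- cbind(xs[-i], ys[-i])
    tg <- cbind(xs[i], ys[i])
    if (method == "ok") {
      r <- krige_solve(coords, zs[-i], model, tg,
                       matrix(1, n - 1, 1), matrix(1, 1, 1))
    } else {
      if (stats::sd(fs[-i]) == 0) {
        r <- krige_solve(coords, zs[-i], model, tg,
                         matrix(1, n - 1, 1), matrix(1, 1, 1))
      } else {
        r <- krige_solve(coords, zs[-i], model, tg,
                         cbind(1, fs[-i]), cbind(1, fs[i]))
      }
    }
    preds[i] <- r$pred; vars[i] <- r$var
  }
  err <- preds - zs
  structure(
    list(mean_err = mean(err),
         nrmse = sqrt(mean(err^2)) / diff(range(zs)),
         msdr = mean(err^2 / pmax(vars, .Machine$double.eps)),
         n = n,
         details = tibble::tibble(x = xs, y = ys, observed = zs,
                                  predicted = preds, var = vars)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> n = %d: meanErr %.4g, nRMSE %.4g, MSDR %.3f\n",
              x$n, x$mean_err, x$nrmse, x$msdr))
  invisible(x)
}
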