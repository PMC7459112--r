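#' Plot an elevation raster
#'
#' @param object An [elev_raster].
#' @param ... Unused.
#' @return A ggplot: filled raster of cell values.
#' @exportS3Method ggplot2::autoplot
autoplot.elev_raster <- function(object, ...) {
  as_tibble.elev_raster(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "value")
}

#' Plot an empirical variogram, optionally with a fitted model
#'
#' @param object An [empirical_variogram()].
#' @param model Optional [fit_variogram_model()] result drawn as a line.
#' @param ... Unused.
#' @return A ggplot: semivariance against lag, point size = pair count.
#' @exportS3Method ggplot2::autoplot
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$lag, .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "lag distance (m)", y = "semivariance",
                  size = "pairs")
  if (!is.null(model)) {
    h <- seq(0, max(object$lag), length.out = 200)
    line <- tibble::tibble(
      lag = h,
      gamma = variogram_value(h, model$family, model$nugget, model$psill,
                              model$range_par)
    )
    p <- p + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  p
}

#' Plot a kriged map
#'
#' @param object A `kriged_map` tibble on a regular grid.
#' @param what `"pred"` or `"var"`.
#' @param ... Unused.
#' @return A ggplot raster of the prediction (or variance) surface.
#' @exportS3Method ggplot2::autoplot
autoplot.kriged_map <- function(object, what = c("pred", "var"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$x, .data$y, fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (m)", y = "y (m)",
      fill = if (what == "pred") "prediction" else "kriging variance",
      subtitle = attr(object, "method")
    )
}

#' Plot a bell-curve fit over the proxy scatter
#'
#' @param object A [fit_bell_curve()] result.
#' @param groups Optional factor (same order as the fitted data) to colour
#'   points, e.g. rank groups or SOC quintiles.
#' @param ... Unused.
#' @return A ggplot: rangeRs against rankRs with the fitted Gaussian curve.
#' @exportS3Method ggplot2::autoplot
autoplot.bell_fit <- function(object, groups = NULL, ...) {
  df <- object$data
  if (!is.null(groups)) df$group <- groups
  xs <- seq(min(df$rank_rs), max(df$rank_rs), length.out = 200)
  curve <- tibble::tibble(
    rank_rs = xs,
    range_rs = object$a * stats::dnorm(xs, object$mu, object$sigma)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rank_rs, .data$range_rs))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  }
  p + ggplot2::geom_line(data = curve, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "rankRs (mean rank)", y = "rangeRs (rank range)",
                  colour = NULL)
}
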