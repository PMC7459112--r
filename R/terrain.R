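#' Aggregate a DEM by block means
#'
#' Coarsens a raster by an integer factor: each output cell is the mean of the
#' corresponding `factor` x `factor` block of input cells (missing cells are
#' ignored; a block that is entirely missing stays missing). This is the
#' "smooth by box blur, then subsample" step of the mixed-scaling pyramid.
#'
#' @param dem An [elev_raster].
#' @param factor Integer aggregation factor, >= 2.
#' @return An [elev_raster] with `cell_size * factor`.
#' @export
aggregate_dem <- function(dem, factor) {
  stopifnot(inherits(dem, "elev_raster"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) {
    stop("`factor` must be an integer >= 2.", call. = FALSE)
  }
  v <- dem$values
  if (nrow(v) < factor || ncol(v) < factor) {
    stop("Raster dimensions must be at least `factor` in each direction.",
         call. = FALSE)
  }
  out <- block_reduce(v, factor)
  # partial blocks pad southwards, shifting the lower-left corner down
  pad_rows <- nrow(out) * factor - nrow(v)
  elev_raster(out, cell_size = dem$cell_size * factor,
              xll = dem$xll, yll = dem$yll - pad_rows * dem$cell_size)
}

# Block mean over f x f blocks, NA-aware. Trailing partial blocks use the
# available cells.
block_reduce <- function(v, f) {
  ny <- nrow(v); nx <- ncol(v)
  nyb <- ceiling(ny / f); nxb <- ceiling(nx / f)
  # pad to full blocks with NA
  if (nyb * f > ny || nxb * f > nx) {
    p <- matrix(NA_real_, nyb * f, nxb * f)
    p[seq_len(ny), seq_len(nx)] <- v
    v <- p
  }
  ri <- rep(seq_len(nyb), each = f)
  sums_r <- rowsum(ifelse(is.na(v), 0, v), ri)
  cnts_r <- rowsum((!is.na(v)) * 1, ri)
  ci <- rep(seq_len(nxb), each = f)
  sums <- t(rowsum(t(sums_r), ci))
  cnts <- t(rowsum(t(cnts_r), ci))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  out
}

#' Smooth a DEM with a moving-window kernel
#'
#' Moving-window mean with a box or Gaussian kernel at the raster's own
#' resolution. Kernels are renormalized over the cells actually available, so
#' edges (and cells next to missing data) are averages of fewer cells rather
#' than being padded with fill values.
#'
#' @param dem An [elev_raster].
#' @param kernel `"box"` or `"gaussian"`.
#' @param width_cells Odd window width in cells, >= 3. For the Gaussian kernel
#'   the standard deviation is `width_cells / 4` cells, truncated at the window.
#' @return An [elev_raster] with unchanged geometry.
#' @export
smooth_dem <- function(dem, kernel = c("box", "gaussian"), width_cells = 3) {
  stopifnot(inherits(dem, "elev_raster"))
  kernel <- match.arg(kernel)
  w <- as.integer(width_cells)
  if (is.na(w) || w < 3L || w %% 2L == 0L) {
    stop("`width_cells` must be an odd integer >= 3.", call. = FALSE)
  }
  k <- if (kernel == "box") {
    rep(1, w)
  } else {
    half <- (w - 1L) / 2L
    stats::dnorm(seq(-half, half), sd = max(w / 4, 0.5))
  }
  out <- separable_mean(dem$values, k)
  elev_raster(out, cell_size = dem$cell_size, xll = dem$xll, yll = dem$yll)
}

# Separable weighted moving mean with renormalization over available cells.
separable_mean <- function(v, k) {
  ok <- !is.na(v)
  z <- ifelse(ok, v, 0)
  num <- conv_sep(z, k)
  den <- conv_sep(ok * 1, k)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out[!ok] <- NA_real_  # keep missing cells missing
  out
}

# 2-D separable convolution (zero-padded) with a symmetric 1-D kernel.
conv_sep <- function(m, k) {
  conv_cols <- function(mat) {
    half <- (length(k) - 1L) / 2L
    n <- nrow(mat)
    pad <- matrix(0, half, ncol(mat))
    big <- rbind(pad, mat, pad)
    out <- stats::filter(big, k, method = "convolution", sides = 2)
    matrix(out[(half + 1L):(half + n), ], nrow = n)
  }
  t(conv_cols(t(conv_cols(m))))
}

# Shift a matrix by (dr, dc) with edge replication.
shift_mat <- function(m, dr, dc) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- pmin(pmax(seq_len(ny) + dr, 1L), ny)
  ci <- pmin(pmax(seq_len(nx) + dc, 1L), nx)
  m[ri, ci, drop = FALSE]
}

#' Compute terrain attributes from a DEM
#'
#' Six per-cell attributes at the DEM's own resolution:
#' \describe{
#'   \item{malt}{local mean elevation — moving-window mean (m)}
#'   \item{sd}{moving-window sample standard deviation of elevation (m)}
#'   \item{tpi}{topographic position index — center elevation minus the mean
#'     of the window *excluding* the center (m); positive on ridges}
#'   \item{sl}{slope angle from Horn's 3x3 finite differences (degrees)}
#'   \item{north}{cosine of the downslope aspect (aspect measured clockwise
#'     from geographic north); 0 on flat cells}
#'   \item{east}{sine of the downslope aspect; 0 on flat cells}
#' }
#' Window statistics renormalize over available cells; slope/aspect replicate
#' edge rows/columns.
#'
#' @param dem An [elev_raster].
#' @param window_cells Odd window width (cells) for `malt`, `sd` and `tpi`.
#' @return Named list of six [elev_raster]s
#'   (`malt`, `sd`, `tpi`, `sl`, `north`, `east`).
#' @export
compute_attributes <- function(dem, window_cells = 3) {
  stopifnot(inherits(dem, "elev_raster"))
  w <- as.integer(window_cells)
  if (is.na(w) || w < 3L || w %% 2L == 0L) {
    stop("`window_cells` must be an odd integer >= 3.", call. = FALSE)
  }
  v <- dem$values
  if (nrow(v) < w || ncol(v) < w) {
    stop("Raster is smaller than the analysis window.", call. = FALSE)
  }
  k <- rep(1, w)
  ok <- !is.na(v)
  z <- ifelse(ok, v, 0)
  s1 <- conv_sep(z, k)
  s2 <- conv_sep(z^2, k)
  cnt <- conv_sep(ok * 1, k)
  malt <- s1 / cnt
  varw <- (s2 - s1^2 / cnt) / pmax(cnt - 1, 1)
  sdw <- sqrt(pmax(varw, 0))
  sdw[cnt < 2] <- NA_real_
  # TPI: center minus mean of neighbours (window minus center cell)
  tpi <- v - (s1 - z) / pmax(cnt - ok, 1)
  tpi[(cnt - ok) < 1] <- NA_real_
  malt[!ok] <- NA_real_; sdw[!ok] <- NA_real_; tpi[!ok] <- NA_real_
  malt[cnt == 0] <- NA_real_

  # Horn 3x3 slope/aspect; x east (columns), y north (row 1 = north)
  cs <- dem$cell_size
  a <- shift_mat(v, -1L, -1L); b <- shift_mat(v, -1L, 0L); cc <- shift_mat(v, -1L, 1L)
  d <- shift_mat(v, 0L, -1L);                               f <- shift_mat(v, 0L, 1L)
  g <- shift_mat(v, 1L, -1L); h <- shift_mat(v, 1L, 0L);  i <- shift_mat(v, 1L, 1L)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  grad <- sqrt(dzdx^2 + dzdy^2)
  sl <- atan(grad) * 180 / pi
  # downslope compass bearing: atan2(east component, north component) of -grad
  north <- ifelse(grad > 0, -dzdy / grad, 0)
  east <- ifelse(grad > 0, -dzdx / grad, 0)
  sl[!ok] <- NA_real_; north[!ok] <- NA_real_; east[!ok] <- NA_real_

  mk <- function(m) elev_raster(m, cell_size = cs, xll = dem$xll, yll = dem$yll)
  list(malt = mk(malt), sd = mk(sdw), tpi = mk(tpi),
       sl = mk(sl), north = mk(north), east = mk(east))
}

#' Disaggregate a raster to a finer resolution
#'
#' Nearest-neighbour replication: each coarse cell is copied into the block of
#' fine cells it covers. Values are unchanged — this is the "upscale attributes
#' back to base resolution" step of mixed scaling.
#'
#' @param r An [elev_raster].
#' @param target_cell_size Target resolution (m); must divide `r$cell_size`
#'   into an integer number of fine cells.
#' @return An [elev_raster] at `target_cell_size`.
#' @export
disaggregate <- function(r, target_cell_size) {
  stopifnot(inherits(r, "elev_raster"))
  ratio <- r$cell_size / target_cell_size
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1) {
    stop("`target_cell_size` must divide the source cell size into an ",
         "integer factor.", call. = FALSE)
  }
  f <- as.integer(round(ratio))
  out <- r$values[rep(seq_len(nrow(r$values)), each = f),
                  rep(seq_len(ncol(r$values)), each = f), drop = FALSE]
  elev_raster(out, cell_size = target_cell_size, xll = r$xll, yll = r$yll)
}

#' Build the mixed-scaling terrain-attribute pyramid
#'
#' Implements the multi-scale pyramid: the base DEM (level 1) is repeatedly
#' aggregated by a factor of two up to level 6, and a final level 7 is built by
#' direct block-mean aggregation to `level7_resolution` (10 m by default, the
#' sampling-grid resolution). Attributes are computed at each level with a
#' 3x3 window *of that level's cells* (so the neighbourhood grows with scale),
#' then disaggregated back to the base resolution.
#'
#' @param dem0 Base-resolution [elev_raster] (level 1).
#' @param max_level Highest level to build (1-7).
#' @param kernel Smoothing kernel tag recorded on the result; aggregation is
#'   block-mean ("box"). With `"gaussian"` a Gaussian pre-smooth of width 3 is
#'   applied before each factor-2 aggregation.
#' @param window_cells Attribute window at each level.
#' @param level7_resolution Resolution (m) of the final level.
#' @return A `terrain_pyramid`: list of levels, each with `level`,
#'   `resolution`, `dem`, `attributes` (at level resolution) and
#'   `attributes_base` (disaggregated to base resolution).
#' @export
build_pyramid <- function(dem0, max_level = 7, kernel = c("box", "gaussian"),
                          window_cells = 3, level7_resolution = 10) {
  stopifnot(inherits(dem0, "elev_raster"))
  kernel <- match.arg(kernel)
  max_level <- as.integer(max_level)
  stopifnot(max_level >= 1L, max_level <= 7L)
  cs0 <- dem0$cell_size

  levels <- vector("list", max_level)
  dem <- dem0
  for (lev in seq_len(min(max_level, 6L))) {
    if (lev > 1L) {
      src <- if (kernel == "gaussian") smooth_dem(dem, "gaussian", 3) else dem
      dem <- aggregate_dem(src, 2L)
    }
    levels[[lev]] <- list(level = lev, resolution = dem$cell_size, dem = dem)
  }
  if (max_level == 7L) {
    f7 <- level7_resolution / cs0
    if (abs(f7 - round(f7)) > 1e-8) {
      stop("Base resolution must divide the level-7 resolution evenly.",
           call. = FALSE)
    }
    f7 <- as.integer(round(f7))
    if (nrow(dem0$values) < f7 || ncol(dem0$values) < f7) {
      stop("Raster extent is too small for the ", level7_resolution,
           " m level.", call. = FALSE)
    }
    d7 <- aggregate_dem(dem0, f7)
    levels[[7L]] <- list(level = 7L, resolution = d7$cell_size, dem = d7)
  }

  levels <- purrr::map(levels, function(L) {
    att <- compute_attributes(L$dem, window_cells = window_cells)
    att_base <- purrr::map(att, disaggregate, target_cell_size = cs0)
    c(L, list(attributes = att, attributes_base = att_base))
  })
  structure(list(levels = levels, base_cell_size = cs0, kernel = kernel),
            class = "terrain_pyramid")
}

#' @export
print.terrain_pyramid <- function(x, ...) {
  res <- purrr::map_dbl(x$levels, "resolution")
  cat(sprintf("<terrain_pyramid> %d levels (%s m), kernel = %s\n",
              length(x$levels), paste(signif(res, 3), collapse = ", "),
              x$kernel))
  invisible(x)
}

#' Extract pyramid terrain attributes at point positions
#'
#' Looks up, for every position, the base-resolution (disaggregated) cell value
#' of each attribute at each pyramid level.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param positions Data frame with columns `position_id`, `x`, `y`.
#' @param levels Which pyramid levels to extract (default: all built).
#' @return A long tibble: `position_id`, `level`, `attribute`
#'   (`malt`,`sd`,`tpi`,`sl`,`north`,`east`) and `value`.
#' @export
extract_terrain <- function(pyramid, positions, levels = NULL) {
  stopifnot(inherits(pyramid, "terrain_pyramid"))
  stopifnot(all(c("position_id", "x", "y") %in% names(positions)))
  levels <- levels %||% purrr::map_int(pyramid$levels, "level")
  purrr::map_dfr(pyramid$levels[levels], function(L) {
    purrr::imap_dfr(L$attributes_base, function(rast, att) {
      tibble::tibble(
        position_id = positions$position_id,
        level = L$level,
        attribute = att,
        value = extract_cells(rast, positions$x, positions$y)
      )
    })
  })
}

#' Pivot a long terrain extraction to one row per position
#'
#' @param terrain_long Output of [extract_terrain()].
#' @return A tibble with one row per position and columns like `malt_d1`.
#' @export
terrain_wide <- function(terrain_long) {
  terrain_long |>
    dplyr::mutate(name = paste0(.data$attribute, "_d", .data$level)) |>
    dplyr::select("position_id", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
}
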