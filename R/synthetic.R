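#' Configuration objects for the synthetic grassland emulator
#'
#' The generator emulates a finely undulating semi-arid grassland plot:
#' a smooth correlated elevation surface with at most `relief_max` total
#' relief, a campaign sampling grid, and a simple soil CO2 efflux model.
#'
#' @param nx,ny Cell counts (east-west, north-south); at least 8.
#' @param cell_size Cell size (m). Default 0.2 m emulates a laser-scan DEM.
#' @param relief_max Total relief, max minus min elevation (m).
#' @param correlation_length Spatial correlation scale of the surface (m).
#' @param base_elevation Elevation added to the surface (m a.s.l.).
#' @param seed Integer seed; the surface is deterministic given the config.
#' @return `terrain_config()` returns a `terrain_config` list.
#' @export
terrain_config <- function(nx = 400, ny = 300, cell_size = 0.2,
                           relief_max = 1.5, correlation_length = 15,
                           base_elevation = 113.5, seed = 1) {
  if (nx < 8 || ny < 8) stop("`nx` and `ny` must be >= 8.", call. = FALSE)
  if (cell_size <= 0 || relief_max <= 0 || correlation_length <= 0) {
    stop("`cell_size`, `relief_max` and `correlation_length` must be positive.",
         call. = FALSE)
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_size = cell_size, relief_max = relief_max,
                 correlation_length = correlation_length,
                 base_elevation = base_elevation, seed = as.integer(seed)),
            class = "terrain_config")
}

#' @rdname terrain_config
#' @param n_positions Number of measuring positions.
#' @param extent_x,extent_y Plot extent (m).
#' @param n_campaigns Number of measuring campaigns.
#' @param soc_campaigns Number of campaigns with SOC sampling.
#' @param position_spacing Sampling-grid spacing (m).
#' @return `study_design()` returns a `study_design` list.
#' @export
study_design <- function(n_positions = 78, extent_x = 80, extent_y = 60,
                         n_campaigns = 15, soc_campaigns = 6,
                         position_spacing = 10) {
  if (n_positions < 3) stop("`n_positions` must be >= 3.", call. = FALSE)
  if (soc_campaigns > n_campaigns) {
    stop("`soc_campaigns` cannot exceed `n_campaigns`.", call. = FALSE)
  }
  structure(list(n_positions = as.integer(n_positions),
                 extent_x = extent_x, extent_y = extent_y,
                 n_campaigns = as.integer(n_campaigns),
                 soc_campaigns = as.integer(soc_campaigns),
                 position_spacing = position_spacing),
            class = "study_design")
}

#' Default per-campaign environmental regimes
#'
#' Fifteen campaigns spanning seven growing seasons in spring / summer-drought
#' / autumn triplets: a mean soil temperature (deg C) and a plot-wide wetness
#' multiplier applied to each position's baseline soil water content. Drought
#' campaigns have low wetness and high temperature.
#'
#' @return A tibble: `campaign`, `date`, `ts_mean`, `wetness`.
#' @export
default_campaign_regimes <- function() {
  tibble::tibble(
    campaign = 1:15,
    date = as.Date(c(
      "2012-10-19", "2013-05-08", "2013-06-26", "2013-10-14", "2014-05-07",
      "2014-05-28", "2014-09-25", "2015-06-09", "2015-11-20", "2016-10-24",
      "2017-06-02", "2017-08-24", "2017-11-03", "2018-05-17", "2018-08-16"
    )),
    ts_mean = c(12, 17, 24, 12, 16, 18, 18, 23, 7, 11, 22, 27, 7, 18, 26),
    wetness = c(0.90, 1.15, 0.50, 0.95, 1.20, 1.10, 1.00, 0.60, 0.95,
                0.90, 0.65, 0.40, 0.90, 1.05, 0.45)
  )
}

#' @rdname terrain_config
#' @param rs_ref Reference soil respiration at 10 deg C, optimal moisture and
#'   mean SOC (umol CO2 m-2 s-1).
#' @param q10 Temperature sensitivity (factor per 10 deg C).
#' @param swc_opt,swc_width Optimum and width of the Gaussian soil-moisture
#'   response (% volumetric water content).
#' @param soc_weight Fractional change in efflux per SD of soil organic carbon.
#' @param noise_sd Measurement noise on Rs (umol CO2 m-2 s-1).
#' @param swc_noise_sd,ts_noise_sd Campaign measurement noise on SWC (%) and
#'   soil temperature (deg C).
#' @param soc_obs_sd SOC measurement noise (%).
#' @param campaign_regimes Tibble as in [default_campaign_regimes()].
#' @return `flux_params()` returns a `flux_params` list.
#' @export
flux_params <- function(rs_ref = 3, q10 = 2, swc_opt = 18, swc_width = 8,
                        soc_weight = 0.7, noise_sd = 0.3,
                        swc_noise_sd = 1, ts_noise_sd = 0.5, soc_obs_sd = 0.08,
                        campaign_regimes = default_campaign_regimes()) {
  if (rs_ref <= 0) stop("`rs_ref` must be positive.", call. = FALSE)
  if (q10 < 1) stop("`q10` must be >= 1.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  structure(list(rs_ref = rs_ref, q10 = q10, swc_opt = swc_opt,
                 swc_width = swc_width, soc_weight = soc_weight,
                 noise_sd = noise_sd, swc_noise_sd = swc_noise_sd,
                 ts_noise_sd = ts_noise_sd, soc_obs_sd = soc_obs_sd,
                 campaign_regimes = campaign_regimes),
            class = "flux_params")
}

#' Generate a smooth correlated elevation surface
#'
#' White noise filtered with a Gaussian kernel whose standard deviation equals
#' the configured correlation length, then rescaled linearly so that the total
#' relief (max minus min) equals `relief_max` exactly, and shifted to
#' `base_elevation`.
#'
#' @param cfg A [terrain_config()].
#' @return An [elev_raster] of `ny` rows by `nx` columns.
#' @export
generate_terrain <- function(cfg) {
  stopifnot(inherits(cfg, "terrain_config"))
  set.seed(cfg$seed)
  noise <- matrix(stats::rnorm(cfg$ny * cfg$nx), cfg$ny, cfg$nx)
  sd_cells <- cfg$correlation_length / cfg$cell_size
  half <- max(3L, ceiling(2.5 * sd_cells))
  k <- stats::dnorm(seq(-half, half), sd = sd_cells)
  smooth <- separable_mean(noise, k)
  rng <- range(smooth)
  if (diff(rng) < .Machine$double.eps) {
    stop("Degenerate surface: no variation after smoothing.", call. = FALSE)
  }
  z <- (smooth - rng[1]) / diff(rng) * cfg$relief_max + cfg$base_elevation
  elev_raster(z, cell_size = cfg$cell_size)
}

#' Lay out measuring positions on the sampling grid
#'
#' A regular lattice at `position_spacing` spanning the extent, plus seeded
#' in-fill positions at lattice-cell midpoints until `n_positions` is reached
#' (78 positions on an 80 x 60 m grid = a 9 x 7 lattice plus 15 in-fills).
#'
#' @param design A [study_design()].
#' @param seed Integer seed for the in-fill sample.
#' @return Tibble: `position_id`, `x`, `y` (m).
#' @export
study_positions <- function(design, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  sp <- design$position_spacing
  xs <- seq(0, design$extent_x, by = sp)
  ys <- seq(0, design$extent_y, by = sp)
  lattice <- expand.grid(x = xs, y = ys)
  n_lat <- nrow(lattice)
  if (design$n_positions < n_lat) {
    pts <- lattice[seq_len(design$n_positions), ]
  } else {
    mids <- expand.grid(x = xs[-length(xs)] + sp / 2, y = ys[-length(ys)] + sp / 2)
    n_fill <- design$n_positions - n_lat
    if (n_fill > nrow(mids)) {
      stop("Too many positions for the lattice + midpoint layout.", call. = FALSE)
    }
    set.seed(seed)
    pts <- rbind(lattice, mids[sample.int(nrow(mids), n_fill), ])
  }
  tibble::tibble(
    position_id = sprintf("P%02d", seq_len(nrow(pts))),
    x = pts$x, y = pts$y
  )
}

#' Generate per-position soil fields from terrain
#'
#' Builds mean soil organic carbon (SOC, %) and baseline soil water content
#' (SWC, %) at the measuring positions as linear responses to standardized
#' terrain attributes: SOC decreases with elevation, local elevation SD and
#' slope and increases with northness and easterness; baseline SWC decreases
#' with local SD, slope and elevation. Attributes are taken from a ~1.6 m
#' aggregation of the DEM (3x3 window).
#'
#' @param dem Base [elev_raster].
#' @param positions Tibble from [study_positions()].
#' @param seed Integer seed for the field noise.
#' @param soc_coefs,swc_coefs Named lists of coefficients (`s0`/`w0` intercept,
#'   `b_elev`, `b_sd`, `b_sl`, `b_north`, `b_east` for SOC; `c_elev`, `c_sd`,
#'   `c_sl` for SWC; `noise_sd` each). Coefficients act on z-scored attributes.
#' @return Tibble: `position_id`, `x`, `y`, `elev`, `sd_local`, `slope`,
#'   `northness`, `eastness`, `soc`, `swc_base`.
#' @export
generate_soil_fields <- function(dem, positions, seed = 1,
                                 soc_coefs = list(s0 = 3, b_elev = 0.9,
                                                  b_sd = 0.3, b_sl = 0.3,
                                                  b_north = 0.45, b_east = 0.45,
                                                  noise_sd = 0.12),
                                 swc_coefs = list(w0 = 18, c_elev = 1.5,
                                                  c_sd = 3.5, c_sl = 3.5,
                                                  noise_sd = 2)) {
  stopifnot(inherits(dem, "elev_raster"))
  agg_factor <- max(2L, as.integer(round(1.6 / dem$cell_size)))
  agg_factor <- min(agg_factor, nrow(dem$values), ncol(dem$values))
  coarse <- aggregate_dem(dem, agg_factor)
  att <- compute_attributes(coarse, window_cells = 3)

  zsc <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  elev <- extract_cells(dem, positions$x, positions$y)
  sd_l <- extract_cells(att$sd, positions$x, positions$y)
  sl <- extract_cells(att$sl, positions$x, positions$y)
  no <- extract_cells(att$north, positions$x, positions$y)
  ea <- extract_cells(att$east, positions$x, positions$y)

  n <- nrow(positions)
  set.seed(seed)
  soc <- soc_coefs$s0 -
    soc_coefs$b_elev * zsc(elev) - soc_coefs$b_sd * zsc(sd_l) -
    soc_coefs$b_sl * zsc(sl) + soc_coefs$b_north * zsc(no) +
    soc_coefs$b_east * zsc(ea) + stats::rnorm(n, 0, soc_coefs$noise_sd)
  soc <- pmax(soc, 0.05)
  swc <- swc_coefs$w0 -
    swc_coefs$c_elev * zsc(elev) - swc_coefs$c_sd * zsc(sd_l) -
    swc_coefs$c_sl * zsc(sl) + stats::rnorm(n, 0, swc_coefs$noise_sd)
  swc <- pmin(pmax(swc, 2), 60)

  tibble::tibble(
    position_id = positions$position_id, x = positions$x, y = positions$y,
    elev = elev, sd_local = sd_l, slope = sl, northness = no, eastness = ea,
    soc = soc, swc_base = swc
  )
}

#' Generate the multi-campaign flux panel
#'
#' Simulates, for every position and campaign, soil water content (baseline
#' times the campaign wetness multiplier, plus noise, clipped to 0-100%), soil
#' temperature (campaign mean plus micro-noise) and soil respiration from a
#' Q10 temperature response, a Gaussian soil-moisture response and a linear
#' SOC scaling, plus measurement noise, clipped at zero:
#' \deqn{Rs = rs_{ref}\,(1 + w\, z(SOC))\, Q10^{(Ts-10)/10}
#'       e^{-((SWC-opt)/width)^2} + \epsilon}
#' SOC is reported only for `soc_campaigns` campaigns (evenly spread).
#'
#' Because the moisture response is flat near its optimum and steep far from
#' it, wet campaigns order positions mostly by SOC while dry campaigns weight
#' the moisture ordering — so positions with extreme SOC hold their rank while
#' intermediate positions swap ranks between wet and dry campaigns.
#'
#' @param design A [study_design()].
#' @param soil Tibble from [generate_soil_fields()].
#' @param params A [flux_params()].
#' @param seed Integer seed.
#' @return A `campaign_panel` tibble in long format: `position_id`, `x`, `y`,
#'   `campaign`, `date`, `rs`, `ts`, `swc`, `soc` (`NA` when unobserved).
#' @export
generate_campaigns <- function(design, soil, params = flux_params(), seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(params, "flux_params"))
  regimes <- params$campaign_regimes
  if (nrow(regimes) < design$n_campaigns) {
    stop("`campaign_regimes` has fewer rows than `n_campaigns`.", call. = FALSE)
  }
  regimes <- regimes[seq_len(design$n_campaigns), ]
  n <- nrow(soil)
  if (n != design$n_positions) {
    stop(sprintf("Soil fields have %d positions but the design expects %d.",
                 n, design$n_positions), call. = FALSE)
  }
  soc_camps <- unique(round(seq(1, design$n_campaigns,
                                length.out = design$soc_campaigns)))
  zsoc <- {
    s <- stats::sd(soil$soc)
    if (is.na(s) || s == 0) rep(0, n) else (soil$soc - mean(soil$soc)) / s
  }
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(design$n_campaigns), function(c) {
    swc <- pmin(pmax(regimes$wetness[c] * soil$swc_base +
                       stats::rnorm(n, 0, params$swc_noise_sd), 0), 100)
    ts <- regimes$ts_mean[c] + stats::rnorm(n, 0, params$ts_noise_sd)
    rs <- params$rs_ref * pmax(1 + params$soc_weight * zsoc, 0.1) *
      params$q10^((ts - 10) / 10) *
      exp(-((swc - params$swc_opt) / params$swc_width)^2) +
      stats::rnorm(n, 0, params$noise_sd)
    soc <- if (c %in% soc_camps) {
      pmax(soil$soc + stats::rnorm(n, 0, params$soc_obs_sd), 0.01)
    } else {
      rep(NA_real_, n)
    }
    tibble::tibble(
      position_id = soil$position_id, x = soil$x, y = soil$y,
      campaign = c, date = regimes$date[c],
      rs = pmax(rs, 0), ts = ts, swc = swc, soc = soc
    )
  })
  structure(rows, class = c("campaign_panel", class(rows)))
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: terrain, positions, soil fields and campaign panel in
#' one call, all derived deterministically from one seed.
#'
#' @param terrain A [terrain_config()] (its `seed` is overridden by `seed`).
#' @param design A [study_design()].
#' @param params A [flux_params()].
#' @param seed Integer master seed.
#' @return List with `dem`, `positions`, `soil`, `panel`.
#' @export
simulate_study <- function(terrain = terrain_config(), design = study_design(),
                           params = flux_params(), seed = 1) {
  terrain$seed <- as.integer(seed)
  dem <- generate_terrain(terrain)
  positions <- study_positions(design, seed = seed + 1L)
  ext <- raster_extent(dem)
  if (any(positions$x > ext["xmax"]) || any(positions$y > ext["ymax"])) {
    stop("Study design extent exceeds the terrain extent.", call. = FALSE)
  }
  soil <- generate_soil_fields(dem, positions, seed = seed + 2L)
  panel <- generate_campaigns(design, soil, params, seed = seed + 3L)
  list(dem = dem, positions = positions, soil = soil, panel = panel)
}

#' Write / read a campaign panel as CSV
#'
#' Long-format CSV with columns `position_id, x, y, campaign, date, rs, ts,
#' swc, soc` (empty `soc` when unobserved).
#'
#' @param panel A `campaign_panel` tibble.
#' @param path File path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_id", "x", "y", "campaign", "rs", "ts", "swc")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("Panel CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"soc" %in% names(df)) df$soc <- NA_real_
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  out <- tibble::as_tibble(df)
  structure(out, class = c("campaign_panel", class(out)))
}
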