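#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the study defaults:
#' 15 campaigns over 78 positions on an 80 x 60 m grid, a 7-level terrain
#' pyramid with a box kernel, average-rank tie handling, three candidate
#' variogram families with 10 lag bins, external drift from the 10 m
#' local-mean-elevation surface, maps on a 2 m grid, p < 0.05 and
#' fixed-moment bell fitting.
#'
#' @param simulate Generate synthetic inputs (`TRUE`) or read `dem_path` /
#'   `panel_path`.
#' @param dem_path,panel_path Input files (ESRI ASCII grid / long CSV) when
#'   `simulate = FALSE`.
#' @param seed Integer master seed.
#' @param terrain A [terrain_config()] for simulation.
#' @param design A [study_design()] for simulation.
#' @param flux A [flux_params()] for simulation.
#' @param max_level,kernel,window_cells Pyramid options (see
#'   [build_pyramid()]).
#' @param ties Rank tie rule (see [rank_campaign()]).
#' @param families Candidate variogram families.
#' @param n_bins Variogram lag bins.
#' @param drift_level,drift_attribute Pyramid level and attribute used as the
#'   external drift surface.
#' @param map_cell_size Kriged-map resolution (m).
#' @param scan_levels Pyramid levels entering the correlation scan.
#' @param alpha Significance level for the scan.
#' @param fix_moments Fix the bell-curve moments at the sample moments?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, dem_path = NULL, panel_path = NULL,
                            seed = 1,
                            terrain = terrain_config(),
                            design = study_design(),
                            flux = flux_params(),
                            max_level = 7, kernel = "box", window_cells = 3,
                            ties = "average",
                            families = c("exponential", "gaussian", "spherical"),
                            n_bins = 10,
                            drift_level = 7, drift_attribute = "malt",
                            map_cell_size = 2,
                            scan_levels = 1:5, alpha = 0.05,
                            fix_moments = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  if (!simulate) {
    if (is.null(dem_path)) {
      stop("Without `simulate`, `dem_path` must be set.", call. = FALSE)
    }
    if (is.null(panel_path)) {
      stop("Without `simulate`, `panel_path` must be set.", call. = FALSE)
    }
    if (!file.exists(dem_path)) {
      stop("`dem_path` does not exist: ", dem_path, call. = FALSE)
    }
    if (!file.exists(panel_path)) {
      stop("`panel_path` does not exist: ", panel_path, call. = FALSE)
    }
  }
  structure(
    list(simulate = simulate, dem_path = dem_path, panel_path = panel_path,
         seed = as.integer(seed), terrain = terrain, design = design,
         flux = flux, max_level = max_level, kernel = kernel,
         window_cells = window_cells, ties = ties, families = families,
         n_bins = n_bins, drift_level = drift_level,
         drift_attribute = drift_attribute, map_cell_size = map_cell_size,
         scan_levels = scan_levels, alpha = alpha, fix_moments = fix_moments),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' The structured-text form of [pipeline_config()] (nested key-value pairs
#' with the full default set). Campaign regimes are embedded as columns.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ser <- rapply(unclass(config), how = "replace", f = function(x) x)
  ser$terrain <- unclass(config$terrain)
  ser$design <- unclass(config$design)
  flux <- unclass(config$flux)
  flux$campaign_regimes <- lapply(as.list(flux$campaign_regimes), function(col) {
    if (inherits(col, "Date")) as.character(col) else col
  })
  ser$flux <- flux
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  regimes <- tibble::as_tibble(raw$flux$campaign_regimes)
  regimes$date <- as.Date(regimes$date)
  flux <- do.call(flux_params, c(
    raw$flux[setdiff(names(raw$flux), "campaign_regimes")],
    list(campaign_regimes = regimes)
  ))
  terrain <- do.call(terrain_config, raw$terrain[
    setdiff(names(raw$terrain), character(0))])
  design <- do.call(study_design, raw$design)
  do.call(pipeline_config, c(
    raw[setdiff(names(raw), c("terrain", "design", "flux"))],
    list(terrain = terrain, design = design, flux = flux)
  ))
}

# variogram fitting + selection + OK/KED maps + LOO CV for one variable
map_variable <- function(var, proxies, config, drift_raster, grid_raster,
                         grid_drift, drift_at_pos) {
  data <- dplyr::select(proxies, "x", "y", value = dplyr::all_of(var)) |>
    dplyr::mutate(drift = drift_at_pos)
  data <- data[stats::complete.cases(data), ]
  emp <- empirical_variogram(data, value, n_bins = config$n_bins)
  fits <- purrr::map(config$families, function(fam) {
    tryCatch(fit_variogram_model(emp, fam), error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  diag <- study_diagonal(data)
  sel <- if (length(fits)) select_variogram(fits, diag) else
    structure(list(reason = "no convergent fits"), class = "variogram_rejection")
  rejected <- inherits(sel, "variogram_rejection")
  # without a valid variogram there is no OK map; KED still needs a
  # covariance model, so fall back to the best-efficiency fit for the drift map
  model <- if (!rejected) sel else if (length(fits)) {
    fits[[which.max(purrr::map_dbl(fits, function(f) f$e %||% -Inf))]]
  } else NULL
  out <- list(variable = var, variogram = emp, fits = fits, selected = sel,
              rejected = rejected, model = model,
              ok_map = NULL, ked_map = NULL, cv_ok = NULL, cv_ked = NULL)
  if (is.null(model)) return(out)
  if (!rejected) {
    out$ok_map <- krige_ok(data, value, grid_raster, model)
    out$cv_ok <- loo_cross_validate(data, value, model, "ok")
  }
  out$ked_map <- krige_ked(data, value, drift, grid_raster, grid_drift, model)
  out$cv_ked <- loo_cross_validate(data, value, model, "ked", drift = drift)
  out
}

#' Run the full stability-analysis pipeline
#'
#' Executes, in order: input simulation (or reading), the terrain-attribute
#' pyramid, the stability proxies, variography + kriging (OK and
#' external-drift) with leave-one-out cross-validation for the four mapped
#' variables, the scale-dependent correlation scan, the bell-curve fit and
#' the two-state classification. All tables, rasters, a machine-readable
#' `summary.json` and a `manifest.json` are written to `out_dir`. Runs are
#' deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with every intermediate object
#'   (`dem`, `pyramid`, `terrain`, `proxies`, `maps`, `correlations`,
#'   `scale_classes`, `bell`, `states`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("rsrun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- step("inputs", {
    if (config$simulate) {
      sim <- simulate_study(config$terrain, config$design, config$flux,
                            seed = config$seed)
      list(dem = sim$dem, panel = sim$panel, positions = sim$positions)
    } else {
      dem <- read_esri_ascii(config$dem_path)
      panel <- read_panel_csv(config$panel_path)
      positions <- dplyr::distinct(panel, .data$position_id, .data$x, .data$y)
      list(dem = dem, panel = panel, positions = positions)
    }
  })

  pyramid <- step("terrain", build_pyramid(
    inputs$dem, max_level = config$max_level, kernel = config$kernel,
    window_cells = config$window_cells))
  terrain <- step("terrain", extract_terrain(pyramid, inputs$positions))

  proxies <- step("proxies", compute_proxies(inputs$panel, ties = config$ties))

  maps <- step("geostats", {
    if (config$drift_level > length(pyramid$levels)) {
      stop("`drift_level` (", config$drift_level,
           ") exceeds the number of pyramid levels built (",
           length(pyramid$levels), ").")
    }
    drift_raster <- pyramid$levels[[config$drift_level]]$attributes_base[[
      config$drift_attribute]]
    f <- config$map_cell_size / drift_raster$cell_size
    grid_raster <- aggregate_dem(drift_raster, as.integer(round(f)))
    grid_drift <- as_tibble.elev_raster(grid_raster)$value
    drift_at_pos <- extract_cells(drift_raster, inputs$positions$x,
                                  inputs$positions$y)
    purrr::map(
      rlang::set_names(c("rank_rs", "range_rs", "mean_soc", "mean_swc")),
      map_variable,
      proxies = proxies, config = config, drift_raster = drift_raster,
      grid_raster = grid_raster, grid_drift = grid_drift,
      drift_at_pos = drift_at_pos
    )
  })

  correlations <- step("analysis", correlation_scan(
    proxies, terrain, levels = config$scan_levels, alpha = config$alpha))
  scale_classes <- step("analysis", classify_scale_dependence(
    correlations, levels = config$scan_levels))
  bell <- step("analysis", fit_bell_curve(
    proxies, fix_moments = config$fix_moments))
  states <- step("analysis", classify_states(proxies))
  state_summary <- step("analysis", summarise_states(states, terrain))

  # --- outputs ----------------------------------------------------------
  wpath <- function(f) file.path(out_dir, f)
  write_esri_ascii(inputs$dem, wpath("dem.asc"))
  write_panel_csv(inputs$panel, wpath("panel.csv"))
  utils::write.csv(terrain, wpath("terrain_attributes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(proxies), wpath("proxies.csv"),
                   row.names = FALSE)
  utils::write.csv(correlations, wpath("correlations.csv"), row.names = FALSE)
  utils::write.csv(
    dplyr::mutate(scale_classes, levels_significant = purrr::map_chr(
      .data$levels_significant, paste, collapse = ";")),
    wpath("scale_classes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dplyr::select(states, -dplyr::any_of("date"))),
                   wpath("states.csv"), row.names = FALSE)
  cv_rows <- purrr::imap_dfr(maps, function(m, var) {
    purrr::imap_dfr(list(OK = m$cv_ok, KED = m$cv_ked), function(cv, meth) {
      if (is.null(cv)) return(NULL)
      tibble::tibble(variable = var, method = meth, mean_err = cv$mean_err,
                     nrmse = cv$nrmse, msdr = cv$msdr, n = cv$n)
    })
  })
  utils::write.csv(cv_rows, wpath("cv_report.csv"), row.names = FALSE)
  for (var in names(maps)) {
    m <- maps[[var]]
    if (!is.null(m$ked_map)) {
      grid_raster <- NULL
      rs <- kriged_to_raster(m$ked_map, template = {
        drift_raster <- pyramid$levels[[config$drift_level]]$attributes_base[[
          config$drift_attribute]]
        aggregate_dem(drift_raster,
                      as.integer(round(config$map_cell_size /
                                         drift_raster$cell_size)))
      })
      write_esri_ascii(rs$pred, wpath(sprintf("map_%s_ked.asc", var)))
      write_esri_ascii(rs$var, wpath(sprintf("map_%s_ked_var.asc", var)))
    }
  }

  summary <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_positions = nrow(proxies),
    n_campaigns = length(unique(inputs$panel$campaign)),
    rank_rs = list(mean = mean(proxies$rank_rs, na.rm = TRUE),
                   sd = stats::sd(proxies$rank_rs, na.rm = TRUE)),
    range_rs = list(mean = mean(proxies$range_rs, na.rm = TRUE),
                    max = max(proxies$range_rs, na.rm = TRUE)),
    bell = list(a = bell$a, mu = bell$mu, sigma = bell$sigma,
                r_squared = bell$r_squared, p = bell$f_p_value),
    variograms = purrr::map(maps, function(m) {
      if (m$rejected) list(selected = "rejected")
      else list(selected = m$selected$family, e = m$selected$e,
                range = m$selected$practical_range)
    }),
    cv = purrr::map(maps, function(m) {
      purrr::map(purrr::compact(list(ok = m$cv_ok, ked = m$cv_ked)),
                 function(cv) list(nrmse = cv$nrmse, mean_err = cv$mean_err,
                                   msdr = cv$msdr))
    }),
    states = as.list(table(states$state))
  )
  jsonlite::write_json(summary, wpath("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "rsstability",
    version = as.character(utils::packageVersion("rsstability")),
    seed = config$seed,
    config_hash = summary$config_hash,
    outputs = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  write_config(config, wpath("config.yaml"))

  invisible(list(dem = inputs$dem, panel = inputs$panel, pyramid = pyramid,
                 terrain = terrain, proxies = proxies, maps = maps,
                 correlations = correlations, scale_classes = scale_classes,
                 bell = bell, states = states, state_summary = state_summary,
                 summary = summary, out_dir = out_dir))
}
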