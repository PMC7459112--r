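# Shared fixtures: small deterministic rasters and panels built in code.

# tiny smooth raster: a tilted plane z = ax*x + ay*y + c at cell centers
plane_raster <- function(nrow = 20, ncol = 30, cell_size = 1,
                         ax = 0, ay = 0, c0 = 0) {
  xs <- (seq_len(ncol) - 0.5) * cell_size
  ys <- (nrow - seq_len(nrow) + 0.5) * cell_size  # row 1 = north
  z <- outer(ys, xs, function(y, x) ax * x + ay * y + c0)
  elev_raster(z, cell_size = cell_size)
}

# small campaign panel from explicit rs matrix (positions x campaigns)
panel_from_matrix <- function(rs, swc = NULL, soc = NULL) {
  n <- nrow(rs); k <- ncol(rs)
  if (is.null(swc)) swc <- matrix(20, n, k)
  if (is.null(soc)) soc <- matrix(NA_real_, n, k)
  ids <- sprintf("P%02d", seq_len(n))
  rows <- do.call(rbind, lapply(seq_len(k), function(c) {
    data.frame(position_id = ids, x = seq_len(n), y = 0, campaign = c,
               date = as.Date("2020-01-01") + c,
               rs = rs[, c], ts = 15, swc = swc[, c], soc = soc[, c])
  }))
  out <- tibble::as_tibble(rows)
  structure(out, class = c("campaign_panel", class(out)))
}

# small default simulation shared across tests (cheap sizes)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(
        terrain = terrain_config(nx = 160, ny = 128, cell_size = 0.5,
                                 correlation_length = 12),
        design = study_design(extent_x = 80, extent_y = 60),
        seed = 42
      )
    }
    cache
  }
})

# exponential-covariance Gaussian random field at given coords (for
# variogram / kriging recovery tests); direct Cholesky simulation
sim_gaussian_field <- function(coords, nugget, psill, range_par,
                               family = "spherical", seed = 1) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  sill <- nugget + psill
  cov <- sill - variogram_value(d, family, nugget, psill, range_par)
  diag(cov) <- sill
  set.seed(seed)
  ch <- chol(cov + diag(1e-10, n))
  as.vector(t(ch) %*% rnorm(n))
}
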