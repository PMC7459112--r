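#' Gridded elevation raster
#'
#' A minimal in-memory raster: a numeric matrix of cell values plus the cell
#' size and the projected coordinates of the lower-left corner. Rows run from
#' north (row 1) to south (last row), matching the ESRI ASCII grid layout;
#' columns run west to east. Missing cells are `NA`.
#'
#' @param values Numeric matrix of cell values (row 1 = northernmost row).
#' @param cell_size Cell edge length in metres (cells are square).
#' @param xll,yll Projected x/y of the lower-left corner of the grid (m).
#' @return An object of class `elev_raster`.
#' @examples
#' r <- elev_raster(matrix(1:12, nrow = 3), cell_size = 0.5)
#' raster_extent(r)
#' @export
elev_raster <- function(values, cell_size, xll = 0, yll = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number.", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("Raster values must be finite or NA.", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "elev_raster"
  )
}

#' @export
print.elev_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<elev_raster> %d rows x %d cols @ %g m (origin %g, %g)\n",
    nrow(v), ncol(v), x$cell_size, x$xll, x$yll
  ))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng))) {
    cat(sprintf("  values: [%.4g, %.4g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @describeIn elev_raster Extent as a named vector `xmin, xmax, ymin, ymax`.
#' @param r An `elev_raster`.
#' @export
raster_extent <- function(r) {
  stopifnot(inherits(r, "elev_raster"))
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cell_size,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cell_size)
}

#' Convert a raster to a tibble of cell centers
#'
#' @param x An `elev_raster`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (cell-center coordinates, m) and
#'   `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.elev_raster <- function(x, ...) {
  v <- x$values
  ny <- nrow(v); nx <- ncol(v)
  cs <- x$cell_size
  xs <- x$xll + (seq_len(nx) - 0.5) * cs
  ys <- x$yll + (ny - seq_len(ny) + 0.5) * cs  # row 1 is northernmost
  tibble::tibble(
    x = rep(xs, each = ny),
    y = rep(ys, times = nx),
    value = as.vector(v)
  )
}

# Row/col of the cell containing projected point(s); points on the max edge
# belong to the last cell. Errors on points outside the extent.
cell_index <- function(r, x, y) {
  ext <- raster_extent(r)
  eps <- 1e-9 * r$cell_size
  bad <- x < ext["xmin"] - eps | x > ext["xmax"] + eps |
    y < ext["ymin"] - eps | y > ext["ymax"] + eps
  if (any(bad)) {
    stop(sprintf("%d position(s) fall outside the raster extent (first: x=%g, y=%g).",
                 sum(bad), x[bad][1], y[bad][1]), call. = FALSE)
  }
  nx <- ncol(r$values); ny <- nrow(r$values)
  col <- pmin(nx, floor((x - r$xll) / r$cell_size) + 1L)
  iy <- pmin(ny, floor((y - r$yll) / r$cell_size) + 1L)  # from bottom
  row <- ny - iy + 1L
  cbind(row = pmax(1L, row), col = pmax(1L, col))
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point (no interpolation).
#'
#' @param r An `elev_raster`.
#' @param x,y Coordinate vectors (m, same projection as the raster).
#' @return Numeric vector of cell values.
#' @export
extract_cells <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  r$values[idx]
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, north first.
#'
#' @param path File path.
#' @return `read_esri_ascii()` returns an [elev_raster]; `write_esri_ascii()`
#'   returns `path` invisibly.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("Malformed ESRI ASCII header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, ".", call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  elev_raster(m, cell_size = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' @rdname read_esri_ascii
#' @param r An `elev_raster` to write.
#' @param nodata Value used to encode missing cells.
#' @param digits Significant digits written.
#' @export
write_esri_ascii <- function(r, path, nodata = -9999, digits = 7) {
  stopifnot(inherits(r, "elev_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1L, function(row) paste(signif(row, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
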