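#' Canonical topographic predictor names
#'
#' The six per-pixel predictors used throughout the package: topographic
#' position index at 50 m, 500 m and 5000 m neighbourhood radius, slope
#' angle, and the sine (eastness) and cosine (northness) of the compass
#' aspect.
#' @export
TOPO_FEATURES <- c("TPI_50m", "TPI_500m", "TPI_5000m",
                   "slope", "aspect_sin", "aspect_cos")

#' Topographic position index
#'
#' TPI at a pixel is its elevation minus the mean elevation of a square
#' neighbourhood of side `2 * round(radius_m / cell_size) + 1` pixels
#' centred on it (centre included). Positive values mark ridges and crests,
#' negative values depressions and valley floors. Edges are handled by
#' mirror reflection with edge repetition; nodata cells are excluded from
#' the neighbourhood mean and propagate to the output.
#'
#' @param elev Elevation [mt_raster] (metres).
#' @param radius_m Neighbourhood radius in metres; must be at least one
#'   cell.
#' @return [mt_raster] of TPI values in metres.
#' @export
tpi <- function(elev, radius_m) {
  stopifnot_raster(elev)
  if (!is.numeric(radius_m) || length(radius_m) != 1L ||
      radius_m < elev$cell_size)
    stop("`radius_m` must be a single value of at least one cell size",
         call. = FALSE)
  w <- as.integer(round(radius_m / elev$cell_size))
  mt_raster(elev$values - box_mean(elev$values, w),
            cell_size = elev$cell_size, origin = elev$origin)
}

# Horn 3x3 gradient: returns east (gx) and north (gy) components of
# d(elev)/d(distance), edge cells via clamped (replicated) borders. Any NA
# in the 3x3 stencil yields NA.
horn_gradient <- function(elev) {
  m <- elev$values
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L)
    stop("grid must be at least 3x3 for slope/aspect", call. = FALSE)
  up <- c(1L, 1L:(nr - 1L)); dn <- c(2L:nr, nr)
  lf <- c(1L, 1L:(nc - 1L)); rt <- c(2L:nc, nc)
  z1 <- m[up, lf]; z2 <- m[up, ]; z3 <- m[up, rt]
  z4 <- m[, lf];                  z6 <- m[, rt]
  z7 <- m[dn, lf]; z8 <- m[dn, ]; z9 <- m[dn, rt]
  d <- 8 * elev$cell_size
  gx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / d   # +x = east
  gy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / d   # +y = north
  bad <- is.na(z1) | is.na(z2) | is.na(z3) | is.na(z4) | is.na(m) |
    is.na(z6) | is.na(z7) | is.na(z8) | is.na(z9)
  gx[bad] <- NA_real_; gy[bad] <- NA_real_
  list(gx = gx, gy = gy)
}

#' Slope angle
#'
#' Horn's 3x3 finite-difference gradient;
#' `slope = atan(sqrt(gx^2 + gy^2))` in degrees. Border cells use
#' replicated edges; a nodata cell anywhere in the stencil yields nodata.
#'
#' @param elev Elevation [mt_raster].
#' @return [mt_raster] of slope in degrees, in `[0, 90)`.
#' @export
horn_slope <- function(elev) {
  stopifnot_raster(elev)
  g <- horn_gradient(elev)
  mt_raster(atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi,
            cell_size = elev$cell_size, origin = elev$origin)
}

#' Aspect as eastness and northness components
#'
#' Aspect is the compass direction the slope faces (its downhill
#' direction, 0 deg = north, 90 deg = east). To avoid the circular
#' discontinuity it is returned as `aspect_sin` (eastness) and
#' `aspect_cos` (northness), the unit downhill vector. Flat cells
#' (zero gradient) get the documented sentinel `(0, 0)`, keeping the full
#' feature vector defined on every valid pixel.
#'
#' @param elev Elevation [mt_raster].
#' @return List of two [mt_raster]s, `aspect_sin` and `aspect_cos`.
#' @export
aspect_components <- function(elev) {
  stopifnot_raster(elev)
  g <- horn_gradient(elev)
  mag <- sqrt(g$gx^2 + g$gy^2)
  sin_ <- ifelse(mag > 0, -g$gx / mag, 0)   # downhill = -gradient
  cos_ <- ifelse(mag > 0, -g$gy / mag, 0)
  sin_[is.na(g$gx)] <- NA_real_
  cos_[is.na(g$gx)] <- NA_real_
  list(
    aspect_sin = mt_raster(sin_, cell_size = elev$cell_size,
                           origin = elev$origin),
    aspect_cos = mt_raster(cos_, cell_size = elev$cell_size,
                           origin = elev$origin)
  )
}

#' Topographic roughness of a tile
#'
#' Population standard deviation of valid elevations inside a landscape
#' window.
#'
#' @param elev Elevation [mt_raster].
#' @param window One-row data frame with `row0`, `row1`, `col0`, `col1`
#'   (1-based inclusive pixel bounds), as produced by [tile_windows()]; or
#'   `NULL` to use the whole grid.
#' @return Standard deviation in metres; `NA` (with a warning) when the
#'   tile holds fewer than two valid cells.
#' @export
tile_roughness <- function(elev, window = NULL) {
  stopifnot_raster(elev)
  v <- if (is.null(window)) elev$values else
    elev$values[window$row0:window$row1, window$col0:window$col1]
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    warning("tile has fewer than 2 valid cells; roughness undefined")
    return(NA_real_)
  }
  sqrt(mean((v - mean(v))^2))
}

#' Derive the six topographic predictors from elevation
#'
#' Computes TPI at each requested radius, slope, and the aspect components,
#' on the full grid (so TPI neighbourhoods cross tile boundaries, as they
#' should).
#'
#' @param elev Elevation [mt_raster].
#' @param radii TPI neighbourhood radii in metres.
#' @return Named list of [mt_raster]s, one per feature, names
#'   `TPI_<r>m`, `slope`, `aspect_sin`, `aspect_cos`.
#' @export
feature_stack <- function(elev, radii = c(50, 500, 5000)) {
  stopifnot_raster(elev)
  out <- list()
  for (r in radii) out[[sprintf("TPI_%gm", r)]] <- tpi(elev, r)
  out$slope <- horn_slope(elev)
  asp <- aspect_components(elev)
  out$aspect_sin <- asp$aspect_sin
  out$aspect_cos <- asp$aspect_cos
  out
}

#' Flatten a feature stack to a per-pixel table
#'
#' @param features Named list of [mt_raster]s (from [feature_stack()]).
#' @return Data frame with one column per feature plus `row` and `col`
#'   pixel indices; one row per grid cell in column-major order. Rows with
#'   any nodata feature carry `NA`s (filter with [stats::complete.cases()]).
#' @export
feature_table <- function(features) {
  stopifnot(length(features) > 0)
  d <- dim(features[[1]]$values)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  out <- as.data.frame(lapply(features, function(f) as.vector(f$values)))
  names(out) <- names(features)
  cbind(out, idx)
}
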