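#' Partition a grid into square landscape tiles
#'
#' Non-overlapping `tile_size` x `tile_size` pixel windows covering the
#' grid from the top-left corner; trailing partial tiles (when the grid is
#' not divisible by `tile_size`) are dropped rather than padded, so every
#' landscape has the same area. At 30 m cells the default 333-pixel tile
#' is approximately the 0.1 degree (~10 km) landscape used in continental
#' analyses.
#'
#' @param x An [mt_raster] or an integer `(rows, cols)` vector.
#' @param tile_size Tile edge length in pixels.
#' @return Data frame with columns `tile_id`, `row0`, `row1`, `col0`,
#'   `col1` (1-based inclusive pixel bounds).
#' @export
tile_windows <- function(x, tile_size = 333L) {
  d <- if (is_mt_raster(x)) dim(x$values) else as.integer(x)
  tile_size <- as.integer(tile_size)
  if (tile_size < 1L) stop("`tile_size` must be >= 1", call. = FALSE)
  ntr <- d[1] %/% tile_size; ntc <- d[2] %/% tile_size
  if (ntr < 1L || ntc < 1L)
    stop("grid smaller than one tile", call. = FALSE)
  g <- expand.grid(tr = seq_len(ntr), tc = seq_len(ntc))
  data.frame(
    tile_id = seq_len(nrow(g)),
    row0 = (g$tr - 1L) * tile_size + 1L,
    row1 = g$tr * tile_size,
    col0 = (g$tc - 1L) * tile_size + 1L,
    col1 = g$tc * tile_size
  )
}

#' Locate the tree-cover threshold between the open and closed modes
#'
#' Smooths the frequency distribution of percent tree cover with a kernel
#' density estimate (Gaussian kernel, bandwidth by Silverman's
#' rule-of-thumb) and returns the location of the density minimum between
#' the two highest modes. In bimodal tree-cover regions this is the
#' natural cut separating savanna from forest states; continental studies
#' use the fixed value 65.
#'
#' @param percent_values Numeric vector of percent-cover values (>= 1000
#'   valid values required).
#' @param bw Bandwidth passed to [stats::density()].
#' @return Threshold in percent cover.
#' @seealso [classify_pixels()]
#' @section Errors: Signals a condition of class `mt_bimodality_error`
#'   when fewer than two modes are present; callers may fall back to a
#'   fixed threshold.
#' @export
find_bimodal_threshold <- function(percent_values, bw = "nrd0") {
  v <- percent_values[is.finite(percent_values)]
  if (length(v) < 1000L)
    stop("need at least 1000 valid values to locate the mode gap",
         call. = FALSE)
  d <- stats::density(v, bw = bw, n = 1024)
  y <- d$y
  # interior local maxima, ignoring numerically negligible ripples
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= 0.01 * max(y)]
  bimodality_error <- function() {
    cond <- structure(
      class = c("mt_bimodality_error", "error", "condition"),
      list(message = "distribution is not bimodal: fewer than two modes found",
           call = sys.call(-2)))
    stop(cond)
  }
  if (length(is_max) < 2L) bimodality_error()
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  dip <- min(y[seg])
  # the two candidate modes must be separated by a real trough, not a
  # numerical ripple on a unimodal hump
  if (dip > 0.9 * min(y[top2])) bimodality_error()
  d$x[seg[which.min(y[seg])]]
}

#' Binarize percent tree cover into open/closed labels
#'
#' A pixel is closed where percent cover is strictly greater than the
#' threshold (so a pixel exactly at the threshold is open); nodata
#' propagates.
#'
#' @param percent [mt_raster] of percent cover in `[0, 100]`.
#' @param threshold Percent-cover threshold (default 65, the minimum
#'   between the two modes of the continental cover distribution).
#' @return [mt_raster] with values 0 (open), 1 (closed) and `NA`.
#' @export
classify_pixels <- function(percent, threshold = 65) {
  stopifnot_raster(percent)
  v <- percent$values
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("percent cover must lie in [0, 100]", call. = FALSE)
  lab <- ifelse(v > threshold, 1, 0)
  mt_raster(lab, cell_size = percent$cell_size, origin = percent$origin)
}

#' Classify a landscape tile from its cover fractions
#'
#' A tile with less than `min_valid` valid (non-masked) pixels is
#' `excluded`. Otherwise it is a `mosaic` when the closed fraction (over
#' valid pixels) lies in `mosaic_bounds` (inclusive, default
#' `[0.05, 0.95]`, i.e. at least 5% of each cover state),
#' `homogeneous_closed` above the upper bound and `homogeneous_open`
#' below the lower bound.
#'
#' @param fraction_closed Closed fraction over valid pixels (vectorized).
#' @param fraction_valid Valid fraction over all tile pixels (vectorized).
#' @param mosaic_bounds Length-2 inclusive bounds on the closed fraction.
#' @param min_valid Minimum valid-pixel fraction for a tile to be used.
#' @return Factor with levels `mosaic`, `homogeneous_open`,
#'   `homogeneous_closed`, `excluded`.
#' @export
classify_landscape <- function(fraction_closed, fraction_valid,
                               mosaic_bounds = c(0.05, 0.95),
                               min_valid = 0.75) {
  lv <- c("mosaic", "homogeneous_open", "homogeneous_closed", "excluded")
  out <- rep("excluded", length(fraction_closed))
  ok <- !is.na(fraction_valid) & fraction_valid >= min_valid &
    !is.na(fraction_closed)
  fc <- fraction_closed
  out[ok & fc >= mosaic_bounds[1] & fc <= mosaic_bounds[2]] <- "mosaic"
  out[ok & fc > mosaic_bounds[2]] <- "homogeneous_closed"
  out[ok & fc < mosaic_bounds[1]] <- "homogeneous_open"
  factor(out, levels = lv)
}

#' Build the per-landscape summary table
#'
#' Tiles the label grid, computes per-tile cover fractions, classifies
#' each tile, and (when elevation is supplied) adds topographic roughness.
#'
#' @param labels Label [mt_raster] (0 = open, 1 = closed, `NA` invalid).
#' @param elev Optional elevation [mt_raster] on the same grid, for
#'   roughness.
#' @param tile_size Tile edge in pixels.
#' @param mosaic_bounds,min_valid Passed to [classify_landscape()].
#' @return Data frame (one row per tile): `tile_id`, pixel bounds,
#'   `fraction_valid`, `fraction_open`, `fraction_closed`,
#'   `landscape_class`, and `roughness` when elevation is given.
#' @export
landscape_table <- function(labels, elev = NULL, tile_size = 333L,
                            mosaic_bounds = c(0.05, 0.95),
                            min_valid = 0.75) {
  stopifnot_raster(labels)
  tiles <- tile_windows(labels, tile_size)
  n <- nrow(tiles)
  fv <- fo <- fc <- rg <- numeric(n)
  for (i in seq_len(n)) {
    v <- labels$values[tiles$row0[i]:tiles$row1[i],
                       tiles$col0[i]:tiles$col1[i]]
    nv <- sum(!is.na(v))
    fv[i] <- nv / length(v)
    fc[i] <- if (nv > 0) sum(v == 1, na.rm = TRUE) / nv else NA_real_
    fo[i] <- if (nv > 0) 1 - fc[i] else NA_real_
    rg[i] <- if (!is.null(elev))
      suppressWarnings(tile_roughness(elev, tiles[i, ])) else NA_real_
  }
  out <- cbind(tiles,
               data.frame(fraction_valid = fv, fraction_open = fo,
                          fraction_closed = fc))
  out$landscape_class <- classify_landscape(fc, fv, mosaic_bounds, min_valid)
  if (!is.null(elev)) out$roughness <- rg
  out
}

#' Aggregate a covariate raster to landscape means
#'
#' Arithmetic mean of valid covariate cells per tile (the rule used to
#' bring ~1 km climate grids onto the landscape scale). The covariate is
#' first aligned to the tile grid's raster when origins/cell sizes differ.
#'
#' @param covariate Covariate [mt_raster].
#' @param tiles Tile table from [tile_windows()] / [landscape_table()].
#' @param template Optional [mt_raster] defining the grid the tile bounds
#'   refer to; when given and differing from `covariate`'s geometry, the
#'   covariate is resampled onto it with [align_nearest()].
#' @return Numeric vector of per-tile means (`NA` for fully-nodata tiles).
#' @export
aggregate_to_landscapes <- function(covariate, tiles, template = NULL) {
  stopifnot_raster(covariate)
  if (!is.null(template) &&
      (!identical(dim(covariate$values), dim(template$values)) ||
       covariate$cell_size != template$cell_size ||
       !identical(covariate$origin, template$origin)))
    covariate <- align_nearest(covariate, template)
  vapply(seq_len(nrow(tiles)), function(i) {
    v <- covariate$values[tiles$row0[i]:tiles$row1[i],
                          tiles$col0[i]:tiles$col1[i]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Histogram of landscape composition over mosaic tiles
#'
#' Counts of mosaic landscapes by closed-cover fraction over fixed-width
#' bins spanning the mosaic range `[0.05, 0.95]`.
#'
#' @param records Landscape table from [landscape_table()].
#' @param n_bins Number of equal-width bins.
#' @return Data frame with `bin_lo`, `bin_hi`, `mid`, `count`.
#' @export
composition_histogram <- function(records, n_bins = 18L) {
  fc <- records$fraction_closed[records$landscape_class == "mosaic"]
  if (!length(fc)) stop("no mosaic landscapes in `records`", call. = FALSE)
  edges <- seq(0.05, 0.95, length.out = n_bins + 1L)
  bin <- findInterval(fc, edges, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             mid = (edges[-1] + edges[-length(edges)]) / 2,
             count = tabulate(bin, nbins = n_bins))
}
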