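#' @title Balanced pixel sampling for cover models
#' @description Sample sets are plain data frames with one column per
#'   topographic feature plus `label` (factor `open`/`closed`), `tile_id`,
#'   `row`, `col`, and attributes `seed` and `provenance`. No sampled
#'   pixel is nodata in the labels or any feature, and every produced set
#'   is class-balanced. Per-tile draws use a deterministic substream
#'   derived from the master seed and the tile id, so results do not
#'   depend on tile iteration order.
#' @name sampling
NULL

# label vector, feature matrix and validity over the whole grid
grid_arrays <- function(labels, features) {
  labv <- as.vector(labels$values)
  fmat <- vapply(features, function(f) as.vector(f$values),
                 numeric(length(labv)))
  valid <- !is.na(labv) & rowSums(is.na(fmat)) == 0L
  list(labv = labv, fmat = fmat, valid = valid, nr = nrow(labels$values))
}

# linear (column-major) cell indices of a tile
tile_cells <- function(tile, nr) {
  rows <- tile$row0:tile$row1
  cols <- tile$col0:tile$col1
  as.vector(outer(rows, (cols - 1L) * nr, "+"))
}

make_sample_set <- function(cells, ga, seed, provenance) {
  nr <- ga$nr
  df <- as.data.frame(ga$fmat[cells, , drop = FALSE])
  df$label <- factor(ifelse(ga$labv[cells] == 1, "closed", "open"),
                     levels = c("open", "closed"))
  df$row <- ((cells - 1L) %% nr) + 1L
  df$col <- ((cells - 1L) %/% nr) + 1L
  attr(df, "seed") <- seed
  attr(df, "provenance") <- provenance
  df
}

#' Stratified regional sample across all mosaic landscapes
#'
#' Draws `n_per_class` open and `n_per_class` closed valid pixels
#' uniformly without replacement from each mosaic tile. A tile with fewer
#' than `n_per_class` pixels of one class contributes all pixels of the
#' deficient class and an equal number of the other, preserving balance;
#' shortfalls are recorded in the `shortfall` attribute.
#'
#' @param labels Label [mt_raster] (0/1/`NA`).
#' @param features Named list of feature [mt_raster]s.
#' @param tiles Landscape table ([landscape_table()]); only rows with
#'   `landscape_class == "mosaic"` are sampled.
#' @param n_per_class Pixels per class per tile (default 5).
#' @param seed Master seed.
#' @return Sample-set data frame (see [sampling]); attribute `shortfall`
#'   lists tiles that could not supply the full quota.
#' @export
sample_regional <- function(labels, features, tiles, n_per_class = 5L,
                            seed = 1L) {
  stopifnot_raster(labels)
  mos <- tiles[tiles$landscape_class == "mosaic", , drop = FALSE]
  if (!nrow(mos))
    stop("no mosaic landscapes to sample from", call. = FALSE)
  ga <- grid_arrays(labels, features)
  picks <- vector("list", nrow(mos))
  short <- list()
  for (i in seq_len(nrow(mos))) {
    cells <- tile_cells(mos[i, ], ga$nr)
    cells <- cells[ga$valid[cells]]
    op <- cells[ga$labv[cells] == 0]
    cl <- cells[ga$labv[cells] == 1]
    k <- min(n_per_class, length(op), length(cl))
    if (k < n_per_class)
      short[[length(short) + 1L]] <-
        data.frame(tile_id = mos$tile_id[i], n_open = length(op),
                   n_closed = length(cl), n_taken_per_class = as.integer(k))
    if (k == 0L) next
    sel <- with_seed(mix_seed(seed, mos$tile_id[i]), {
      c(if (length(op) == 1L) op else sample(op, k),
        if (length(cl) == 1L) cl else sample(cl, k))
    })
    picks[[i]] <- data.frame(cell = sel, tile_id = mos$tile_id[i])
  }
  picks <- do.call(rbind, picks)
  if (is.null(picks))
    stop("no mosaic tile had pixels of both classes", call. = FALSE)
  out <- make_sample_set(picks$cell, ga, seed, "regional")
  out$tile_id <- picks$tile_id
  attr(out, "shortfall") <- if (length(short)) do.call(rbind, short) else NULL
  out
}

#' Balanced sample from a single mosaic landscape
#'
#' Draws `n_total / 2` pixels per class without replacement; when the
#' minority class has fewer valid pixels, both classes are shrunk to the
#' minority count so balance is preserved. Tiles whose minority count is
#' below `min_per_class` are skipped: a zero-row set is returned with a
#' `skip_reason` attribute.
#'
#' @param labels,features As in [sample_regional()].
#' @param tile One row of the landscape table; must be a mosaic.
#' @param n_total Target total sample size (default 5000, evenly split).
#' @param min_per_class Minimum per-class count below which the tile is
#'   skipped (default 50).
#' @param seed Master seed (mixed with the tile id).
#' @return Sample-set data frame, possibly zero-row with `skip_reason`.
#' @export
sample_local <- function(labels, features, tile, n_total = 5000L,
                         min_per_class = 50L, seed = 1L) {
  stopifnot_raster(labels)
  if (nrow(tile) != 1L)
    stop("`tile` must be a single landscape-table row", call. = FALSE)
  if (as.character(tile$landscape_class) != "mosaic")
    stop(sprintf("tile %s is not a mosaic landscape", tile$tile_id),
         call. = FALSE)
  ga <- grid_arrays(labels, features)
  cells <- tile_cells(tile, ga$nr)
  cells <- cells[ga$valid[cells]]
  op <- cells[ga$labv[cells] == 0]
  cl <- cells[ga$labv[cells] == 1]
  k <- min(n_total %/% 2L, length(op), length(cl))
  if (k < min_per_class) {
    out <- make_sample_set(integer(0), ga, seed, "local")
    out$tile_id <- integer(0)
    attr(out, "skip_reason") <-
      sprintf("minority class has %d valid pixels (< %d)",
              min(length(op), length(cl)), min_per_class)
    return(out)
  }
  sel <- with_seed(mix_seed(seed, tile$tile_id),
                   c(sample(op, k), sample(cl, k)))
  out <- make_sample_set(sel, ga, seed, "local")
  out$tile_id <- tile$tile_id
  out
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive split stratified by label; per-class training
#' counts are within one row of `train_fraction` times the class size.
#'
#' @param samples Sample-set data frame with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Seed for the shuffle.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(samples, train_fraction = 0.8, seed = 1L) {
  if (nrow(samples) < 10L)
    stop("need at least 10 rows to split", call. = FALSE)
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(samples)), samples$label), function(ix) {
      n_tr <- round(train_fraction * length(ix))
      n_tr <- max(1L, min(length(ix) - 1L, n_tr))
      if (length(ix) == 1L) ix else sample(ix, n_tr)
    }), use.names = FALSE)
  })
  train <- samples[sort(idx_train), , drop = FALSE]
  test <- samples[setdiff(seq_len(nrow(samples)), idx_train), , drop = FALSE]
  for (a in c("seed", "provenance")) {
    attr(train, a) <- attr(samples, a)
    attr(test, a) <- attr(samples, a)
  }
  list(train = train, test = test)
}
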