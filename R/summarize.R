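#' Split mosaic landscapes by composition
#'
#' Partitions the mosaic tiles into mostly-open, balanced and
#' mostly-closed subsets by closed-cover fraction at the two bounds
#' (default thirds).
#'
#' @param table Landscape table ([landscape_table()]).
#' @param bounds Length-2 increasing cut points on `fraction_closed`.
#' @return Named list of three integer vectors of `tile_id`s:
#'   `mostly_open` (fraction_closed < bounds[1]), `balanced`
#'   (in `[bounds[1], bounds[2]]`) and `mostly_closed` (> bounds[2]).
#' @export
composition_subsets <- function(table, bounds = c(1 / 3, 2 / 3)) {
  mos <- table[table$landscape_class == "mosaic", , drop = FALSE]
  if (!nrow(mos)) stop("no mosaic landscapes in `table`", call. = FALSE)
  fc <- mos$fraction_closed
  list(mostly_open = mos$tile_id[fc < bounds[1]],
       balanced = mos$tile_id[fc >= bounds[1] & fc <= bounds[2]],
       mostly_closed = mos$tile_id[fc > bounds[2]])
}

regional_fit_eval <- function(samples, config, seed, ale_features,
                              n_bins = 20L) {
  sp <- split_train_test(samples, 0.8, seed = mix_seed(seed, 999983L))
  model <- fit_cover_model(sp$train, config)
  curves <- lapply(ale_features, function(f)
    ale_curve(model, sp$train, f, n_bins = n_bins))
  names(curves) <- ale_features
  list(model = model,
       accuracy = model_accuracy(model, sp$test),
       importance = feature_importance(model),
       top_feature = top_feature(model),
       ale = curves,
       directions = vapply(curves, function(cv)
         as.numeric(effect_direction(cv)), numeric(1)),
       n_train = nrow(sp$train), n_test = nrow(sp$test))
}

#' Fit and evaluate the regional cover model
#'
#' Draws the stratified regional sample (5 + 5 pixels per mosaic
#' landscape), splits 80/20, fits the configured forest, and reports
#' held-out accuracy, impurity importances and ALE curves per feature.
#' The same procedure is repeated on each composition subset
#' (mostly open / balanced / mostly closed) so effects that cancel in the
#' pooled model can be inspected separately.
#'
#' @param labels Label [mt_raster].
#' @param features Named list of feature [mt_raster]s.
#' @param table Landscape table.
#' @param config A [model_config()].
#' @param seed Master seed.
#' @param n_per_class Pixels per class per landscape (default 5).
#' @param subset_bounds Composition cut points for
#'   [composition_subsets()].
#' @param n_bins ALE bins.
#' @return List: `accuracy`, `importance`, `top_feature`, `ale` (list of
#'   [ale_curve()]s), `directions`, sample sizes, and `subsets` (the same
#'   summary per composition subset; subsets with fewer than 10 rows are
#'   recorded as skipped).
#' @export
run_regional <- function(labels, features, table, config = model_config(),
                         seed = 1L, n_per_class = 5L,
                         subset_bounds = c(1 / 3, 2 / 3), n_bins = 20L) {
  samples <- sample_regional(labels, features, table, n_per_class, seed)
  feats <- sample_feature_cols(samples)
  out <- regional_fit_eval(samples, config, seed, feats, n_bins)
  out$n_samples <- nrow(samples)
  sub_ids <- composition_subsets(table, subset_bounds)
  out$subsets <- lapply(sub_ids, function(ids) {
    rows <- samples[samples$tile_id %in% ids, , drop = FALSE]
    if (nrow(rows) < 10L)
      return(list(skipped = TRUE,
                  reason = sprintf("only %d rows", nrow(rows))))
    c(regional_fit_eval(rows, config, seed, feats, n_bins),
      list(skipped = FALSE))
  })
  out
}

#' Fit and evaluate one cover model per mosaic landscape
#'
#' For every mosaic tile: draw a balanced within-tile sample (default
#' 5000 pixels, shrunk to the minority class when necessary, skipped
#' below 50 per class), split 80/20, fit the configured forest, and
#' record held-out accuracy, normalized importances, the top feature and
#' the signed and absolute ALE effect directions of every feature.
#' Per-tile seeds are deterministic substreams of the master seed.
#'
#' @param labels Label [mt_raster].
#' @param features Named list of feature [mt_raster]s.
#' @param table Landscape table (its `fraction_closed` and `roughness`
#'   columns are carried into the results).
#' @param config A [model_config()].
#' @param seed Master seed.
#' @param n_total Per-tile sample target (default 5000).
#' @param min_per_class Skip threshold (default 50).
#' @param n_bins ALE bins.
#' @return Data frame with one row per mosaic tile: `tile_id`,
#'   `accuracy`, `top_feature`, `imp_<feature>`, `dir_<feature>`,
#'   `absdir_<feature>`, `fraction_closed`, `roughness`, `n_train`,
#'   `skipped`, `skip_reason`. Attribute `summary` holds the mean
#'   accuracy over fitted tiles and the share exceeding 0.625.
#' @export
run_local <- function(labels, features, table, config = model_config(),
                      seed = 1L, n_total = 5000L, min_per_class = 50L,
                      n_bins = 20L) {
  mos <- table[table$landscape_class == "mosaic", , drop = FALSE]
  if (!nrow(mos)) {
    warning("no mosaic landscapes; returning empty result")
    return(structure(data.frame(), summary = list(n_fitted = 0L)))
  }
  fnames <- names(features)
  rows <- vector("list", nrow(mos))
  for (i in seq_len(nrow(mos))) {
    tile <- mos[i, , drop = FALSE]
    base <- data.frame(tile_id = tile$tile_id,
                       fraction_closed = tile$fraction_closed,
                       roughness = if ("roughness" %in% names(tile))
                         tile$roughness else NA_real_)
    samp <- sample_local(labels, features, tile, n_total, min_per_class,
                         seed)
    if (!nrow(samp)) {
      base$accuracy <- NA_real_; base$top_feature <- NA_character_
      for (f in fnames) {
        base[[paste0("imp_", f)]] <- NA_real_
        base[[paste0("dir_", f)]] <- NA_real_
        base[[paste0("absdir_", f)]] <- NA_real_
      }
      base$n_train <- 0L
      base$skipped <- TRUE
      base$skip_reason <- attr(samp, "skip_reason")
      rows[[i]] <- base
      next
    }
    tile_cfg <- config
    tile_cfg$seed <- mix_seed(config$seed, tile$tile_id)
    sp <- split_train_test(samp, 0.8, seed = mix_seed(seed, tile$tile_id + 1L))
    model <- fit_cover_model(sp$train, tile_cfg)
    imp <- feature_importance(model)
    base$accuracy <- model_accuracy(model, sp$test)
    base$top_feature <- top_feature(model)
    for (f in fnames) {
      cv <- ale_curve(model, sp$train, f, n_bins = n_bins)
      base[[paste0("imp_", f)]] <- unname(imp[f])
      base[[paste0("dir_", f)]] <- as.numeric(effect_direction(cv))
      base[[paste0("absdir_", f)]] <- as.numeric(abs_effect_direction(cv))
    }
    base$n_train <- nrow(sp$train)
    base$skipped <- FALSE
    base$skip_reason <- NA_character_
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows)
  acc <- out$accuracy[!out$skipped]
  attr(out, "summary") <- list(
    n_fitted = sum(!out$skipped),
    n_skipped = sum(out$skipped),
    mean_accuracy = if (length(acc)) mean(acc) else NA_real_,
    share_above_0625 = if (length(acc)) mean(acc > 0.625) else NA_real_,
    top_feature_counts = as.list(base::table(out$top_feature[!out$skipped]))
  )
  out
}

#' Two-dimensional binned summary of landscapes
#'
#' Regular-grid binning of a landscape metric over two covariates, with
#' sparsely populated bins masked, as used for composition-versus-climate
#' heat maps.
#'
#' @param table Data frame of landscapes.
#' @param x,y Covariate column names.
#' @param statistic Column to average per bin (default
#'   `"fraction_closed"`).
#' @param n_bins Bins per axis.
#' @param min_count Bins with fewer rows are masked (`NA`), default 10.
#' @return List: `x_breaks`, `y_breaks`, `count` matrix, `stat` matrix
#'   (rows index x-bins, columns y-bins; masked cells `NA`).
#' @export
bin_2d <- function(table, x, y, statistic = "fraction_closed",
                   n_bins = 10L, min_count = 10L) {
  for (col in c(x, y, statistic))
    if (!col %in% names(table))
      stop(sprintf("column '%s' not in table", col), call. = FALSE)
  ok <- stats::complete.cases(table[, c(x, y, statistic)])
  tb <- table[ok, , drop = FALSE]
  xb <- seq(min(tb[[x]]), max(tb[[x]]), length.out = n_bins + 1L)
  yb <- seq(min(tb[[y]]), max(tb[[y]]), length.out = n_bins + 1L)
  ix <- findInterval(tb[[x]], xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(tb[[y]], yb, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- matrix(0L, n_bins, n_bins)
  st <- matrix(NA_real_, n_bins, n_bins)
  for (k in seq_len(nrow(tb))) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1L
  sums <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(tb)))
    sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + tb[[statistic]][k]
  nonzero <- cnt > 0
  st[nonzero] <- sums[nonzero] / cnt[nonzero]
  st[cnt < min_count] <- NA_real_
  list(x_breaks = xb, y_breaks = yb, count = cnt, stat = st)
}

#' Relate a per-landscape metric to a covariate
#'
#' Covariate-binned means of the metric plus a Spearman rank correlation
#' across landscapes (e.g. accuracy versus roughness, effect direction
#' versus composition).
#'
#' @param results Data frame of per-landscape results (>= 10 complete
#'   rows).
#' @param metric,covariate Column names.
#' @param n_bins Number of equal-width covariate bins.
#' @return List: `bins` (data frame `center`, `mean`, `n`), `rho`
#'   (Spearman correlation; `NA` with attribute `degenerate` when the
#'   covariate is constant).
#' @export
relate <- function(results, metric, covariate, n_bins = 5L) {
  ok <- stats::complete.cases(results[, c(metric, covariate)])
  tb <- results[ok, , drop = FALSE]
  if (nrow(tb) < 10L)
    stop("need at least 10 complete results", call. = FALSE)
  m <- tb[[metric]]; cv <- tb[[covariate]]
  if (stats::sd(cv) == 0) {
    return(list(bins = data.frame(center = mean(cv), mean = mean(m),
                                  n = length(m)),
                rho = structure(NA_real_, degenerate = TRUE)))
  }
  br <- seq(min(cv), max(cv), length.out = n_bins + 1L)
  bin <- findInterval(cv, br, rightmost.closed = TRUE, all.inside = TRUE)
  bins <- data.frame(
    center = (br[-1] + br[-length(br)]) / 2,
    mean = as.numeric(tapply(m, factor(bin, levels = seq_len(n_bins)), mean)),
    n = tabulate(bin, nbins = n_bins)
  )
  list(bins = bins,
       rho = structure(stats::cor(m, cv, method = "spearman"),
                       degenerate = FALSE))
}
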