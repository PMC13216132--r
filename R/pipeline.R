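#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the chain
#' simulate -> features -> classify-landscapes -> regional model ->
#' local models -> summaries, under a single master seed. Either supply
#' paths to existing elevation/percent-cover rasters, or set
#' `simulate = TRUE` to generate them from the bundled synthetic
#' generators.
#'
#' @param out_dir Output directory (created if missing).
#' @param elevation_path,percent_path,mask_path Optional input raster
#'   paths (any format of [read_raster()]).
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param sim_shape,sim_amplitude,sim_exponent,sim_coefficients,sim_noise_sd
#'   Synthetic-input parameters (used when `simulate = TRUE`).
#' @param cell_size Metres per pixel for simulated grids.
#' @param tile_size Landscape tile edge in pixels.
#' @param threshold Percent-cover threshold for open/closed.
#' @param mosaic_bounds,min_valid Landscape classification rules.
#' @param radii TPI radii in metres.
#' @param n_trees,min_samples_leaf,max_depth Forest hyperparameters.
#' @param n_per_class Regional pixels per class per landscape.
#' @param n_local Per-tile local sample target.
#' @param subset_bounds Composition subset cut points.
#' @param seed Master seed; every stage derives its substream from it.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(out_dir,
                            elevation_path = NULL, percent_path = NULL,
                            mask_path = NULL, simulate = is.null(elevation_path),
                            sim_shape = c(256, 384), sim_amplitude = 15,
                            sim_exponent = 2.5,
                            sim_coefficients = c(TPI_500m = -2),
                            sim_noise_sd = 1,
                            cell_size = 30, tile_size = 128L,
                            threshold = 65, mosaic_bounds = c(0.05, 0.95),
                            min_valid = 0.75, radii = c(50, 500, 5000),
                            n_trees = 100L, min_samples_leaf = 10L,
                            max_depth = 10L, n_per_class = 5L,
                            n_local = 5000L, subset_bounds = c(1 / 3, 2 / 3),
                            seed = 1L) {
  if (!simulate && (is.null(elevation_path) || is.null(percent_path)))
    stop("either set simulate = TRUE or give elevation and percent paths",
         call. = FALSE)
  stopifnot(threshold >= 0, threshold <= 100,
            mosaic_bounds[1] >= 0, mosaic_bounds[2] <= 1,
            min_valid >= 0, min_valid <= 1)
  cfg <- list(out_dir = out_dir, elevation_path = elevation_path,
              percent_path = percent_path, mask_path = mask_path,
              simulate = simulate, sim_shape = as.integer(sim_shape),
              sim_amplitude = sim_amplitude, sim_exponent = sim_exponent,
              sim_coefficients = sim_coefficients,
              sim_noise_sd = sim_noise_sd, cell_size = cell_size,
              tile_size = as.integer(tile_size), threshold = threshold,
              mosaic_bounds = mosaic_bounds, min_valid = min_valid,
              radii = radii, n_trees = as.integer(n_trees),
              min_samples_leaf = as.integer(min_samples_leaf),
              max_depth = as.integer(max_depth),
              n_per_class = as.integer(n_per_class),
              n_local = as.integer(n_local),
              subset_bounds = subset_bounds, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all artefacts plus a JSON run
#' manifest into `config$out_dir`. The manifest lists the configuration,
#' per-stage counts (tiles per class, samples, skipped tiles) and an md5
#' content hash of every output file, so two runs under the same
#' configuration can be compared byte-for-byte. The manifest carries no
#' timestamps: identical configs yield identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`elevation`, `labels`, `table`, `regional`, `local`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outfile <- function(name) file.path(config$out_dir, name)

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    tspec <- terrain_spec(config$sim_shape, cell_size = config$cell_size,
                          spectral_exponent = config$sim_exponent,
                          amplitude = config$sim_amplitude,
                          seed = mix_seed(seed, 11L))
    elev <- generate_elevation(tspec)
    vspec <- vegetation_spec(coefficients = config$sim_coefficients,
                             noise_sd = config$sim_noise_sd,
                             seed = mix_seed(seed, 12L))
    veg <- generate_vegetation(elev, vspec)
    percent <- veg$percent
    write_raster(elev, outfile("elevation.asc"))
    write_raster(percent, outfile("percent_cover.asc"))
  } else {
    elev <- read_raster(config$elevation_path)
    percent <- read_raster(config$percent_path)
    if (!identical(dim(elev$values), dim(percent$values)))
      elev <- align_nearest(elev, percent)
    if (!is.null(config$mask_path)) {
      msk <- read_raster(config$mask_path)
      percent <- apply_mask(percent, msk)
      elev <- apply_mask(elev, msk)
    }
  }

  # --- features + classification -----------------------------------------
  features <- feature_stack(elev, radii = config$radii)
  labels <- classify_pixels(percent, config$threshold)
  write_raster(labels, outfile("labels.asc"))
  ltab <- landscape_table(labels, elev = elev,
                          tile_size = config$tile_size,
                          mosaic_bounds = config$mosaic_bounds,
                          min_valid = config$min_valid)
  utils::write.csv(ltab, outfile("landscape_table.csv"),
                   row.names = FALSE)

  # --- models -------------------------------------------------------------
  mcfg <- model_config(config$n_trees, config$min_samples_leaf,
                       config$max_depth, seed = mix_seed(seed, 13L))
  regional <- run_regional(labels, features, ltab, mcfg,
                           seed = mix_seed(seed, 14L),
                           n_per_class = config$n_per_class,
                           subset_bounds = config$subset_bounds)
  reg_out <- list(
    accuracy = regional$accuracy,
    importance = as.list(regional$importance),
    top_feature = regional$top_feature,
    directions = as.list(regional$directions),
    n_samples = regional$n_samples,
    subsets = lapply(regional$subsets, function(s)
      if (isTRUE(s$skipped)) list(skipped = TRUE, reason = s$reason)
      else list(skipped = FALSE, accuracy = s$accuracy,
                top_feature = s$top_feature,
                directions = as.list(s$directions)))
  )
  jsonlite::write_json(reg_out, outfile("regional_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ale_df <- do.call(rbind, lapply(regional$ale, as.data.frame))
  utils::write.csv(ale_df, outfile("regional_ale.csv"), row.names = FALSE)

  local <- run_local(labels, features, ltab, mcfg,
                     seed = mix_seed(seed, 15L), n_total = config$n_local)
  utils::write.csv(local, outfile("local_results.csv"), row.names = FALSE)
  jsonlite::write_json(attr(local, "summary"), outfile("local_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(hashes) <- files
  cfg_out <- unclass(config)[setdiff(names(config), "out_dir")]
  cfg_out$sim_coefficients <- as.list(cfg_out$sim_coefficients)
  manifest <- list(
    config = cfg_out,
    counts = list(
      tiles = as.list(base::table(ltab$landscape_class)),
      regional_samples = regional$n_samples,
      local_fitted = attr(local, "summary")$n_fitted,
      local_skipped = attr(local, "summary")$n_skipped
    ),
    files = hashes
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(elevation = elev, labels = labels, table = ltab,
                 regional = regional, local = local, manifest = manifest))
}

#' Write the small golden fixture grids
#'
#' Deterministic miniature rasters used by the oracle tests and examples:
#' a flat grid (TPI must be identically zero), an inclined plane with
#' known analytic slope and aspect, a single raised peak, and a bimodal
#' percent-cover grid — each with an expected-output companion where the
#' expectation is closed-form.
#'
#' @param dir Output directory.
#' @param seed Seed for the stochastic cover fixture.
#' @return Invisibly, the named list of written paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wr <- function(r, name) {
    p <- file.path(dir, name)
    write_raster(r, p)
    paths[[name]] <<- p
    p
  }
  n <- 12L
  flat <- mt_raster(matrix(100, n, n), cell_size = 30)
  wr(flat, "flat.csv")
  wr(tpi(flat, 90), "flat_expected_tpi.csv")
  # plane descending eastward at 0.1 m/m: slope atan(0.1), aspect east
  plane <- mt_raster(outer(rep(1, n), seq_len(n)) * -3, cell_size = 30)
  wr(plane, "plane.csv")
  wr(horn_slope(plane), "plane_expected_slope.csv")
  peak <- mt_raster(matrix(0, 9, 9), cell_size = 30)
  peak$values[5, 5] <- 10
  wr(peak, "peak.csv")
  cover <- with_seed(seed, {
    closed <- stats::runif(n * n) < 0.5
    v <- stats::rnorm(n * n, mean = ifelse(closed, 90, 20), sd = 5)
    mt_raster(matrix(pmin(pmax(v, 0), 100), n, n), cell_size = 30)
  })
  wr(cover, "cover_bimodal.csv")
  invisible(paths)
}
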