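#' Specification of a synthetic terrain field
#'
#' Parameters for spectral (Fourier) synthesis of a spatially
#' autocorrelated elevation field with a power-law spectrum
#' `P(k) ~ k^-spectral_exponent`. Larger exponents give smoother,
#' longer-range terrain; the field is rescaled so its sample standard
#' deviation equals `amplitude` exactly.
#'
#' @param shape Integer vector `(rows, cols)` in pixels.
#' @param cell_size Metres per pixel (default 30, matching ~1 arcsecond
#'   elevation products).
#' @param spectral_exponent Power-law slope of the spectrum (unitless;
#'   around 2-3 resembles natural topography).
#' @param amplitude Target standard deviation of elevation in metres
#'   (>= 0; 0 gives a flat grid).
#' @param seed Integer seed; identical specs produce identical grids.
#' @return An object of class `terrain_spec`.
#' @export
terrain_spec <- function(shape, cell_size = 30, spectral_exponent = 2.5,
                         amplitude = 15, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers (rows, cols)", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(shape = shape, cell_size = cell_size,
                 spectral_exponent = spectral_exponent,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "terrain_spec")
}

# Gaussian random field with power-law spectrum, unit variance (or zeros
# for a degenerate grid). Spectral synthesis: white noise filtered in the
# Fourier domain by k^(-exponent/2); periodic boundary artifacts are
# accepted since analyses are local.
grf_powerlaw <- function(nr, nc, exponent) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (nr * nc == 1L) return(white * 0)
  fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)] / nr
  fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)] / nc
  k <- sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
  filt <- matrix(0, nr, nc)
  filt[k > 0] <- k[k > 0]^(-exponent / 2)
  field <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(as.vector(field))
  if (!is.finite(s) || s == 0) return(field * 0)
  (field - mean(field)) / s
}

#' Generate a synthetic elevation raster
#'
#' @param spec A [terrain_spec()].
#' @return Elevation [mt_raster] with sample standard deviation equal to
#'   `spec$amplitude` and mean 0.
#' @export
generate_elevation <- function(spec) {
  if (!inherits(spec, "terrain_spec"))
    stop("`spec` must be a terrain_spec", call. = FALSE)
  field <- with_seed(spec$seed,
                     grf_powerlaw(spec$shape[1], spec$shape[2],
                                  spec$spectral_exponent))
  mt_raster(field * spec$amplitude, cell_size = spec$cell_size)
}

#' Specification of synthetic vegetation on a terrain
#'
#' The generative model for pixel cover state: each of the named
#' topographic features is standardized (z-scored over the grid), a logit
#' surface `eta = intercept + sum(coefficients * z-features) + noise` is
#' formed, and the closed-cover propensity is `plogis(eta)`. A pixel is
#' labelled closed where `eta > 0` (i.e. propensity > 0.5); exact ties are
#' broken by an independent fair coin. Stochasticity therefore enters only
#' through the logit noise field, whose standard deviation `noise_sd`
#' dials the achievable classification accuracy: `noise_sd = 0` makes
#' cover fully determined by topography. Percent tree cover is then drawn
#' from a two-component normal (mean `mode_open` or `mode_closed` by
#' label, sd `mode_sd`), clipped to `[0, 100]`, giving the bimodal cover
#' distribution characteristic of forest-savanna regions.
#'
#' @param coefficients Named numeric vector of logistic coefficients on
#'   standardized features; names must be among [TOPO_FEATURES].
#' @param intercept Unitless logit intercept.
#' @param noise_sd Standard deviation of the added logit noise (>= 0).
#' @param noise_correlation_length Spatial scale of the noise in pixels
#'   (0 or 1 = independent per pixel; larger values give patchy noise via
#'   box smoothing and re-standardization).
#' @param mode_open,mode_closed Percent tree cover of the savanna and
#'   forest modes (`0 <= mode_open < mode_closed <= 100`).
#' @param mode_sd Within-mode standard deviation in percent cover.
#' @param seed Integer seed.
#' @return An object of class `vegetation_spec`.
#' @export
vegetation_spec <- function(coefficients = c(TPI_500m = -2),
                            intercept = 0, noise_sd = 1,
                            noise_correlation_length = 5,
                            mode_open = 20, mode_closed = 90, mode_sd = 8,
                            seed = 1L) {
  if (length(coefficients) && is.null(names(coefficients)))
    stop("`coefficients` must be a named vector", call. = FALSE)
  bad <- setdiff(names(coefficients), TOPO_FEATURES)
  if (length(bad))
    stop(sprintf("unknown feature name(s): %s (must be among %s)",
                 paste(bad, collapse = ", "),
                 paste(TOPO_FEATURES, collapse = ", ")), call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!(mode_open >= 0 && mode_open < mode_closed && mode_closed <= 100))
    stop("need 0 <= mode_open < mode_closed <= 100", call. = FALSE)
  structure(list(coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd,
                 noise_correlation_length = noise_correlation_length,
                 mode_open = mode_open, mode_closed = mode_closed,
                 mode_sd = mode_sd, seed = as.integer(seed)),
            class = "vegetation_spec")
}

#' Generate synthetic vegetation from an elevation raster
#'
#' Applies the generative model documented in [vegetation_spec()] to the
#' topographic features derived from `elev`.
#'
#' @param elev Elevation [mt_raster] with finite values.
#' @param spec A [vegetation_spec()].
#' @return List with elements `labels` (0 = open, 1 = closed),
#'   `percent` (0-100 tree cover) and `propensity` (closed-cover
#'   probability surface), all [mt_raster]s on `elev`'s grid.
#' @export
generate_vegetation <- function(elev, spec) {
  stopifnot_raster(elev)
  if (!inherits(spec, "vegetation_spec"))
    stop("`spec` must be a vegetation_spec", call. = FALSE)
  if (any(!is.finite(elev$values)))
    stop("elevation must be finite everywhere", call. = FALSE)
  nr <- nrow(elev$values); nc <- ncol(elev$values)

  eta <- matrix(spec$intercept, nr, nc)
  if (length(spec$coefficients)) {
    radii <- as.numeric(sub("^TPI_([0-9.]+)m$", "\\1",
                            grep("^TPI_", names(spec$coefficients),
                                 value = TRUE)))
    feats <- feature_stack(elev, radii = if (length(radii)) radii else
      numeric(0))
    for (nm in names(spec$coefficients))
      eta <- eta + spec$coefficients[[nm]] * zscore_mat(feats[[nm]]$values)
  }

  res <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      cl <- spec$noise_correlation_length
      if (cl > 1) {
        noise <- box_mean(noise, as.integer(round((cl - 1) / 2)))
        noise <- zscore_mat(noise)
      }
      eta <- eta + spec$noise_sd * noise
    }
    lab <- matrix(0, nr, nc)
    lab[eta > 0] <- 1
    ties <- eta == 0
    if (any(ties))
      lab[ties] <- as.numeric(stats::runif(sum(ties)) < 0.5)
    pct <- matrix(stats::rnorm(nr * nc,
                               mean = ifelse(lab == 1, spec$mode_closed,
                                             spec$mode_open),
                               sd = spec$mode_sd), nr, nc)
    list(lab = lab, pct = pmin(pmax(pct, 0), 100), eta = eta)
  })

  list(labels = mt_raster(res$lab, elev$cell_size, elev$origin),
       percent = mt_raster(res$pct, elev$cell_size, elev$origin),
       propensity = mt_raster(stats::plogis(res$eta), elev$cell_size,
                              elev$origin))
}

#' Generate a topography-independent patchy cover field
#'
#' Null-model vegetation: a spatially patchy binary field produced by
#' thresholding an independent smoothed noise field at the empirical
#' quantile matching `closed_fraction_target`. By construction the labels
#' are statistically independent of any elevation raster, emulating a
#' landscape whose mosaic structure is maintained purely by internal
#' feedbacks rather than topography.
#'
#' @param shape Integer `(rows, cols)`.
#' @param patch_scale Characteristic patch size in pixels; 1 gives an
#'   independent (i.i.d.) field.
#' @param closed_fraction_target Desired closed fraction, in (0, 1).
#' @param seed Integer seed.
#' @param cell_size Metres per pixel for the returned raster.
#' @return Label [mt_raster] (0 = open, 1 = closed) whose realized closed
#'   fraction matches the target to within grid discreteness.
#' @export
generate_feedback_only <- function(shape, patch_scale = 1,
                                   closed_fraction_target = 0.5,
                                   seed = 1L, cell_size = 30) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers", call. = FALSE)
  if (!(closed_fraction_target > 0 && closed_fraction_target < 1))
    stop("`closed_fraction_target` must be in (0, 1)", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  lab <- with_seed(seed, {
    field <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (patch_scale > 1) {
      field <- box_mean(field, as.integer(round((patch_scale - 1) / 2)))
    }
    thr <- stats::quantile(field, probs = 1 - closed_fraction_target,
                           names = FALSE, type = 7)
    (field > thr) * 1
  })
  mt_raster(lab, cell_size = cell_size)
}
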