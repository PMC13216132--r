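#' First-order Accumulated Local Effects curve
#'
#' Quantifies how one feature changes the model's closed-cover
#' probability, free of the extrapolation bias of partial-dependence
#' curves on correlated features. The feature range is cut at empirical
#' quantiles into `n_bins` bins (duplicate quantile edges are merged and
#' their weights pooled). The local effect of bin *k* is the mean, over
#' the rows falling in that bin, of the prediction difference when the
#' feature is set to the bin's upper versus lower edge with all other
#' features held at the row's observed values. Local effects are
#' accumulated (cumulative sum) and centred by subtracting the
#' bin-count-weighted mean, so the curve reads as a deviation from the
#' average prediction.
#'
#' @param model A `cover_model`, or a function `data.frame -> probability`
#'   (see [predict_closed_prob()]).
#' @param data Non-empty data frame of observations containing `feature`.
#' @param feature Feature column name.
#' @param n_bins Target number of quantile bins (default 20).
#' @return Object of class `ale_curve`: list with `feature`, `edges`,
#'   `centers`, `ale` (centred effects, probability units), `weights`
#'   (rows per bin) and `degenerate` (flag: constant feature, curve of
#'   zeros).
#' @export
ale_curve <- function(model, data, feature, n_bins = 20L) {
  if (!nrow(data)) stop("`data` is empty", call. = FALSE)
  if (!feature %in% names(data))
    stop(sprintf("feature '%s' not present in data", feature), call. = FALSE)
  x <- data[[feature]]
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) {
    out <- structure(list(feature = feature, edges = c(edges, edges),
                          centers = edges, ale = 0,
                          weights = length(x), degenerate = TRUE),
                     class = "ale_curve")
    return(out)
  }
  K <- length(edges) - 1L
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  d_lo <- data; d_lo[[feature]] <- edges[bin]
  d_hi <- data; d_hi[[feature]] <- edges[bin + 1L]
  delta <- predict_closed_prob(model, d_hi) - predict_closed_prob(model, d_lo)
  w <- tabulate(bin, nbins = K)
  eff <- rep(0, K)
  means <- tapply(delta, factor(bin, levels = seq_len(K)), mean)
  eff[w > 0] <- means[w > 0]
  acc <- cumsum(eff)
  acc <- acc - sum(w * acc) / sum(w)
  structure(list(feature = feature, edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 ale = acc, weights = w, degenerate = FALSE),
            class = "ale_curve")
}

#' @export
print.ale_curve <- function(x, ...) {
  cat(sprintf("<ale_curve> %s: %d bins%s, range [%.4g, %.4g]\n",
              x$feature, length(x$ale),
              if (x$degenerate) " (degenerate)" else "",
              min(x$ale), max(x$ale)))
  invisible(x)
}

spearman_or_zero <- function(a, b) {
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    structure(0, degenerate = TRUE)
  } else {
    structure(stats::cor(a, b, method = "spearman"), degenerate = FALSE)
  }
}

#' Effect direction and monotonicity of an ALE curve
#'
#' Spearman rank correlation between the bin centres and the ALE values.
#' The sign gives the direction of the feature's effect on the likelihood
#' of closed cover (positive: higher feature values favour forest); the
#' magnitude reflects how monotonic the relationship is. Degenerate
#' curves (constant feature or flat curve) return 0 with a `degenerate`
#' attribute set.
#'
#' @param curve An [ale_curve()].
#' @return Correlation in `[-1, 1]` with attribute `degenerate`.
#' @export
effect_direction <- function(curve) {
  if (!inherits(curve, "ale_curve"))
    stop("`curve` must be an ale_curve", call. = FALSE)
  if (curve$degenerate) return(structure(0, degenerate = TRUE))
  spearman_or_zero(curve$centers, curve$ale)
}

#' Effect direction of the feature's absolute value
#'
#' Spearman correlation between `|bin centre|` and the ALE values;
#' detects symmetric V- or hat-shaped responses (e.g. closed cover
#' favoured at both strongly positive and strongly negative topographic
#' positions) that a signed direction averages away.
#'
#' @param curve An [ale_curve()].
#' @return Correlation in `[-1, 1]` with attribute `degenerate`.
#' @export
abs_effect_direction <- function(curve) {
  if (!inherits(curve, "ale_curve"))
    stop("`curve` must be an ale_curve", call. = FALSE)
  if (curve$degenerate) return(structure(0, degenerate = TRUE))
  spearman_or_zero(abs(curve$centers), curve$ale)
}

#' Serialize an ALE curve to a data frame
#'
#' @param x An [ale_curve()].
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return Data frame with columns `feature`, `edge_lo`, `edge_hi`,
#'   `center`, `ale`, `weight`.
#' @export
as.data.frame.ale_curve <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  K <- length(x$ale)
  data.frame(feature = x$feature,
             edge_lo = x$edges[seq_len(K)],
             edge_hi = x$edges[seq_len(K) + 1L],
             center = x$centers, ale = x$ale, weight = x$weights)
}
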