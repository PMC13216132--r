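# Independent brute-force oracles and tiny fixture builders. These are
# written from the operator definitions (literal per-pixel / per-row
# loops) and share no code with the package implementations.

# mirror reflection with edge repetition, folding until in range
oracle_reflect <- function(i, n) {
  if (n == 1L) return(1L)
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# TPI: value minus the mean of a centred square window (centre included),
# reflected edges, NAs dropped from the mean
oracle_tpi <- function(m, cell, radius) {
  w <- round(radius / cell)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rr <- vapply((r - w):(r + w), oracle_reflect, 1L, n = nr)
    for (c in seq_len(nc)) {
      if (is.na(m[r, c])) next
      cc <- vapply((c - w):(c + w), oracle_reflect, 1L, n = nc)
      out[r, c] <- m[r, c] - mean(m[rr, cc], na.rm = TRUE)
    }
  }
  out
}

# Horn 3x3 slope (degrees) and aspect components, clamped borders
oracle_slope_aspect <- function(m, cell) {
  nr <- nrow(m); nc <- ncol(m)
  clamp <- function(i, n) min(max(i, 1L), n)
  slope <- asin_ <- acos_ <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    z <- matrix(NA_real_, 3, 3)
    for (dr in -1:1) for (dc in -1:1)
      z[dr + 2, dc + 2] <- m[clamp(r + dr, nr), clamp(c + dc, nc)]
    if (any(is.na(z))) next
    gx <- ((z[1, 3] + 2 * z[2, 3] + z[3, 3]) -
             (z[1, 1] + 2 * z[2, 1] + z[3, 1])) / (8 * cell)
    gy <- ((z[1, 1] + 2 * z[1, 2] + z[1, 3]) -
             (z[3, 1] + 2 * z[3, 2] + z[3, 3])) / (8 * cell)
    g <- sqrt(gx^2 + gy^2)
    slope[r, c] <- atan(g) * 180 / pi
    if (g > 0) {
      asin_[r, c] <- -gx / g
      acos_[r, c] <- -gy / g
    } else {
      asin_[r, c] <- 0
      acos_[r, c] <- 0
    }
  }
  list(slope = slope, aspect_sin = asin_, aspect_cos = acos_)
}

# Definition-level first-order ALE: loop over bins and rows
oracle_ale <- function(predfun, data, feature, n_bins) {
  x <- data[[feature]]
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  K <- length(edges) - 1L
  assign_bin <- function(xi) min(max(sum(xi >= edges[-length(edges)]), 1L), K)
  bins <- vapply(x, assign_bin, 1L)
  eff <- numeric(K); w <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(bins == k)
    w[k] <- length(idx)
    if (!length(idx)) next
    d <- numeric(length(idx))
    for (j in seq_along(idx)) {
      row_hi <- data[idx[j], , drop = FALSE]; row_hi[[feature]] <- edges[k + 1]
      row_lo <- data[idx[j], , drop = FALSE]; row_lo[[feature]] <- edges[k]
      d[j] <- predfun(row_hi) - predfun(row_lo)
    }
    eff[k] <- mean(d)
  }
  acc <- numeric(K)
  s <- 0
  for (k in seq_len(K)) { s <- s + eff[k]; acc[k] <- s }
  acc - sum(w * acc) / sum(w)
}

# balanced two-class sample set with given feature matrix and labels
make_samples <- function(feats, labels01) {
  df <- as.data.frame(feats)
  df$label <- factor(ifelse(labels01 == 1, "closed", "open"),
                     levels = c("open", "closed"))
  df$tile_id <- 1L
  df$row <- seq_len(nrow(df)); df$col <- 1L
  df
}

# six-feature random sample set with labels driven by one feature
make_driver_samples <- function(n, driver = "TPI_500m", coef = -5,
                                noise = 0, seed = 1) {
  set.seed(seed)
  feats <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, mosaictopo::TOPO_FEATURES))
  eta <- coef * feats[, driver] + rnorm(n, sd = noise)
  make_samples(feats, as.numeric(eta > 0))
}
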