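# Internal numeric helpers shared across modules.

# Evaluate `expr` under a temporary RNG state; the caller's stream is
# untouched. All exported stochastic functions route through this so that a
# recorded seed fully determines their output.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic per-tile substream: mixes a master seed with a tile id so
# each tile's draw is reproducible independently of iteration order.
# Kept below 2^31 - 1.
mix_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + as.double(k) * 16807 + 1) %%
               2147483647)
}

# Mirror-reflect an out-of-range index into 1..n with edge repetition
# (scipy uniform_filter 'reflect': d c b a | a b c d | d c b a), folding as
# many times as needed so windows wider than the grid remain defined.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period          # 0-based within one mirror period
  j <- ifelse(j < 0, j + period, j)
  ifelse(j < n, j + 1L, period - j)
}

# Mean over a centred square window of half-width w (side 2w+1) at every
# cell, mirror-reflected edges, NA cells excluded from the mean. O(N) via a
# summed-area table on the reflect-padded grid.
box_mean <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  if (w == 0L) return(m)
  ri <- reflect_index((1L - w):(nr + w), nr)
  ci <- reflect_index((1L - w):(nc + w), nc)
  p <- m[ri, ci, drop = FALSE]
  valid <- !is.na(p)
  p[!valid] <- 0
  S <- sat(p)
  C <- sat(valid * 1)
  side <- 2L * w + 1L
  sums <- win_sum(S, nr, nc, side)
  cnts <- win_sum(C, nr, nc, side)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out[is.na(m)] <- NA_real_
  out
}

# Summed-area table with a zero guard row/column.
sat <- function(m) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  S
}

# Window sums of side `side` over a padded SAT, for an unpadded nr x nc grid.
win_sum <- function(S, nr, nc, side) {
  S[(side + 1L):(nr + side), (side + 1L):(nc + side), drop = FALSE] -
    S[1L:nr, (side + 1L):(nc + side), drop = FALSE] -
    S[(side + 1L):(nr + side), 1L:nc, drop = FALSE] +
    S[1L:nr, 1L:nc, drop = FALSE]
}

# Standardize a matrix over its valid cells; a constant field maps to zeros.
zscore_mat <- function(m) {
  mu <- mean(m, na.rm = TRUE)
  sd_ <- stats::sd(as.vector(m), na.rm = TRUE)
  if (!is.finite(sd_) || sd_ == 0) {
    z <- m * 0
  } else {
    z <- (m - mu) / sd_
  }
  z
}
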