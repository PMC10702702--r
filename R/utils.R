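# Internal helpers shared across modules.

# dB floor used for plotting and ratio computations
VOX_DB_FLOOR <- -100

vox_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "vox_error", "error", "condition")))
}

vox_io_error <- function(msg) vox_error(msg, "vox_io_error")
vox_duration_error <- function(msg) vox_error(msg, "vox_duration_error")
vox_validation_error <- function(msg) vox_error(msg, "vox_validation_error")
vox_config_error <- function(msg) vox_error(msg, "vox_config_error")

hann_window <- function(n) {
  if (n <= 1) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

gaussian_window <- function(n, sigma_frac = 1 / 6) {
  if (n <= 1) return(rep(1, n))
  c <- (n - 1) / 2
  exp(-0.5 * ((0:(n - 1) - c) / (sigma_frac * n))^2)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# centered moving average with edge replication, length preserved
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  h <- k %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}

# moving average along rows (margin = 1) or columns (margin = 2) of a matrix,
# edge rows/cols replicated so the output has the same dimensions
moving_average_mat <- function(m, k, margin) {
  k <- as.integer(k)
  if (k <= 1L) return(m)
  h <- k %/% 2L
  if (margin == 2L) m <- t(m)
  n <- nrow(m)
  mp <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(n, h), , drop = FALSE])
  sm <- stats::filter(mp, rep(1 / k, k), sides = 2)
  sm <- matrix(as.numeric(sm), nrow = nrow(mp))[(h + 1L):(h + n), , drop = FALSE]
  if (margin == 2L) sm <- t(sm)
  sm
}

# power -> dB relative to reference, clamped at the package dB floor
power_db <- function(p, ref = 1) {
  db <- 10 * log10(pmax(p / ref, 0))
  pmax(db, VOX_DB_FLOOR)
}

# run-length voiced runs: returns data.frame(start, end) of frame indices
voiced_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# evaluate synthesis/test code under a temporary seeded RNG, restoring state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
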