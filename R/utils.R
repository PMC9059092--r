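# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Fractional part mapped to [0, 1).
frac <- function(x) x - floor(x)

# Circular difference in cycles, mapped to [-0.5, 0.5).
circ_diff <- function(a, b) {
  d <- frac(a - b)
  ifelse(d >= 0.5, d - 1, d)
}

# Root-mean-square circular error in cycles.
circ_rmse <- function(a, b) sqrt(mean(circ_diff(a, b)^2))

# Flatten a 4D array [x, y, z, t] to a voxel-by-frame matrix.
as_voxel_matrix <- function(arr) {
  d <- dim(arr)
  stopifnot(length(d) == 4L)
  matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
}

# Inverse of as_voxel_matrix for per-voxel vectors/matrices.
as_grid_array <- function(x, grid) {
  if (is.matrix(x)) array(x, dim = c(grid, ncol(x))) else array(x, dim = grid)
}

# Simple local-maximum finder: indices i with x[i] strictly greater than the
# closest distinct neighbours, separated by at least min_dist samples.
find_peaks <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

# Sub-sample refinement of a peak location by quadratic interpolation through
# the three samples around index i; returns list(offset in samples, value).
refine_peak <- function(x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(list(offset = 0, value = x[i]))
  y1 <- x[i - 1L]; y2 <- x[i]; y3 <- x[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps * max(1, abs(y2))) {
    return(list(offset = 0, value = x[i]))
  }
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  val <- y2 - 0.25 * (y1 - y3) * delta
  list(offset = delta, value = val)
}

# Dominant periodogram frequency of a demeaned series within [f_lo, f_hi].
# Returns NULL when no bin exceeds `snr` times the median periodogram power.
dominant_frequency <- function(x, fs, f_lo, f_hi, snr = 5) {
  x <- x - mean(x)
  n <- length(x)
  if (stats::sd(x) == 0) return(NULL)
  nfft <- 8L * 2L^ceiling(log2(n))  # zero-padding for a fine frequency grid
  p <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  f <- (seq_len(nfft) - 1L) * fs / nfft
  half <- f <= fs / 2
  p <- p[half]; f <- f[half]
  band <- f >= f_lo & f <= f_hi
  if (!any(band)) return(NULL)
  floor_p <- stats::median(p[f > 0])
  i <- which(band)[which.max(p[band])]
  if (p[i] < snr * floor_p) return(NULL)
  f[i]
}

# Arithmetic mean over finite values; errors on empty input.
mean_finite <- function(x, what = "values") {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite ", what, " to summarize")
  mean(x)
}
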