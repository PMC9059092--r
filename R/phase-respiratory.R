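#' Estimate per-frame respiratory phase from the parenchymal mean signal
#'
#' Analyzes the spatially averaged lung signal with a cosine model to assign
#' each frame a respiratory phase in \[0, 1). Phase 0 is anchored at
#' end-expiration, where the parenchymal signal is maximal (lung signal is
#' inversely related to inflation). Expiratory peaks are detected on the
#' smoothed parenchymal mean; within each breath the signal is normalized to
#' its refined extrema and the phase is the normalized angular position of
#' the cosine model, \eqn{\phi = \arccos(2u - 1)/2\pi} on the
#' expiration-to-inspiration half and its mirror on the way back. This
#' honors variable breath lengths and gives sub-frame temporal resolution.
#'
#' @param series a [dynamic_series()]; normally the low-pass-filtered
#'   ventilation branch. Must contain at least 3 full respiratory cycles.
#' @return A `phase_assignment`: data frame with columns `frame`, `time`,
#'   `phase`, `cycle_index`, and attributes `rate_estimate` (Hz) and
#'   `n_cycles`.
#' @export
estimate_respiratory_phase <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  x <- mask_mean_signal(series, series$parenchyma_mask)
  t <- series$frame_times
  fs <- series_fs(series)

  f0 <- dominant_frequency(x, fs, 0.1, 0.5)
  if (is.null(f0)) stop("no respiratory signal detected in the 0.1-0.5 Hz band")
  span <- t[length(t)] - t[1]
  if (f0 * span < 3) stop("series must contain at least 3 full respiratory cycles")

  # light smoothing (~1/6 period) before peak picking
  k <- max(1L, round(fs / f0 / 6))
  xs <- stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  xs[is.na(xs)] <- x[is.na(xs)]
  min_dist <- max(2L, floor(0.6 * fs / f0))
  pk <- find_peaks(as.numeric(xs), min_dist = min_dist)
  if (length(pk) < 2L) stop("no respiratory signal detected: fewer than 2 breaths")

  # refine peak (end-expiration) times and values on the unsmoothed signal
  pk_t <- pk_v <- numeric(length(pk))
  for (i in seq_along(pk)) {
    r <- refine_peak(x, pk[i])
    pk_t[i] <- t[pk[i]] + r$offset / fs
    pk_v[i] <- r$value
  }
  rate <- 1 / mean(diff(pk_t))

  phase <- numeric(length(t))
  cycle <- integer(length(t))
  breaks <- c(-Inf, pk_t, Inf)
  for (b in seq_len(length(pk_t) + 1L)) {
    idx <- which(t >= breaks[b] & t < breaks[b + 1L])
    if (!length(idx)) next
    if (b == 1L) {                      # before the first detected peak
      phase[idx] <- frac((t[idx] - pk_t[1]) * rate)
      cycle[idx] <- 0L
    } else if (b == length(pk_t) + 1L) { # after the last detected peak
      phase[idx] <- frac((t[idx] - pk_t[length(pk_t)]) * rate)
      cycle[idx] <- length(pk_t)
    } else {
      t0 <- pk_t[b - 1L]; t1 <- pk_t[b]
      seg <- x[idx]
      hi <- max(pk_v[b - 1L], pk_v[b])
      tr <- refine_trough(x, t, idx)
      u <- (seg - tr) / max(hi - tr, .Machine$double.eps)
      u <- pmin(1, pmax(0, u))
      ang <- acos(2 * u - 1) / (2 * pi)  # in [0, 0.5]
      tmin <- attr(tr, "time")
      descending <- t[idx] <= tmin
      phase[idx] <- ifelse(descending, ang, 1 - ang)
      cycle[idx] <- b - 1L
    }
  }

  new_phase_assignment(seq_along(t), t, phase, cycle, rate)
}

# Refined minimum value of x over index window idx; its time as attribute.
refine_trough <- function(x, t, idx) {
  j <- idx[which.min(x[idx])]
  r <- refine_peak(-x, j)
  out <- -r$value
  attr(out, "time") <- t[j] + r$offset * mean(diff(t))
  out
}

new_phase_assignment <- function(frame, time, phase, cycle_index, rate) {
  out <- data.frame(frame = frame, time = time, phase = phase,
                    cycle_index = cycle_index)
  attr(out, "rate_estimate") <- rate
  attr(out, "n_cycles") <- length(unique(cycle_index))
  class(out) <- c("phase_assignment", "data.frame")
  out
}

#' Estimated cycle rate of a phase assignment
#' @param phases a `phase_assignment`.
#' @return rate in Hz.
#' @export
phase_rate <- function(phases) attr(phases, "rate_estimate")
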