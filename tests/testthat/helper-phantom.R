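# Shared fixtures, built in code at test time.

# Desk-scale single-section phantom spec.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 1L), ...)
}

# A dynamic series whose every voxel carries the same time course x;
# whole grid is parenchyma, vessel empty.
series_from_signal <- function(x, dt = 0.288) {
  grid <- c(2L, 2L, 1L)
  arr <- array(rep(x, each = prod(grid)), dim = c(grid, length(x)))
  dynamic_series(arr, (seq_along(x) - 1) * dt,
                 parenchyma_mask = array(TRUE, grid),
                 vessel_mask = array(FALSE, grid))
}

# A series with a parenchymal time course xp and a vessel time course xv.
series_with_vessel <- function(xp, xv, dt = 0.288) {
  grid <- c(2L, 2L, 1L)
  n <- length(xp)
  arr <- array(0, dim = c(grid, n))
  arr[1, , 1, ] <- rep(xp, each = 2)
  arr[2, , 1, ] <- rep(xv, each = 2)
  par <- array(FALSE, grid); par[1, , 1] <- TRUE
  ves <- array(FALSE, grid); ves[2, , 1] <- TRUE
  dynamic_series(arr, (seq_len(n) - 1) * dt, par, ves)
}

# Least-squares amplitude of the component at frequency f (independent
# spectral amplitude oracle).
fit_amplitude <- function(x, t, f) {
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# Total sinusoidal power (amplitude^2 / 2) of x at the given frequencies,
# each estimated by least squares.
band_variance <- function(x, t, freqs) {
  sum(vapply(freqs, function(f) fit_amplitude(x, t, f)^2 / 2, numeric(1)))
}

# Brute-force linearly interpolated quantile (sort-based oracle).
brute_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Circular RMS phase error in cycles.
circular_rmse <- function(a, b) {
  d <- (a - b) %% 1
  d <- ifelse(d >= 0.5, d - 1, d)
  sqrt(mean(d^2))
}

# Build a phase assignment directly (bypassing estimation) for sorting
# tests.
phases_from <- function(phase, time = seq_along(phase) * 0.288, rate = 0.3) {
  prefulr:::new_phase_assignment(seq_along(phase), time, phase,
                                 cycle_index = floor(seq_along(phase) / 10),
                                 rate = rate)
}

# Binary defect_label_map from a logical vector laid out on a 1-section
# grid (for match/VQM oracle tests).
label_map_from <- function(defect, metric = "RVent", threshold = 0.075) {
  n <- length(defect)
  side <- ceiling(sqrt(n))
  grid <- c(side, side, 1L)
  map <- array(NA_real_, grid)
  mask <- array(FALSE, grid)
  mask[seq_len(n)] <- TRUE
  map[seq_len(n)] <- ifelse(defect, threshold - 0.01, threshold + 0.01)
  threshold_map(map, threshold, metric, mask)
}
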