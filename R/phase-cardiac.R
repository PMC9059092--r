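#' Estimate per-frame cardiac phase from the large-vessel signal
#'
#' Assigns each frame a cardiac phase in \[0, 1) by analyzing the average
#' signal time series within the large-vessel segmentation. The vessel mean
#' is high-pass filtered, the heart rate is located as the dominant spectral
#' peak above 0.5 Hz and refined by a sinusoid regression (the rate
#' maximizing the fitted sine's R^2), and beats are segmented at the fitted
#' oscillation's cycle boundaries. Where a beat segment contains enough
#' samples (>= 5), a bounded per-segment sine re-fit adjusts the local phase
#' offset, accommodating heart-rate drift. Phase 0.25 is anchored at the
#' vessel pulsatility maximum (peak systolic inflow).
#'
#' At 288 ms sampling a 1 Hz beat holds only ~3.5 samples, so individual
#' beats cannot be fitted independently; the shared-rate sinusoid model is
#' what makes retrospective cardiac gating possible at this frame rate.
#'
#' @param series a [dynamic_series()]; normally the high-pass-filtered
#'   perfusion branch. The vessel mask must be non-empty and the series must
#'   contain at least 10 beats.
#' @param highpass_hz cutoff used to detrend the vessel mean before rate
#'   estimation (set to `NULL` to skip).
#' @return A `phase_assignment` (see [estimate_respiratory_phase()]); its
#'   `rate_estimate` attribute is in Hz, and `heart_rate` gives beats/min.
#' @export
estimate_cardiac_phase <- function(series, highpass_hz = 0.8) {
  stopifnot(inherits(series, "dynamic_series"))
  if (!any(series$vessel_mask)) {
    stop("vessel mask is empty: cardiac phase cannot be estimated")
  }
  x <- mask_mean_signal(series, series$vessel_mask)
  t <- series$frame_times
  fs <- series_fs(series)
  if (!is.null(highpass_hz) && highpass_hz < fs / 2) {
    x <- as.numeric(fft_filter_matrix(matrix(x, ncol = 1), fs,
                                      highpass_hz, 0.15, "high"))
  }

  f0 <- dominant_frequency(x, fs, 0.5, fs / 2 * 0.999)
  if (is.null(f0)) stop("no cardiac signal detected in the vessel region")

  # refine rate and phase by maximizing sinusoid-regression R^2
  span <- t[length(t)] - t[1]
  fgrid <- seq(max(0.5, f0 - 1.5 / span), min(fs / 2 * 0.999, f0 + 1.5 / span),
               length.out = 121L)
  fits <- vapply(fgrid, function(f) sine_fit_r2(x, t, f), numeric(1))
  fhat <- fgrid[which.max(fits)]
  co <- sine_fit(x, t, fhat)
  # fitted signal a*sin + b*cos = R*sin(2*pi*f*t + delta); its maximum sits
  # at 2*pi*f*t + delta = pi/2, which we anchor to phase 0.25
  delta <- atan2(co["cos"], co["sin"])
  phase <- frac(fhat * t + delta / (2 * pi))
  cycle <- floor(fhat * t + delta / (2 * pi))
  cycle <- as.integer(cycle - min(cycle))

  n_beats <- floor(fhat * span)
  if (n_beats < 10) {
    stop(sprintf("fewer than 10 beats detected (%d); series too short for cardiac gating",
                 n_beats))
  }

  # bounded per-beat refinement where sampling allows
  for (b in unique(cycle)) {
    idx <- which(cycle == b)
    if (length(idx) < 5L) next
    obj <- function(d) {
      ph <- phase[idx] + d
      fit <- stats::lm.fit(cbind(1, sin(2 * pi * ph), cos(2 * pi * ph)),
                           x[idx])
      sum(fit$residuals^2)
    }
    d <- stats::optimize(obj, c(-0.1, 0.1))$minimum
    phase[idx] <- frac(phase[idx] + d)
  }

  out <- new_phase_assignment(seq_along(t), t, phase, cycle, fhat)
  attr(out, "heart_rate") <- fhat * 60
  out
}

#' Mean heart rate of a cardiac phase assignment
#' @param phases a `phase_assignment` from [estimate_cardiac_phase()].
#' @return heart rate in beats/min.
#' @export
heart_rate <- function(phases) attr(phases, "heart_rate")

sine_fit <- function(x, t, f) {
  X <- cbind(sin = sin(2 * pi * f * t), cos = cos(2 * pi * f * t))
  fit <- stats::lm.fit(cbind(1, X), x)
  c(sin = unname(fit$coefficients[2]), cos = unname(fit$coefficients[3]))
}

sine_fit_r2 <- function(x, t, f) {
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  fit <- stats::lm.fit(X, x)
  1 - sum(fit$residuals^2) / sum((x - mean(x))^2)
}
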