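#' Zero-phase temporal filtering of a dynamic series
#'
#' Voxelwise frequency-domain filters separating the respiratory and cardiac
#' signal components of a free-breathing acquisition.
#' `lowpass_ventilation()` removes cardiac (perfusion) signal variations
#' above its cutoff; `highpass_perfusion()` removes respiratory variations
#' below its cutoff.
#'
#' The filter is applied in the frequency domain on an even (mirror)
#' extension of each voxel time course, with a real, symmetric transfer
#' function — hence exactly zero-phase, so later phase sorting is not biased
#' by group delay. The transfer function is 1 in the passband, 0 in the
#' stopband, with a raised-cosine taper of half-width `transition_hz` around
#' the cutoff (gain 0.5 at the cutoff itself). With the defaults, components
#' at or below 0.4 Hz pass the 0.6 Hz low-pass unattenuated and components
#' at or above 1 Hz are removed, and conversely for the 0.8 Hz high-pass.
#'
#' @param series a [dynamic_series()] with uniform sampling.
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param transition_hz half-width of the raised-cosine transition band (Hz).
#' @return A filtered [dynamic_series()] with the same grid, times and masks.
#' @name temporal_filters
NULL

#' @rdname temporal_filters
#' @export
lowpass_ventilation <- function(series, cutoff = 0.6, transition_hz = 0.15) {
  filter_series(series, cutoff, transition_hz, type = "low")
}

#' @rdname temporal_filters
#' @export
highpass_perfusion <- function(series, cutoff = 0.8, transition_hz = 0.15) {
  filter_series(series, cutoff, transition_hz, type = "high")
}

filter_series <- function(series, cutoff, transition_hz, type) {
  stopifnot(inherits(series, "dynamic_series"))
  fs <- series_fs(series)
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff %.3f Hz must be below the Nyquist frequency %.3f Hz",
                 cutoff, fs / 2))
  }
  X <- t(as_voxel_matrix(series$signal))  # frames x voxels
  Y <- fft_filter_matrix(X, fs, cutoff, transition_hz, type)
  out <- series
  out$signal <- array(t(Y), dim = dim(series$signal))
  out
}

# Frequency response: raised-cosine taper from 1 to 0 over
# [cutoff - w, cutoff + w]; `high` is its complement.
filter_response <- function(f, cutoff, w, type) {
  lo <- cutoff - w
  h <- ifelse(f <= lo, 1,
              ifelse(f >= cutoff + w, 0,
                     0.5 * (1 + cos(pi * (f - lo) / (2 * w)))))
  if (type == "high") 1 - h else h
}

# Zero-phase FFT filter on columns of X (frames x series), using an even
# extension to suppress boundary wrap-around artifacts.
fft_filter_matrix <- function(X, fs, cutoff, w, type) {
  n <- nrow(X)
  Xe <- rbind(X, X[n:1, , drop = FALSE])
  N <- 2L * n
  k <- 0:(N - 1)
  f <- pmin(k, N - k) * fs / N
  H <- filter_response(f, cutoff, w, type)
  Y <- stats::mvfft(stats::mvfft(Xe) * H, inverse = TRUE)
  Re(Y[seq_len(n), , drop = FALSE]) / N
}
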