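#' Quantify pulmonary perfusion in mL/min/100 mL
#'
#' Converts the cardiac-sorted signal pulsatility of each voxel into a
#' perfusion estimate normalized to the full-blood signal and scaled by the
#' heart rate:
#' \deqn{Q = \frac{A_Q}{S_b} \cdot HR \cdot 100}
#' where \eqn{A_Q} is the voxel's cycle amplitude (peak-to-peak over the 30
#' phases, or the peak-to-peak of the first harmonic with
#' `amplitude_mode = "first_harmonic"`), \eqn{S_b} the full-blood signal —
#' a high percentile of the vessel-region mean over its sorted cardiac
#' cycle, a robust proxy for a fully blood-filled voxel — and HR the mean
#' heart rate in beats/min.
#'
#' @param cardiac_cycle a `phase_cycle` from the perfusion (high-pass)
#'   branch.
#' @param vessel_cycle numeric vector: the vessel-region mean of the
#'   *unfiltered* signal sorted onto the cardiac phase grid (signal units).
#' @param hr heart rate in beats/min; must lie in \[30, 180\].
#' @param mask logical array of voxels to quantify (default: parenchyma).
#' @param blood_ref_percentile percentile of `vessel_cycle` used as
#'   \eqn{S_b}.
#' @param amplitude_mode `"ptp"` (raw peak-to-peak) or `"first_harmonic"`.
#' @return A `perfusion_result`: `q_map` (grid array, NA outside mask),
#'   `amplitude_map`, `blood_reference`, `heart_rate`.
#' @export
quantify_perfusion <- function(cardiac_cycle, vessel_cycle, hr,
                               mask = cardiac_cycle$parenchyma_mask,
                               blood_ref_percentile = 95,
                               amplitude_mode = c("ptp", "first_harmonic")) {
  stopifnot(inherits(cardiac_cycle, "phase_cycle"))
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.numeric(vessel_cycle) || !any(is.finite(vessel_cycle)) ||
      stats::sd(vessel_cycle) == 0) {
    stop("vessel cycle is degenerate; cannot derive a blood reference")
  }
  if (!is.finite(hr) || hr < 30 || hr > 180) {
    stop(sprintf("heart rate %.1f beats/min outside the plausible range [30, 180]", hr))
  }
  s_b <- stats::quantile(vessel_cycle, blood_ref_percentile / 100, names = FALSE)
  if (s_b <= 0) stop("blood reference signal is non-positive")

  M <- cycle_matrix(cardiac_cycle, mask)
  a_q <- switch(amplitude_mode,
    ptp = apply(M, 1L, max) - apply(M, 1L, min),
    first_harmonic = first_harmonic_ptp(M)
  )
  grid <- dim(cardiac_cycle$values)[1:3]
  q_map <- array(NA_real_, dim = grid)
  amp_map <- array(NA_real_, dim = grid)
  q_map[as.vector(mask)] <- a_q / s_b * hr * 100
  amp_map[as.vector(mask)] <- a_q

  structure(list(q_map = q_map, amplitude_map = amp_map,
                 blood_reference = s_b, heart_rate = hr,
                 mask = mask),
            class = "perfusion_result")
}

# Peak-to-peak of the first Fourier harmonic of each row.
first_harmonic_ptp <- function(M) {
  n <- ncol(M)
  k <- seq_len(n) - 1
  basis <- exp(-2i * pi * k / n)
  c1 <- as.complex(M %*% basis) / n
  4 * Mod(c1)  # amplitude 2|c1|, peak-to-peak twice that
}

#' Summary statistics of a perfusion map
#'
#' Arithmetic mean and quartile coefficient of dispersion of Q over the
#' unflagged voxels of a mask.
#'
#' @param q_map grid array of perfusion values (or a `perfusion_result`).
#' @param mask logical array; defaults to the result's mask.
#' @return list with `mean_q` and `qcd_q`.
#' @export
perfusion_summary <- function(q_map, mask = NULL) {
  if (inherits(q_map, "perfusion_result")) {
    if (is.null(mask)) mask <- q_map$mask
    q_map <- q_map$q_map
  }
  if (is.null(mask) || !any(mask)) stop("mask is empty")
  vals <- q_map[mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid perfusion values in mask")
  list(mean_q = mean(vals), qcd_q = qcd(vals))
}
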