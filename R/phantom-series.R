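#' Generate a synthetic dynamic lung MRI series with ground truth
#'
#' Evaluates the phantom signal model of [phantom_spec()] on its frame grid
#' and returns the registered series together with the generating ground
#' truth. The output is deterministic given `spec$seed`.
#'
#' Ground truth reports the fractional ventilation map, the perfusion map
#' `Q = A * HR * 100` (mL/min/100 mL, with `A` the cardiac amplitude as a
#' fraction of the full-blood signal and HR in beats/min), the respiratory
#' phase-lag map, the generating per-frame respiratory and cardiac phases,
#' and the three defect region masks (reduced-FV, phase-lag, reduced
#' perfusion).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `series` (a [dynamic_series()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_frames <- n_phantom_frames(spec)
  t <- (seq_len(n_frames) - 1) * spec$frame_interval
  grid <- spec$grid_shape
  nvox <- prod(grid)

  phi_r <- frac(spec$resp_rate * t)
  phi_c <- frac(spec$cardiac_rate * t)
  qc <- cardiac_waveform(phi_c)

  fv <- as.vector(spec$fv_map)
  lag <- as.vector(spec$phase_lag_map)
  s0 <- as.vector(spec$baseline_map)
  amp <- as.vector(spec$perf_amp_map)
  par_v <- as.vector(spec$parenchyma_mask)
  ves_v <- as.vector(spec$vessel_mask)

  # cardiac multiplier giving peak-to-peak amplitude A * S_b in signal units
  amult <- ifelse(s0 > 0, amp * spec$s_b / s0, 0)

  # frames x voxels; phase lag shifts the respiratory waveform per voxel
  V <- resp_waveform(outer(phi_r, lag, "-"), duty = spec$duty)
  X <- (1 - sweep(V, 2L, fv, "*"))
  X <- sweep(X, 2L, s0, "*")
  X <- X * (1 + outer(qc, amult))
  if (any(ves_v)) {
    vessel_tc <- spec$s_b * (1 - spec$vessel_pulsatility * (1 - qc))
    X[, ves_v] <- matrix(vessel_tc, n_frames, sum(ves_v))
  }
  if (spec$noise_sd > 0) {
    X <- X + withr::with_seed(spec$seed,
      matrix(stats::rnorm(n_frames * nvox, sd = spec$noise_sd),
             n_frames, nvox))
  }

  series <- dynamic_series(
    signal = array(t(X), dim = c(grid, n_frames)),
    frame_times = t,
    parenchyma_mask = spec$parenchyma_mask,
    vessel_mask = spec$vessel_mask
  )

  hr <- spec$cardiac_rate * 60
  q_map <- array(NA_real_, dim = grid)
  q_map[spec$parenchyma_mask] <- spec$perf_amp_map[spec$parenchyma_mask] * hr * 100
  fv_truth <- array(NA_real_, dim = grid)
  fv_truth[spec$parenchyma_mask] <- spec$fv_map[spec$parenchyma_mask]

  truth <- structure(list(
    fv_map = fv_truth,
    q_map = q_map,
    phase_lag_map = spec$phase_lag_map,
    vent_defect_labels = spec$vent_defect_mask,
    lag_defect_labels = spec$lag_defect_mask,
    perf_defect_labels = spec$perf_defect_mask,
    resp_phase = phi_r,
    cardiac_phase = phi_c,
    heart_rate = hr,
    spec = spec
  ), class = "phantom_truth")

  list(series = series, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  cat(sprintf("  FV in [%.3f, %.3f]; Q in [%.0f, %.0f] mL/min/100 mL; HR %.0f bpm\n",
              min(x$fv_map, na.rm = TRUE), max(x$fv_map, na.rm = TRUE),
              min(x$q_map, na.rm = TRUE), max(x$q_map, na.rm = TRUE),
              x$heart_rate))
  cat(sprintf("  defect voxels: vent %d, lag %d, perfusion %d\n",
              sum(x$vent_defect_labels), sum(x$lag_defect_labels),
              sum(x$perf_defect_labels)))
  invisible(x)
}
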