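#' Specification of a synthetic free-breathing lung MRI phantom
#'
#' Defines the geometry, physiology and noise of a registered 2D+time lung
#' phantom: a parenchymal signal inversely modulated by regional inflation, a
#' cardiac pulsatility component, a high-signal large-vessel region, and
#' spatially structured ventilation/perfusion defects.
#'
#' The parenchymal signal model is
#' \deqn{S(x,t) = S_0(x)\,[1 - FV(x)\,v(\phi_r(t) - lag(x))]\,
#'               [1 + A'(x)\,q(\phi_c(t))] + \epsilon(t)}
#' where \eqn{v} is a raised-cosine respiratory waveform rising 0 to 1 from
#' end-expiration to end-inspiration, \eqn{q} a half-rectified-sine cardiac
#' pulsatility waveform in \eqn{[0,1]}, and
#' \eqn{A'(x) = A(x) S_b / S_0(x)} so that the cardiac peak-to-peak amplitude
#' in signal units is \eqn{A(x) S_b}. Vessel voxels carry
#' \eqn{S_b (1 - c (1 - q(\phi_c)))} with pulsatility fraction \eqn{c}.
#'
#' Default defect construction: one region of reduced fractional ventilation
#' (a static-RVent defect), one region with a respiratory phase lag (degrades
#' the flow-volume-loop correlation but not static RVent), and one region of
#' reduced cardiac amplitude (a perfusion defect).
#'
#' @param grid_shape integer vector (nx, ny, n_sections).
#' @param frame_interval frame spacing in seconds.
#' @param duration acquisition duration per section in seconds.
#' @param resp_rate respiratory rate in Hz.
#' @param cardiac_rate cardiac rate in Hz; must be below the sampling Nyquist
#'   limit `1/(2*frame_interval)`.
#' @param s0 parenchymal baseline signal (arbitrary units).
#' @param s_b full-blood vessel signal level (arbitrary units).
#' @param fv_base,fv_range fractional ventilation: base value and half-range
#'   of a smooth linear gradient across the grid (unitless, in \[0, 1)).
#' @param perf_amp,perf_amp_range cardiac peak-to-peak amplitude as a
#'   fraction of `s_b`: base value and relative half-range of a smooth
#'   gradient. The ground-truth perfusion is `perf_amp * HR * 100`
#'   mL/min/100 mL with HR in beats/min.
#' @param fv_defect fractional ventilation inside the ventilation defect.
#' @param perf_amp_defect cardiac amplitude fraction inside the perfusion
#'   defect.
#' @param phase_lag respiratory phase lag (cycle fractions) inside the
#'   lag-defect region.
#' @param include_defects logical; set `FALSE` for a homogeneous lag-free
#'   phantom.
#' @param vessel_pulsatility fraction of the vessel signal that pulses with
#'   the cardiac waveform.
#' @param duty fraction of the respiratory cycle spent going from
#'   end-expiration to end-inspiration (0.5 = symmetric breathing).
#' @param noise_sd additive Gaussian noise SD in signal units
#'   (default `s0/50`, i.e. SNR 50).
#' @param seed integer seed making the generated series deterministic.
#' @param fv_map,perf_amp_map,baseline_map,phase_lag_map optional full
#'   per-voxel maps overriding the built-in geometry (arrays of
#'   `grid_shape`); values outside the parenchyma are ignored.
#'
#' @return An object of class `phantom_spec`: a list of the parameters plus
#'   derived per-voxel maps (`parenchyma_mask`, `vessel_mask`, `fv_map`,
#'   `perf_amp_map`, `baseline_map`, `phase_lag_map`, defect masks).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 3L),
                         frame_interval = 0.288,
                         duration = 60,
                         resp_rate = 0.30,
                         cardiac_rate = 1.0,
                         s0 = 100,
                         s_b = 200,
                         fv_base = 0.11,
                         fv_range = 0.03,
                         perf_amp = 1 / 60,
                         perf_amp_range = 0.2,
                         fv_defect = 0.03,
                         perf_amp_defect = 1 / 400,
                         phase_lag = 0.15,
                         include_defects = TRUE,
                         vessel_pulsatility = 0.3,
                         duty = 0.5,
                         noise_sd = s0 / 50,
                         seed = 1L,
                         fv_map = NULL,
                         perf_amp_map = NULL,
                         baseline_map = NULL,
                         phase_lag_map = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape[1:2] >= 16L),
            grid_shape[3] >= 1L,
            frame_interval > 0, duration > 0,
            resp_rate > 0, cardiac_rate > 0,
            s0 > 0, s_b > 0, noise_sd >= 0,
            duty > 0, duty < 1)
  nyquist <- 1 / (2 * frame_interval)
  if (cardiac_rate >= nyquist) {
    stop(sprintf(
      "cardiac_rate %.3f Hz is at or above the Nyquist limit %.3f Hz of %.0f ms sampling; the cardiac component would alias",
      cardiac_rate, nyquist, 1000 * frame_interval))
  }

  geom <- phantom_geometry(grid_shape)
  nvox <- prod(grid_shape)
  par_mask <- geom$parenchyma
  vessel_mask <- geom$vessel

  # smooth gradients in [-1, 1] along y (FV) and x (perfusion amplitude)
  gx <- array(rep(seq(-1, 1, length.out = grid_shape[1]),
                  times = grid_shape[2] * grid_shape[3]), dim = grid_shape)
  gy <- array(rep(rep(seq(-1, 1, length.out = grid_shape[2]),
                      each = grid_shape[1]), times = grid_shape[3]),
              dim = grid_shape)

  if (is.null(fv_map)) {
    fv_map <- array(0, dim = grid_shape)
    fv_map[par_mask] <- fv_base + fv_range * gy[par_mask]
  }
  if (is.null(perf_amp_map)) {
    perf_amp_map <- array(0, dim = grid_shape)
    perf_amp_map[par_mask] <- perf_amp * (1 + perf_amp_range * gx[par_mask])
  }
  if (is.null(baseline_map)) {
    baseline_map <- array(0, dim = grid_shape)
    baseline_map[par_mask] <- s0 * (1 + 0.1 * gx[par_mask])
  }
  if (is.null(phase_lag_map)) phase_lag_map <- array(0, dim = grid_shape)

  vent_defect_mask <- array(FALSE, dim = grid_shape)
  lag_defect_mask <- array(FALSE, dim = grid_shape)
  perf_defect_mask <- array(FALSE, dim = grid_shape)
  if (include_defects) {
    vent_defect_mask <- geom$vent_defect & par_mask
    lag_defect_mask <- geom$lag_defect & par_mask
    perf_defect_mask <- geom$perf_defect & par_mask
    fv_map[vent_defect_mask] <- fv_defect
    perf_amp_map[perf_defect_mask] <- perf_amp_defect
    phase_lag_map[lag_defect_mask] <- phase_lag
  }

  fv_map[!par_mask] <- 0
  perf_amp_map[!par_mask] <- 0
  if (any(fv_map < 0) || any(fv_map >= 1)) {
    stop("fractional ventilation map must satisfy 0 <= FV < 1")
  }
  if (any(perf_amp_map < 0)) stop("perfusion amplitude map must be >= 0")
  if (any(vent_defect_mask & !par_mask) || any(perf_defect_mask & !par_mask)) {
    stop("defect masks must be subsets of the parenchyma mask")
  }

  structure(list(
    grid_shape = grid_shape, frame_interval = frame_interval,
    duration = duration, resp_rate = resp_rate, cardiac_rate = cardiac_rate,
    s0 = s0, s_b = s_b, vessel_pulsatility = vessel_pulsatility,
    duty = duty, noise_sd = noise_sd, seed = as.integer(seed),
    parenchyma_mask = par_mask, vessel_mask = vessel_mask,
    fv_map = fv_map, perf_amp_map = perf_amp_map,
    baseline_map = baseline_map, phase_lag_map = phase_lag_map,
    vent_defect_mask = vent_defect_mask, lag_defect_mask = lag_defect_mask,
    perf_defect_mask = perf_defect_mask
  ), class = "phantom_spec")
}

# Elliptical two-lung geometry with a mediastinal vessel strip and three
# circular defect regions, scaled to the grid.
phantom_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  xs <- (seq_len(nx) - 0.5) / nx
  ys <- (seq_len(ny) - 0.5) / ny
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  in_ellipse <- function(cx, cy, ax, ay) {
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
  }
  in_disk <- function(cx, cy, r) (X - cx)^2 + (Y - cy)^2 <= r^2

  lungs <- in_ellipse(0.30, 0.52, 0.17, 0.30) | in_ellipse(0.70, 0.52, 0.17, 0.30)
  vessel <- X >= 0.47 & X <= 0.53 & Y >= 0.40 & Y <= 0.55 & !lungs

  rep_z <- function(m) array(rep(m, nz), dim = grid_shape)
  list(
    parenchyma = rep_z(lungs),
    vessel = rep_z(vessel),
    vent_defect = rep_z(in_disk(0.70, 0.40, 0.09)),
    lag_defect = rep_z(in_disk(0.30, 0.35, 0.09)),
    perf_defect = rep_z(in_disk(0.30, 0.70, 0.09))
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  grid %d x %d x %d, %d frames at %.0f ms (%.1f s)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              n_phantom_frames(x), 1000 * x$frame_interval, x$duration))
  cat(sprintf("  respiratory %.2f Hz, cardiac %.2f Hz, noise SD %.2f\n",
              x$resp_rate, x$cardiac_rate, x$noise_sd))
  cat(sprintf("  parenchyma %d voxels, vessel %d voxels\n",
              sum(x$parenchyma_mask), sum(x$vessel_mask)))
  invisible(x)
}

n_phantom_frames <- function(spec) {
  as.integer(floor(spec$duration / spec$frame_interval))
}

#' Respiratory inflation waveform
#'
#' Raised cosine rising from 0 at end-expiration (phase 0) to 1 at
#' end-inspiration, with an optional inspiration:expiration duty asymmetry.
#'
#' @param phase cycle fraction (any real; wrapped to \[0, 1)).
#' @param duty fraction of the cycle spent going expiration to inspiration.
#' @return inflation in \[0, 1\].
#' @export
resp_waveform <- function(phase, duty = 0.5) {
  p <- frac(phase)
  warped <- ifelse(p < duty, p / (2 * duty), 0.5 + (p - duty) / (2 * (1 - duty)))
  (1 - cos(2 * pi * warped)) / 2
}

#' Cardiac pulsatility waveform
#'
#' Half-rectified sine per beat: zero in diastole, peaking at phase 0.25.
#' Its peak-to-peak range over a cycle is exactly 1, giving a well-defined
#' amplitude for perfusion quantification.
#'
#' @param phase cycle fraction (any real; wrapped to \[0, 1)).
#' @return pulsatility in \[0, 1\].
#' @export
cardiac_waveform <- function(phase) {
  pmax(0, sin(2 * pi * frac(phase)))
}
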