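#' Regional ventilation (RVent) maps and time series
#'
#' Computes the static fractional-ventilation map and the per-phase RVent
#' time series from a respiratory phase cycle. Per voxel, with cycle
#' extrema \eqn{S_{ex}} (end-expiration, maximum — lung signal is inversely
#' related to inflation) and \eqn{S_{in}} (end-inspiration, minimum):
#' \deqn{RVent = (S_{ex} - S_{in}) / S_{ex}}
#' \deqn{RVent(\phi) = (S_{ex} - S(\phi)) / S_{ex}}
#' so the time series is 0 at end-expiration and peaks at the static value.
#' Voxels with non-positive \eqn{S_{ex}} are flagged invalid (NA) and are
#' excluded from all downstream maps and summaries.
#'
#' @param cycle a `phase_cycle` from the ventilation (low-pass) branch.
#' @param mask logical array of voxels to evaluate (default: the cycle's
#'   parenchyma mask).
#' @return An object of class `rvent_result`: `static_map` (grid array, NA
#'   outside mask / at flagged voxels), `time_series` (matrix, masked voxels
#'   by phase), `s_ex`, `s_in` (vectors), `voxels` (linear indices of masked
#'   voxels), `flagged` (logical vector), `n_phases`, `nominal_dt_ms`.
#' @export
compute_rvent <- function(cycle, mask = cycle$parenchyma_mask) {
  stopifnot(inherits(cycle, "phase_cycle"))
  M <- cycle_matrix(cycle, mask)
  s_ex <- apply(M, 1L, max)
  s_in <- apply(M, 1L, min)
  flagged <- !(s_ex > 0) | !is.finite(s_ex) | !is.finite(s_in)

  static <- ifelse(flagged, NA_real_, (s_ex - s_in) / s_ex)
  ts <- (s_ex - M) / s_ex
  ts[flagged, ] <- NA_real_

  grid <- dim(cycle$values)[1:3]
  static_map <- array(NA_real_, dim = grid)
  static_map[as.vector(mask)] <- static

  structure(list(
    static_map = static_map, time_series = ts,
    s_ex = s_ex, s_in = s_in,
    voxels = which(as.vector(mask)), flagged = flagged,
    mask = mask, n_phases = cycle$n_phases,
    nominal_dt_ms = cycle$nominal_dt_ms
  ), class = "rvent_result")
}

#' Flow surrogate: symmetric difference quotient of an RVent time series
#'
#' The first derivative of RVent with respect to nominal phase time acts as
#' an MRI surrogate for airflow:
#' `flow(k) = (RVent(k+1) - RVent(k-1)) / (2 * dt)` with circular indices
#' and `dt` the nominal grid resolution in seconds. Because the reference
#' respiratory rate of the grid is conventional, flows are comparable within
#' and between maps but are not absolute airflow.
#'
#' @param rvent_ts numeric matrix (voxels by phases) or vector (one voxel).
#' @param nominal_dt_ms nominal grid resolution in milliseconds.
#' @return Flow in 1/s, same shape as `rvent_ts`.
#' @export
compute_flow <- function(rvent_ts, nominal_dt_ms) {
  one <- is.null(dim(rvent_ts))
  ts <- if (one) matrix(rvent_ts, nrow = 1) else rvent_ts
  n <- ncol(ts)
  dt <- nominal_dt_ms / 1000
  ip <- c(2:n, 1L)   # k + 1, circular
  im <- c(n, 1:(n - 1L))
  flow <- (ts[, ip, drop = FALSE] - ts[, im, drop = FALSE]) / (2 * dt)
  if (one) as.numeric(flow) else flow
}

#' Select the healthy flow-volume reference region
#'
#' Per section, selects parenchyma voxels whose static RVent lies in the
#' \[P80, P90) band of that section's RVent distribution — regions of high
#' (but not extreme) ventilation assumed healthy. Quantiles are
#' linearly interpolated; voxels equal to the lower quantile are included,
#' voxels equal to the upper quantile excluded.
#'
#' @param rvent an `rvent_result` (or a grid array of static RVent values,
#'   in which case `mask` must be given).
#' @param lo,hi percentile bounds of the band.
#' @param mask logical parenchyma array when `rvent` is a plain array.
#' @param min_voxels minimum number of valid parenchyma voxels per section.
#' @return Logical grid array marking the reference region.
#' @export
select_reference_region <- function(rvent, lo = 80, hi = 90, mask = NULL,
                                    min_voxels = 50) {
  if (inherits(rvent, "rvent_result")) {
    static_map <- rvent$static_map
    mask <- rvent$mask
  } else {
    static_map <- rvent
    if (is.null(mask)) stop("mask is required when passing a plain array")
  }
  stopifnot(lo < hi)
  grid <- dim(static_map)
  out <- array(FALSE, dim = grid)
  for (z in seq_len(grid[3])) {
    mz <- mask[, , z]
    vals <- static_map[, , z][mz]
    ok <- is.finite(vals)
    if (sum(ok) < min_voxels) {
      stop(sprintf("section %d has %d valid parenchyma voxels; at least %d required",
                   z, sum(ok), min_voxels))
    }
    q <- stats::quantile(vals[ok], probs = c(lo, hi) / 100, names = FALSE)
    if (q[2] <= q[1]) {
      stop(sprintf("degenerate RVent distribution in section %d: P%g = P%g = %.4g",
                   z, lo, hi, q[1]))
    }
    sel <- ok & vals >= q[1] & vals < q[2]
    plane <- array(FALSE, dim = grid[1:2])
    plane[mz] <- sel
    out[, , z] <- plane
  }
  out
}

#' Individualized reference flow-volume loop
#'
#' Phase-wise arithmetic mean of the volume (RVent) and flow series over the
#' reference region, giving one reference loop per section per individual.
#'
#' @param rvent an `rvent_result`.
#' @param flow flow matrix matching `rvent$time_series`.
#' @param region logical grid array (reference region).
#' @return A `flow_volume_loop`: list with `volume`, `flow` (length
#'   `n_phases`) and `phase_count`.
#' @export
compute_reference_loop <- function(rvent, flow, region) {
  idx <- match(which(as.vector(region)), rvent$voxels)
  idx <- idx[!is.na(idx)]
  idx <- idx[!rvent$flagged[idx]]
  if (!length(idx)) stop("reference region is empty")
  structure(list(
    volume = colMeans(rvent$time_series[idx, , drop = FALSE]),
    flow = colMeans(flow[idx, , drop = FALSE]),
    phase_count = rvent$n_phases
  ), class = "flow_volume_loop")
}

#' Flow-volume loop correlation map (FVL-CM)
#'
#' Correlates each parenchyma voxel's flow-volume loop with the
#' individualized reference loop at zero lag, producing a per-voxel
#' similarity r in \[-1, 1\]. The operands are the concatenated
#' (optionally standardized) volume and flow sequences over the full
#' respiratory cycle (2 x n_phases points); with standardization r equals
#' the mean of the volume-wise and flow-wise Pearson correlations, and is
#' invariant to affine rescaling of the voxel signal. High r is read as a
#' normal ventilation time course, low r as an abnormal one.
#'
#' Degenerate (zero-variance) voxel loops get correlation 0 and are flagged;
#' they appear as NA in the map and are excluded from summaries.
#'
#' @param rvent an `rvent_result`.
#' @param flow flow matrix matching `rvent$time_series`.
#' @param reference a `flow_volume_loop`.
#' @param standardize standardize each sequence to zero mean and unit
#'   variance before correlating (Pearson; the default). With `FALSE`, raw
#'   zero-lag cross-correlation (normalized inner product) is used.
#' @return An `fvl_cm_result`: `map` (grid array, NA at flagged voxels),
#'   `correlation` (vector per masked voxel), `flagged`, `reference_loop`.
#' @export
compute_fvl_cm <- function(rvent, flow, reference, standardize = TRUE) {
  res <- fvl_cm_rows(rvent, flow, reference, seq_along(rvent$voxels),
                     standardize)
  grid <- dim(rvent$static_map)
  map <- array(NA_real_, dim = grid)
  map[rvent$voxels] <- ifelse(res$flagged, NA_real_, res$r)

  structure(list(map = map, correlation = res$r, flagged = res$flagged,
                 reference_loop = reference, voxels = rvent$voxels,
                 mask = rvent$mask),
            class = "fvl_cm_result")
}

# Correlation of a row subset of the voxel loops against one reference.
fvl_cm_rows <- function(rvent, flow, reference, rows, standardize = TRUE) {
  stopifnot(inherits(reference, "flow_volume_loop"),
            reference$phase_count == rvent$n_phases)
  ref <- c(scale_loop(reference$volume, standardize),
           scale_loop(reference$flow, standardize))
  if (all(ref == 0) || stats::sd(ref) == 0) {
    stop("zero-variance reference loop")
  }

  vol <- rvent$time_series[rows, , drop = FALSE]
  flo <- flow[rows, , drop = FALSE]
  sd_v <- apply(vol, 1L, stats::sd)
  sd_f <- apply(flo, 1L, stats::sd)
  degenerate <- !is.finite(sd_v) | !is.finite(sd_f) | sd_v == 0 | sd_f == 0

  r <- rep(0, nrow(vol))
  ok <- which(!degenerate & !rvent$flagged[rows])
  if (length(ok)) {
    X <- cbind(t(apply(vol[ok, , drop = FALSE], 1L, scale_loop, standardize)),
               t(apply(flo[ok, , drop = FALSE], 1L, scale_loop, standardize)))
    r[ok] <- as.numeric(X %*% ref) /
      (sqrt(rowSums(X^2)) * sqrt(sum(ref^2)))
  }
  list(r = r, flagged = degenerate | rvent$flagged[rows])
}

scale_loop <- function(x, standardize) {
  if (!standardize) return(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
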