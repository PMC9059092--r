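#' Sort frames into one equidistant phase cycle per voxel
#'
#' Pools all frames of a series by their assigned phase and interpolates them
#' onto `n_phases` equidistant phase points, producing one reconstructed
#' cycle per voxel (60 phases for the respiratory cycle, 30 for the cardiac
#' cycle). Each frame is assigned to its nearest phase bin and frames within
#' a bin are averaged (ties in phase are resolved by frame order through the
#' running mean); empty bins are filled by circular linear interpolation
#' between the nearest populated bins.
#'
#' The nominal temporal resolution of the grid is
#' `floor(1000 / (reference_rate * n_phases))` ms at the stated reference
#' rate — 55 ms for 60 phases at the conventional 0.3 Hz respiratory
#' reference, 33 ms for 30 phases at 1 Hz (60 beats/min).
#'
#' @param series a [dynamic_series()] (usually a filtered branch).
#' @param phases a `phase_assignment` for the same frames.
#' @param n_phases number of equidistant phase points.
#' @param reference_rate reference cycle rate in Hz used only for the nominal
#'   grid resolution.
#' @return A `phase_cycle`: list with `values` (array `[x, y, z, n_phases]`),
#'   `n_phases`, `nominal_dt_ms`, `reference_rate`, and the masks carried
#'   over from the series.
#' @export
sort_to_cycle <- function(series, phases, n_phases, reference_rate) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(phases, "phase_assignment"),
            n_phases >= 2, reference_rate > 0)
  if (nrow(phases) != dim(series$signal)[4]) {
    stop("phase assignment must cover every frame of the series")
  }
  ph <- frac(phases$phase)

  # circular coverage check on the pooled phases
  sp <- sort(ph)
  gaps <- diff(c(sp, sp[1] + 1))
  if (max(gaps) > 0.2) {
    stop(sprintf("phase coverage gap of %.2f cycles at phase %.2f exceeds 0.2",
                 max(gaps), sp[which.max(gaps)]))
  }

  bin <- (round(ph * n_phases) %% n_phases) + 1L  # 1-based bins at k/n
  V <- as_voxel_matrix(series$signal)             # voxels x frames
  sums <- rowsum(t(V), group = bin)               # populated bins x voxels
  counts <- as.integer(table(bin)[rownames(sums)])
  means <- sums / counts
  present <- as.integer(rownames(sums))

  cyc <- matrix(NA_real_, nrow = nrow(V), ncol = n_phases)
  cyc[, present] <- t(means)
  if (length(present) < n_phases) {
    cyc <- fill_empty_bins(cyc, present, n_phases)
  }

  structure(list(
    values = array(cyc, dim = c(dim(series$signal)[1:3], n_phases)),
    n_phases = as.integer(n_phases),
    nominal_dt_ms = nominal_dt_ms(reference_rate, n_phases),
    reference_rate = reference_rate,
    parenchyma_mask = series$parenchyma_mask,
    vessel_mask = series$vessel_mask
  ), class = "phase_cycle")
}

#' Nominal phase-grid resolution in whole milliseconds
#'
#' @param reference_rate cycle rate in Hz.
#' @param n_phases number of equidistant phases.
#' @return `floor(1000 / (reference_rate * n_phases))`, an integer number of
#'   milliseconds.
#' @export
nominal_dt_ms <- function(reference_rate, n_phases) {
  as.integer(floor(1000 / (reference_rate * n_phases)))
}

# Circular linear interpolation into empty phase bins.
fill_empty_bins <- function(cyc, present, n_phases) {
  missing <- setdiff(seq_len(n_phases), present)
  pos <- sort(present)
  for (m in missing) {
    lo <- pos[pos < m]
    lo <- if (length(lo)) max(lo) else max(pos) - n_phases
    hi <- pos[pos > m]
    hi <- if (length(hi)) min(hi) else min(pos) + n_phases
    w <- (m - lo) / (hi - lo)
    i_lo <- ((lo - 1) %% n_phases) + 1L
    i_hi <- ((hi - 1) %% n_phases) + 1L
    cyc[, m] <- (1 - w) * cyc[, i_lo] + w * cyc[, i_hi]
  }
  cyc
}

#' @export
print.phase_cycle <- function(x, ...) {
  cat(sprintf("<phase_cycle> %d phases, nominal resolution %d ms at %.2f Hz\n",
              x$n_phases, x$nominal_dt_ms, x$reference_rate))
  invisible(x)
}

# Extract mask voxels of a phase cycle as a (voxels x phases) matrix.
cycle_matrix <- function(cycle, mask) {
  m <- matrix(cycle$values, nrow = prod(dim(cycle$values)[1:3]),
              ncol = cycle$n_phases)
  m[as.vector(mask), , drop = FALSE]
}

# Mean cycle over a mask: one value per phase.
cycle_mask_mean <- function(cycle, mask) {
  colMeans(cycle_matrix(cycle, mask))
}
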