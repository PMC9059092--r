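#' Registered dynamic lung MRI series
#'
#' Container for a registered 2D+time acquisition: a 4D signal array
#' `[x, y, section, frame]`, the frame times in seconds, and binary
#' parenchyma / large-vessel masks on the same grid.
#'
#' @param signal 4D numeric array `[x, y, section, frame]`, arbitrary signal
#'   units.
#' @param frame_times numeric vector of frame times in seconds; must be
#'   strictly increasing and uniformly spaced within 1% tolerance.
#' @param parenchyma_mask,vessel_mask logical arrays on the spatial grid.
#'   The parenchyma mask must be non-empty; the two masks must be disjoint.
#'   The vessel mask may be empty, in which case cardiac phase estimation
#'   (and hence perfusion quantification) is unavailable.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(signal, frame_times, parenchyma_mask, vessel_mask) {
  stopifnot(is.array(signal), length(dim(signal)) == 4L)
  grid <- dim(signal)[1:3]
  if (length(frame_times) != dim(signal)[4]) {
    stop("frame_times length must match the number of frames")
  }
  dt <- diff(frame_times)
  if (any(dt <= 0)) stop("frame_times must be strictly increasing")
  if (length(dt) && (max(dt) - min(dt)) > 0.01 * mean(dt)) {
    stop("frame spacing must be uniform within 1% tolerance")
  }
  parenchyma_mask <- array(as.logical(parenchyma_mask), dim = grid)
  vessel_mask <- array(as.logical(vessel_mask), dim = grid)
  if (!any(parenchyma_mask)) stop("parenchyma mask is empty")
  if (any(parenchyma_mask & vessel_mask)) {
    stop("parenchyma and vessel masks must be disjoint")
  }
  structure(list(signal = signal, frame_times = as.numeric(frame_times),
                 parenchyma_mask = parenchyma_mask,
                 vessel_mask = vessel_mask),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dynamic_series> %d x %d x %d grid, %d frames, dt = %.1f ms\n",
              d[1], d[2], d[3], d[4], 1000 * series_dt(x)))
  invisible(x)
}

# Mean frame interval in seconds.
series_dt <- function(series) mean(diff(series$frame_times))

# Sampling rate in Hz.
series_fs <- function(series) 1 / series_dt(series)

# Mean signal over a logical mask, one value per frame.
mask_mean_signal <- function(series, mask) {
  m <- as_voxel_matrix(series$signal)
  colMeans(m[as.vector(mask), , drop = FALSE])
}
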