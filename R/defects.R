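#' Threshold a parameter map into a defect label map
#'
#' Labels a voxel a defect when its metric is strictly below the threshold
#' (values equal to the cutoff are normal). The conventional cutoffs are
#' FVL-CM < 0.90, RVent < 0.075, and Q < 20 mL/min/100 mL. The defect
#' percentage is the defect fraction of the unflagged (non-NA) mask voxels,
#' pooled over all sections.
#'
#' @param map grid array of metric values (NA = flagged/outside).
#' @param threshold cutoff in the metric's units.
#' @param source_metric one of `"FVL-CM"`, `"RVent"`, `"Q"`.
#' @param mask logical array of voxels to classify.
#' @return A `defect_label_map`: `labels` (grid array: 1 defect, 0 normal,
#'   NA flagged/outside), `threshold`, `source_metric`, `defect_pct`,
#'   `n_voxels` (denominator).
#' @export
threshold_map <- function(map, threshold, source_metric = c("FVL-CM", "RVent", "Q"),
                          mask) {
  source_metric <- match.arg(source_metric)
  if (missing(mask) || is.null(mask) || !any(mask)) stop("mask is empty")
  stopifnot(identical(dim(map), dim(array(mask, dim = dim(map)))))
  labels <- array(NA_real_, dim = dim(map))
  idx <- which(as.vector(mask) & is.finite(as.vector(map)))
  if (!length(idx)) stop("no unflagged voxels in mask")
  labels[idx] <- as.numeric(map[idx] < threshold)
  structure(list(
    labels = labels, threshold = threshold, source_metric = source_metric,
    defect_pct = 100 * sum(labels[idx]) / length(idx),
    n_voxels = length(idx)
  ), class = "defect_label_map")
}

#' @export
print.defect_label_map <- function(x, ...) {
  cat(sprintf("<defect_label_map> %s < %g: %.1f%% of %d voxels\n",
              x$source_metric, x$threshold, x$defect_pct, x$n_voxels))
  invisible(x)
}

#' Ventilation-perfusion match (VQM)
#'
#' Fraction of voxels whose binary ventilation and perfusion defect labels
#' agree: a voxel with both a ventilation and a perfusion defect, or with
#' neither, counts as a match. The variant is named from the ventilation
#' source metric: `VQM_CM` when ventilation defects come from the FVL-CM,
#' `VQM_RVent` when they come from static RVent. Voxels flagged in either
#' map are excluded from the denominator.
#'
#' @param vent_defects,perf_defects `defect_label_map`s on the same grid.
#' @return A `match_result`: `vqm` (fraction in \[0, 1\]), `vdp`, `qdp`
#'   (percent, recomputed on the common voxel set), `variant`, `n_voxels`,
#'   `match_map` (grid array: 1 match, 0 mismatch, NA excluded).
#' @export
compute_vqm <- function(vent_defects, perf_defects) {
  stopifnot(inherits(vent_defects, "defect_label_map"),
            inherits(perf_defects, "defect_label_map"))
  if (!identical(dim(vent_defects$labels), dim(perf_defects$labels))) {
    stop("defect maps are on different grids")
  }
  v <- as.vector(vent_defects$labels)
  q <- as.vector(perf_defects$labels)
  ok <- is.finite(v) & is.finite(q)
  if (!any(ok)) stop("no common unflagged voxels")
  match_v <- as.numeric(v[ok] == q[ok])
  mm <- array(NA_real_, dim = dim(vent_defects$labels))
  mm[ok] <- match_v
  structure(list(
    vqm = mean(match_v),
    vdp = 100 * mean(v[ok]),
    qdp = 100 * mean(q[ok]),
    variant = if (vent_defects$source_metric == "FVL-CM") "CM" else "RVent",
    n_voxels = sum(ok),
    match_map = mm
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> VQM_%s = %.3f (VDP %.1f%%, QDP %.1f%%, n = %d)\n",
              x$variant, x$vqm, x$vdp, x$qdp, x$n_voxels))
  invisible(x)
}

#' Quartile coefficient of dispersion
#'
#' Scale-free heterogeneity measure `(P75 - P25) / (P75 + P25)` with
#' linearly interpolated quantiles.
#'
#' @param values numeric vector with at least 4 finite values.
#' @return QCD, a non-negative scalar for positive-valued data.
#' @export
qcd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("at least 4 values are required for the QCD")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  if (sum(q) <= 0) stop("QCD undefined: P25 + P75 is not positive")
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Dice overlap between two binary label arrays
#'
#' @param a,b logical/0-1 arrays of identical dimension (NA treated as 0).
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`; 1 when both empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  stopifnot(length(a) == length(b))
  a <- !is.na(a) & a > 0
  b <- !is.na(b) & b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
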