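#' Pipeline run configuration
#'
#' Collects every stage parameter with its conventional default: 0.6 Hz
#' ventilation low-pass, 0.8 Hz perfusion high-pass, 60 respiratory and 30
#' cardiac phases (referenced to 0.3 Hz and 1 Hz for the nominal grid
#' resolution), defect thresholds FVL-CM 0.90 / RVent 0.075 /
#' Q 20 mL/min/100 mL, and the 80-90 percentile healthy reference band.
#'
#' @param lowpass_hz,highpass_hz filter cutoffs in Hz.
#' @param transition_hz filter transition half-width in Hz.
#' @param n_resp_phases,n_card_phases phase-grid sizes.
#' @param resp_reference_hz,card_reference_hz reference rates for the
#'   nominal grid resolution.
#' @param fvl_cm_threshold,rvent_threshold,q_threshold defect cutoffs.
#' @param ref_percentile_lo,ref_percentile_hi healthy reference band.
#' @param blood_ref_percentile percentile of the vessel cycle used as the
#'   full-blood signal.
#' @param amplitude_mode `"ptp"` or `"first_harmonic"` perfusion amplitude.
#' @param fvl_standardize standardize loops before correlating (Pearson).
#' @param seed integer seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lowpass_hz = 0.6, highpass_hz = 0.8,
                       transition_hz = 0.15,
                       n_resp_phases = 60L, n_card_phases = 30L,
                       resp_reference_hz = 0.3, card_reference_hz = 1.0,
                       fvl_cm_threshold = 0.90, rvent_threshold = 0.075,
                       q_threshold = 20,
                       ref_percentile_lo = 80, ref_percentile_hi = 90,
                       blood_ref_percentile = 95,
                       amplitude_mode = "ptp",
                       fvl_standardize = TRUE,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full ventilation-perfusion analysis pipeline
#'
#' Executes, on a registered dynamic series: zero-phase filtering into a
#' ventilation and a perfusion branch; respiratory and cardiac phase
#' estimation; phase sorting into 60- and 30-phase cycles; RVent maps and
#' flow-volume-loop correlation maps (per section, against the section's
#' individualized healthy reference loop); perfusion quantification in
#' mL/min/100 mL; defect thresholding; and ventilation-perfusion match.
#' Sections are processed independently for the reference loop and FVL-CM
#' and pooled voxelwise for defect and match percentages.
#'
#' @param input a [dynamic_series()] or a [phantom_spec()] (which is
#'   generated first).
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, all maps are
#'   written as NIfTI, phase assignments and the metrics record as CSV, and
#'   a JSON manifest of the configuration, seed and package version.
#' @return A list of class `pipeline_result` with elements `metrics` (named
#'   list of scalar summaries), `maps` (grid arrays: `rvent_static`,
#'   `fvl_cm`, `q`, defect labels, match maps, `reference_region`),
#'   `rvent`, `fvl_cm`, `perfusion`, `defects`, `vqm`, `phases`, `config`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (inherits(input, "phantom_spec")) {
    gen <- stage("simulation", generate_series(input))
    series <- gen$series
    truth <- gen$truth
  } else if (inherits(input, "dynamic_series")) {
    series <- input
  } else {
    stop("input must be a dynamic_series or a phantom_spec")
  }
  cfg <- config
  grid <- dim(series$signal)[1:3]
  par_mask <- series$parenchyma_mask

  # --- ventilation branch ------------------------------------------------
  lp <- stage("ventilation filtering",
              lowpass_ventilation(series, cfg$lowpass_hz, cfg$transition_hz))
  resp <- stage("respiratory phase", estimate_respiratory_phase(lp))
  vent_cycle <- stage("respiratory sorting",
                      sort_to_cycle(lp, resp, cfg$n_resp_phases,
                                    cfg$resp_reference_hz))
  rvent <- stage("ventilation mapping", compute_rvent(vent_cycle))
  flow <- compute_flow(rvent$time_series, vent_cycle$nominal_dt_ms)

  ref_region <- stage("reference region",
                      select_reference_region(rvent, cfg$ref_percentile_lo,
                                              cfg$ref_percentile_hi))
  fvl <- stage("flow-volume correlation",
               fvl_cm_by_section(rvent, flow, ref_region, cfg$fvl_standardize))

  # --- perfusion branch --------------------------------------------------
  hp <- stage("perfusion filtering",
              highpass_perfusion(series, cfg$highpass_hz, cfg$transition_hz))
  card <- stage("perfusion", estimate_cardiac_phase(hp, cfg$highpass_hz))
  card_cycle <- stage("cardiac sorting",
                      sort_to_cycle(hp, card, cfg$n_card_phases,
                                    cfg$card_reference_hz))
  vessel_cycle <- stage("perfusion",
                        vessel_reference_cycle(series, card,
                                               cfg$n_card_phases))
  perf <- stage("perfusion quantification",
                quantify_perfusion(card_cycle, vessel_cycle,
                                   hr = heart_rate(card),
                                   blood_ref_percentile = cfg$blood_ref_percentile,
                                   amplitude_mode = cfg$amplitude_mode))

  # --- defects and match -------------------------------------------------
  d_cm <- stage("defect mapping",
                threshold_map(fvl$map, cfg$fvl_cm_threshold, "FVL-CM", par_mask))
  d_rv <- stage("defect mapping",
                threshold_map(rvent$static_map, cfg$rvent_threshold, "RVent",
                              par_mask))
  d_q <- stage("defect mapping",
               threshold_map(perf$q_map, cfg$q_threshold, "Q", par_mask))
  vqm_cm <- stage("match", compute_vqm(d_cm, d_q))
  vqm_rv <- stage("match", compute_vqm(d_rv, d_q))

  rv_vals <- rvent$static_map[par_mask]
  q_vals <- perf$q_map[par_mask]
  metrics <- list(
    mean_fvl_cm = mean_finite(fvl$map[par_mask], "FVL-CM values"),
    mean_rvent = mean_finite(rv_vals, "RVent values"),
    mean_q = mean_finite(q_vals, "perfusion values"),
    vdp_cm = d_cm$defect_pct,
    vdp_rvent = d_rv$defect_pct,
    qdp = d_q$defect_pct,
    vqm_cm = vqm_cm$vqm,
    vqm_rvent = vqm_rv$vqm,
    qcd_vent = qcd(rv_vals),
    qcd_q = qcd(q_vals[is.finite(q_vals)]),
    resp_rate_hz = phase_rate(resp),
    heart_rate_bpm = heart_rate(card),
    nominal_dt_resp_ms = vent_cycle$nominal_dt_ms,
    nominal_dt_card_ms = card_cycle$nominal_dt_ms
  )

  result <- structure(list(
    metrics = metrics,
    maps = list(rvent_static = rvent$static_map, fvl_cm = fvl$map,
                q = perf$q_map,
                defect_cm = d_cm$labels, defect_rvent = d_rv$labels,
                defect_q = d_q$labels,
                match_cm = vqm_cm$match_map, match_rvent = vqm_rv$match_map,
                reference_region = ref_region),
    rvent = rvent, fvl_cm = fvl, perfusion = perf,
    defects = list(cm = d_cm, rvent = d_rv, q = d_q),
    vqm = list(cm = vqm_cm, rvent = vqm_rv),
    phases = list(respiratory = resp, cardiac = card),
    truth = truth,
    config = cfg
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, series, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$metrics
  cat("<pipeline_result>\n")
  cat(sprintf("  mean FVL-CM %.3f | mean RVent %.3f | mean Q %.0f mL/min/100 mL\n",
              m$mean_fvl_cm, m$mean_rvent, m$mean_q))
  cat(sprintf("  VDP(CM) %.1f%% | VDP(RVent) %.1f%% | QDP %.1f%%\n",
              m$vdp_cm, m$vdp_rvent, m$qdp))
  cat(sprintf("  VQM_CM %.3f | VQM_RVent %.3f | HR %.0f bpm | resp %.2f Hz\n",
              m$vqm_cm, m$vqm_rvent, m$heart_rate_bpm, m$resp_rate_hz))
  invisible(x)
}

# FVL-CM computed per section against that section's reference loop and
# assembled into one map.
fvl_cm_by_section <- function(rvent, flow, ref_region, standardize = TRUE) {
  grid <- dim(rvent$static_map)
  nvox_plane <- prod(grid[1:2])
  map <- array(NA_real_, dim = grid)
  r_all <- rep(NA_real_, length(rvent$voxels))
  flagged_all <- rep(TRUE, length(rvent$voxels))
  section_of <- ((rvent$voxels - 1L) %/% nvox_plane) + 1L
  for (z in seq_len(grid[3])) {
    rows <- which(section_of == z)
    if (!length(rows)) next
    region_z <- array(FALSE, dim = grid)
    region_z[, , z] <- ref_region[, , z]
    ref <- compute_reference_loop(rvent, flow, region_z)
    res <- fvl_cm_rows(rvent, flow, ref, rows, standardize)
    r_all[rows] <- res$r
    flagged_all[rows] <- res$flagged
    map[rvent$voxels[rows]] <- ifelse(res$flagged, NA_real_, res$r)
  }
  structure(list(map = map, correlation = r_all, flagged = flagged_all,
                 reference_region = ref_region, voxels = rvent$voxels,
                 mask = rvent$mask),
            class = "fvl_cm_result")
}

# Vessel-region mean of the unfiltered signal sorted onto the cardiac phase
# grid; uses the middle section's vessel voxels (tracheal-bifurcation level)
# when any exist there, the whole vessel mask otherwise.
vessel_reference_cycle <- function(series, cardiac_phases, n_phases) {
  if (!any(series$vessel_mask)) stop("vessel mask is empty")
  grid <- dim(series$signal)[1:3]
  z_mid <- ceiling(grid[3] / 2)
  vmask <- array(FALSE, dim = grid)
  vmask[, , z_mid] <- series$vessel_mask[, , z_mid]
  if (!any(vmask)) vmask <- series$vessel_mask
  x <- mask_mean_signal(series, vmask)
  sort_vector_to_cycle(x, cardiac_phases, n_phases)
}

# Bin-pool a single time course onto the equidistant phase grid.
sort_vector_to_cycle <- function(x, phases, n_phases) {
  ph <- frac(phases$phase)
  bin <- (round(ph * n_phases) %% n_phases) + 1L
  means <- tapply(x, bin, mean)
  present <- as.integer(names(means))
  cyc <- matrix(NA_real_, 1L, n_phases)
  cyc[, present] <- as.numeric(means)
  if (length(present) < n_phases) {
    cyc <- fill_empty_bins(cyc, present, n_phases)
  }
  as.numeric(cyc)
}

write_pipeline_outputs <- function(result, series, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$maps)) {
    write_map_nifti(result$maps[[nm]], file.path(out_dir, paste0(nm, ".nii")))
  }
  write_phase_csv(result$phases$respiratory,
                  file.path(out_dir, "respiratory_phase.csv"))
  write_phase_csv(result$phases$cardiac,
                  file.path(out_dir, "cardiac_phase.csv"))
  utils::write.csv(
    data.frame(metric = names(result$metrics),
               value = unlist(result$metrics, use.names = FALSE)),
    file.path(out_dir, "metrics.csv"), row.names = FALSE)
  manifest <- list(
    package = "prefulr",
    version = as.character(utils::packageVersion("prefulr")),
    seed = result$config$seed,
    config = unclass(result$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a generated phantom to disk
#'
#' Writes the series and masks as NIfTI, the ground-truth maps as NIfTI,
#' and a JSON sidecar of the generating parameters.
#'
#' @param gen the list returned by [generate_series()].
#' @param dir output directory.
#' @export
write_phantom <- function(gen, dir) {
  write_series_nifti(gen$series, dir)
  tr <- gen$truth
  write_map_nifti(tr$fv_map, file.path(dir, "truth_fv.nii"))
  write_map_nifti(tr$q_map, file.path(dir, "truth_q.nii"))
  write_map_nifti(tr$phase_lag_map, file.path(dir, "truth_phase_lag.nii"))
  write_mask_nifti(tr$vent_defect_labels, file.path(dir, "truth_vent_defect.nii"))
  write_mask_nifti(tr$lag_defect_labels, file.path(dir, "truth_lag_defect.nii"))
  write_mask_nifti(tr$perf_defect_labels, file.path(dir, "truth_perf_defect.nii"))
  spec <- tr$spec
  params <- spec[c("grid_shape", "frame_interval", "duration", "resp_rate",
                   "cardiac_rate", "s0", "s_b", "vessel_pulsatility", "duty",
                   "noise_sd", "seed")]
  jsonlite::write_json(params, file.path(dir, "phantom_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
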