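#' Write and read a dynamic series as NIfTI plus mask files
#'
#' The 4D signal is written as `series.nii` with the frame interval in the
#' time-step header field; masks as uint8 `parenchyma_mask.nii` /
#' `vessel_mask.nii` on the same grid.
#'
#' @param series a [dynamic_series()].
#' @param dir output directory (created if needed).
#' @return `write_series_nifti()` returns the directory invisibly;
#'   `read_series_nifti()` returns a [dynamic_series()].
#' @export
write_series_nifti <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(series$signal)
  RNifti::pixdim(img) <- c(1, 1, 1, series_dt(series))
  RNifti::writeNifti(img, file.path(dir, "series.nii"))
  write_mask_nifti(series$parenchyma_mask, file.path(dir, "parenchyma_mask.nii"))
  write_mask_nifti(series$vessel_mask, file.path(dir, "vessel_mask.nii"))
  invisible(dir)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(dir) {
  img <- RNifti::readNifti(file.path(dir, "series.nii"))
  dt <- RNifti::pixdim(img)[4]
  n <- dim(img)[4]
  dynamic_series(
    signal = array(as.numeric(img), dim = dim(img)),
    frame_times = (seq_len(n) - 1) * dt,
    parenchyma_mask = read_mask_nifti(file.path(dir, "parenchyma_mask.nii")),
    vessel_mask = read_mask_nifti(file.path(dir, "vessel_mask.nii"))
  )
}

#' Write a parameter map (or mask) as NIfTI
#'
#' @param map numeric or logical grid array; NA allowed in numeric maps.
#' @param path output file path (`.nii`).
#' @export
write_map_nifti <- function(map, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map), dim = dim(map))),
                     path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0, dim = dim(img))
}

#' Serialize a phase assignment as CSV
#'
#' Columns `frame`, `time`, `phase`, `cycle_index`; the rate estimate is
#' stored in a `# rate_hz` comment on the first line by the writer and
#' restored by the reader.
#'
#' @param phases a `phase_assignment`.
#' @param path CSV path.
#' @export
write_phase_csv <- function(phases, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.8g", phase_rate(phases)), con)
  utils::write.csv(as.data.frame(phases), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_csv
#' @export
read_phase_csv <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- as.numeric(sub("# rate_hz=", "", first, fixed = TRUE))
  d <- utils::read.csv(path, comment.char = "#")
  new_phase_assignment(d$frame, d$time, d$phase, d$cycle_index, rate)
}
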