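# Build a phase_cycle directly from per-voxel cycle values.
cycle_from_values <- function(vals, n_phases = 60L, reference_rate = 0.3) {
  nvox <- nrow(vals)
  side <- ceiling(sqrt(nvox))
  grid <- c(side, side, 1L)
  arr <- array(NA_real_, dim = c(grid, n_phases))
  m <- matrix(arr, nrow = prod(grid))
  m[seq_len(nvox), ] <- vals
  mask <- array(FALSE, grid)
  mask[seq_len(nvox)] <- TRUE
  structure(list(values = array(m, dim = c(grid, n_phases)),
                 n_phases = as.integer(n_phases),
                 nominal_dt_ms = nominal_dt_ms(reference_rate, n_phases),
                 reference_rate = reference_rate,
                 parenchyma_mask = mask,
                 vessel_mask = array(FALSE, grid)),
            class = "phase_cycle")
}

test_that("RVent follows its defining formula and flags invalid voxels", {
  k <- 0:59
  vals <- rbind(
    100 - 10 * (1 - cos(2 * pi * k / 60)) / 2,  # S_ex 100, S_in 90
    rep(70, 60),                                 # constant
    -1 - sin(2 * pi * k / 60)                    # non-positive S_ex
  )
  cyc <- cycle_from_values(vals)
  rv <- compute_rvent(cyc)
  expect_equal(rv$static_map[1], 0.10, tolerance = 1e-12)
  expect_equal(rv$static_map[2], 0)
  expect_true(all(rv$time_series[2, ] == 0))
  expect_true(is.na(rv$static_map[3]))
  expect_true(rv$flagged[3])
  # time series is 0 at end-expiration and peaks at the static value
  expect_equal(min(rv$time_series[1, ]), 0)
  expect_equal(max(rv$time_series[1, ]), rv$static_map[1])
})

test_that("static RVent recovers the generating fractional ventilation", {
  grid <- c(32L, 32L, 1L)
  fv <- array(0, grid)
  geom <- prefulr:::phantom_geometry(grid)
  fv[geom$parenchyma] <- 0.08
  spec <- small_spec(noise_sd = 0, include_defects = FALSE, fv_map = fv,
                     phase_lag_map = array(0, grid))
  gen <- generate_series(spec)
  lp <- lowpass_ventilation(gen$series)
  resp <- estimate_respiratory_phase(lp)
  cyc <- sort_to_cycle(lp, resp, 60, 0.3)
  rv <- compute_rvent(cyc)
  err <- abs(rv$static_map[spec$parenchyma_mask] - 0.08)
  expect_lt(max(err, na.rm = TRUE), 0.005)
})

test_that("flow is the circular symmetric difference quotient", {
  expect_equal(compute_flow(rep(0.07, 60), 55), rep(0, 60))

  k <- 0:59
  rv <- 0.05 * (1 - cos(2 * pi * k / 60))
  flow <- compute_flow(rv, 55)
  analytic <- 0.05 * 2 * pi / (60 * 0.055) * sin(2 * pi * k / 60)
  expect_lt(max(abs(flow - analytic)), 0.02 * max(abs(analytic)))

  # wrap: a circular ramp has a large seam derivative at both ends
  ramp <- seq(0, 0.59, by = 0.01)
  f <- compute_flow(ramp, 55)
  expect_equal(f[2], (ramp[3] - ramp[1]) / (2 * 0.055))
  expect_equal(f[1], (ramp[2] - ramp[60]) / (2 * 0.055))  # across the seam
})

test_that("reference region picks the within-section [P80, P90) band", {
  grid <- c(10L, 10L, 1L)
  static <- array(NA_real_, grid)
  static[1:100] <- sample(1:100)  # values 1..100, one voxel each
  mask <- array(TRUE, grid)
  sel <- select_reference_region(static, mask = mask)
  vals <- sort(static[sel])
  # brute-force oracle: interpolated P80 = 80.2, P90 = 90.1 -> 81..90
  expect_equal(brute_quantile(1:100, 0.8), 80.2)
  expect_equal(vals, 81:90)

  expect_error(select_reference_region(array(5, grid), mask = mask),
               "degenerate RVent distribution")
})

test_that("reference regions are selected independently per section", {
  grid <- c(10L, 10L, 2L)
  static <- array(NA_real_, grid)
  static[, , 1] <- matrix(1:100, 10)
  static[, , 2] <- matrix(1001:1100, 10)
  mask <- array(TRUE, grid)
  sel <- select_reference_region(static, mask = mask)
  expect_equal(sort(static[, , 1][sel[, , 1]]), 81:90)
  expect_equal(sort(static[, , 2][sel[, , 2]]), 1081:1090)
})

test_that("too few parenchyma voxels in a section is an error", {
  grid <- c(10L, 10L, 1L)
  static <- array(NA_real_, grid)
  static[1:20] <- 1:20
  mask <- array(FALSE, grid); mask[1:20] <- TRUE
  expect_error(select_reference_region(static, mask = mask), "at least 50")
})

test_that("the reference loop is the phase-wise mean over the region", {
  k <- 0:59
  base <- 0.05 * (1 - cos(2 * pi * k / 60))
  set.seed(9)
  vals <- 100 * (1 - (outer(stats::runif(30, 0.5, 1.5), base)))
  cyc <- cycle_from_values(vals)
  rv <- compute_rvent(cyc)
  flow <- compute_flow(rv$time_series, 55)
  region <- array(FALSE, dim = dim(rv$static_map))
  region[rv$voxels[1:10]] <- TRUE
  ref <- compute_reference_loop(rv, flow, region)
  expect_equal(ref$volume, colMeans(rv$time_series[1:10, ]))
  expect_equal(ref$flow, colMeans(flow[1:10, ]))

  # identical loops: reference equals the loop; mirrored flows cancel
  expect_error(compute_reference_loop(rv, flow,
                                      array(FALSE, dim(rv$static_map))),
               "empty")
})

test_that("FVL-CM is 1 for identical loops, -1 for negated ones, 0-flagged for flat ones", {
  k <- 0:59
  base <- 0.06 * (1 - cos(2 * pi * k / 60))
  vals <- rbind(100 * (1 - base),          # same shape as reference
                100 * (1 - 0.5 * base),    # rescaled: still r = 1
                100 + 100 * base,          # inverted time course
                rep(80, 60))               # flat: degenerate
  cyc <- cycle_from_values(vals)
  rv <- compute_rvent(cyc)
  flow <- compute_flow(rv$time_series, 55)
  region <- array(FALSE, dim = dim(rv$static_map))
  region[rv$voxels[1]] <- TRUE
  ref <- compute_reference_loop(rv, flow, region)
  res <- compute_fvl_cm(rv, flow, ref)
  expect_equal(res$correlation[1], 1, tolerance = 1e-12)
  expect_equal(res$correlation[2], 1, tolerance = 1e-12)
  expect_equal(res$correlation[3], -1, tolerance = 1e-12)
  expect_equal(res$correlation[4], 0)
  expect_true(res$flagged[4])
  expect_true(is.na(res$map[rv$voxels[4]]))
})

test_that("FVL-CM is invariant to affine rescaling of the voxel signal", {
  k <- 0:59
  base <- 0.06 * (1 - cos(2 * pi * (k + 4) / 60))
  vals <- rbind(100 * (1 - base),
                20 + 350 * (100 * (1 - base)))  # affine transform
  cyc <- cycle_from_values(vals)
  rv <- compute_rvent(cyc)
  flow <- compute_flow(rv$time_series, 55)
  ref <- structure(list(volume = 0.08 * (1 - cos(2 * pi * k / 60)),
                        flow = compute_flow(0.08 * (1 - cos(2 * pi * k / 60)), 55),
                        phase_count = 60L), class = "flow_volume_loop")
  res <- compute_fvl_cm(rv, flow, ref)
  expect_equal(res$correlation[1], res$correlation[2], tolerance = 1e-9)
})

test_that("a respiratory phase lag lowers FVL-CM but not static RVent", {
  lag <- 0.15
  k <- 0:59
  loop_of <- function(l) 100 * (1 - 0.10 * (1 - cos(2 * pi * (k / 60 - l))))
  cyc <- cycle_from_values(rbind(loop_of(0), loop_of(lag)))
  rv <- compute_rvent(cyc)
  flow <- compute_flow(rv$time_series, 55)
  region <- array(FALSE, dim = dim(rv$static_map))
  region[rv$voxels[1]] <- TRUE
  ref <- compute_reference_loop(rv, flow, region)
  res <- compute_fvl_cm(rv, flow, ref)
  expect_lt(res$correlation[2], 0.9)
  # direct-correlation oracle: r = cos(2 pi lag) for a pure cosine loop
  expect_equal(res$correlation[2], cos(2 * pi * lag), tolerance = 0.01)
  expect_equal(rv$static_map[1], rv$static_map[2], tolerance = 1e-6)

  # monotone decrease of r with growing lag
  lags <- c(0.05, 0.10, 0.15, 0.20, 0.25)
  rs <- vapply(lags, function(l) {
    cyc2 <- cycle_from_values(rbind(loop_of(0), loop_of(l)))
    rv2 <- compute_rvent(cyc2)
    fl2 <- compute_flow(rv2$time_series, 55)
    reg <- array(FALSE, dim = dim(rv2$static_map)); reg[rv2$voxels[1]] <- TRUE
    compute_fvl_cm(rv2, fl2, compute_reference_loop(rv2, fl2, reg))$correlation[2]
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("a zero-variance reference loop is rejected", {
  k <- 0:59
  cyc <- cycle_from_values(rbind(100 - k / 600, 100 - k / 300))
  rv <- compute_rvent(cyc)
  flow <- compute_flow(rv$time_series, 55)
  flat <- structure(list(volume = rep(0.05, 60), flow = rep(0, 60),
                         phase_count = 60L), class = "flow_volume_loop")
  expect_error(compute_fvl_cm(rv, flow, flat), "zero-variance reference")
})
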