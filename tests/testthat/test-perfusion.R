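card_cycle_from <- function(vals) {
  nvox <- nrow(vals)
  side <- ceiling(sqrt(nvox))
  grid <- c(side, side, 1L)
  m <- matrix(NA_real_, prod(grid), 30L)
  m[seq_len(nvox), ] <- vals
  mask <- array(FALSE, grid); mask[seq_len(nvox)] <- TRUE
  structure(list(values = array(m, dim = c(grid, 30L)), n_phases = 30L,
                 nominal_dt_ms = 33L, reference_rate = 1.0,
                 parenchyma_mask = mask, vessel_mask = array(FALSE, grid)),
            class = "phase_cycle")
}

vessel_cycle_sb <- function(s_b) s_b * (0.7 + 0.3 * cardiac_waveform((0:29) / 30 + 1 / 120))

test_that("perfusion follows Q = A_Q / S_b * HR * 100", {
  s_b <- 200
  # voxel 1: peak-to-peak exactly 0.015 * S_b; voxel 2: zero amplitude
  vals <- rbind(0.015 * s_b * (0:29 %% 2), rep(0, 30))
  cyc <- card_cycle_from(vals)
  # vessel cycle whose 95th percentile is exactly S_b
  res <- quantify_perfusion(cyc, rep(c(s_b, s_b / 2), 15), hr = 60)
  expect_equal(res$blood_reference, s_b, tolerance = 1e-6)
  expect_equal(res$q_map[res$mask][1], 90, tolerance = 1e-6)
  expect_equal(res$q_map[res$mask][2], 0)
})

test_that("Q scales linearly with HR and amplitude, inversely with S_b", {
  k <- 0:29
  vals <- rbind(2 * sin(2 * pi * k / 30), 4 * sin(2 * pi * k / 30))
  cyc <- card_cycle_from(vals)
  vessel <- vessel_cycle_sb(200)
  q60 <- quantify_perfusion(cyc, vessel, hr = 60)$q_map
  q120 <- quantify_perfusion(cyc, vessel, hr = 120)$q_map
  expect_equal(q120[cyc$parenchyma_mask], 2 * q60[cyc$parenchyma_mask])
  # doubling amplitude doubles Q
  expect_equal(q60[cyc$parenchyma_mask][2], 2 * q60[cyc$parenchyma_mask][1])
  # doubling S_b halves Q
  qsb <- quantify_perfusion(cyc, vessel_cycle_sb(400), hr = 60)$q_map
  expect_equal(qsb[cyc$parenchyma_mask], q60[cyc$parenchyma_mask] / 2,
               tolerance = 1e-9)
})

test_that("first-harmonic amplitude equals peak-to-peak for sinusoidal cycles", {
  k <- 0:29
  vals <- rbind(3 * sin(2 * pi * k / 30), 1.5 * cos(2 * pi * k / 30))
  cyc <- card_cycle_from(vals)
  vessel <- vessel_cycle_sb(200)
  a <- quantify_perfusion(cyc, vessel, hr = 60, amplitude_mode = "ptp")
  b <- quantify_perfusion(cyc, vessel, hr = 60, amplitude_mode = "first_harmonic")
  pm <- cyc$parenchyma_mask
  expect_equal(b$q_map[pm], a$q_map[pm], tolerance = 0.02)
})

test_that("degenerate vessel cycles and implausible heart rates are rejected", {
  cyc <- card_cycle_from(rbind(sin(2 * pi * (0:29) / 30)))
  expect_error(quantify_perfusion(cyc, rep(5, 30), hr = 60), "degenerate")
  expect_error(quantify_perfusion(cyc, vessel_cycle_sb(200), hr = 20), "30, 180")
  expect_error(quantify_perfusion(cyc, vessel_cycle_sb(200), hr = 200), "30, 180")
  expect_error(quantify_perfusion(cyc, -vessel_cycle_sb(200), hr = 60),
               "non-positive")
})

test_that("noiseless phantom perfusion is recovered within 10%", {
  spec <- small_spec(noise_sd = 0)
  gen <- generate_series(spec)
  hp <- highpass_perfusion(gen$series)
  card <- estimate_cardiac_phase(hp)
  cyc <- sort_to_cycle(hp, card, 30, 1.0)
  vessel <- prefulr:::vessel_reference_cycle(gen$series, card, 30)
  res <- quantify_perfusion(cyc, vessel, hr = heart_rate(card))
  pm <- spec$parenchyma_mask
  rel <- abs(res$q_map[pm] - gen$truth$q_map[pm]) / gen$truth$q_map[pm]
  expect_lt(max(rel, na.rm = TRUE), 0.10)
  # regional rank order of mean Q matches the generating amplitudes
  left <- pm & gen$truth$q_map < 100 & !spec$perf_defect_mask
  right <- pm & gen$truth$q_map > 100
  expect_lt(mean(res$q_map[left]), mean(res$q_map[right]))
})

test_that("perfusion summary gives the mean and sort-oracle QCD", {
  grid <- c(2L, 2L, 1L)
  q <- array(c(50, 100, 150, 200), grid)
  mask <- array(TRUE, grid)
  s <- perfusion_summary(q, mask)
  expect_equal(s$mean_q, 125)
  p25 <- brute_quantile(c(50, 100, 150, 200), 0.25)
  p75 <- brute_quantile(c(50, 100, 150, 200), 0.75)
  expect_equal(s$qcd_q, (p75 - p25) / (p75 + p25))
  expect_equal(s$qcd_q, 0.3)

  # uniform map: mean = value, QCD = 0
  u <- perfusion_summary(array(100, grid), mask)
  expect_equal(u$mean_q, 100)
  expect_equal(u$qcd_q, 0)

  # masked-out voxels (e.g. vessels) do not contribute
  grid5 <- c(5L, 1L, 1L)
  q5 <- array(c(50, 100, 150, 200, 10000), grid5)
  m5 <- array(c(rep(TRUE, 4), FALSE), grid5)
  expect_equal(perfusion_summary(q5, m5)$mean_q, 125)
  expect_error(perfusion_summary(q, array(FALSE, grid)), "empty")
})
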