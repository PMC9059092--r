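test_that("phantom generation is deterministic given the seed", {
  spec <- small_spec(seed = 11L)
  a <- generate_series(spec)
  b <- generate_series(spec)
  expect_identical(a$series$signal, b$series$signal)
  expect_identical(a$truth$q_map, b$truth$q_map)

  c <- generate_series(small_spec(seed = 12L))
  expect_false(identical(a$series$signal, c$series$signal))
})

test_that("with zero ventilation amplitude, parenchymal variance is purely cardiac", {
  grid <- c(32L, 32L, 1L)
  spec <- small_spec(noise_sd = 0, include_defects = FALSE,
                     fv_map = array(0, grid), phase_lag_map = array(0, grid))
  gen <- generate_series(spec)
  m <- matrix(gen$series$signal, nrow = prod(grid))
  pm <- as.vector(spec$parenchyma_mask)
  v <- m[which(pm)[1], ]
  # signal is S0 * (1 + A' * q(phi_c)): correlates exactly with the cardiac
  # waveform and carries no respiratory-band component
  q <- cardiac_waveform(gen$truth$cardiac_phase)
  expect_gt(stats::cor(v, q), 0.999999)
  # respiratory-band amplitude is at most spectral leakage of the cardiac
  # component (finite series), orders below the cardiac amplitude
  amp_resp <- fit_amplitude(v, gen$series$frame_times, spec$resp_rate)
  amp_card <- fit_amplitude(v, gen$series$frame_times, spec$cardiac_rate)
  expect_lt(amp_resp / amp_card, 0.02)
})

test_that("fractional ventilation sets the relative signal excursion", {
  grid <- c(32L, 32L, 1L)
  fv <- array(0, grid)
  geom <- prefulr:::phantom_geometry(grid)
  fv[geom$parenchyma] <- 0.10
  spec <- small_spec(noise_sd = 0, include_defects = FALSE, fv_map = fv,
                     perf_amp_map = array(0, grid),
                     phase_lag_map = array(0, grid))
  gen <- generate_series(spec)
  m <- matrix(gen$series$signal, nrow = prod(grid))
  x0 <- m[which(as.vector(spec$parenchyma_mask))[5], ]
  expect_equal((max(x0) - min(x0)) / max(x0), 0.10, tolerance = 1e-3)
})

test_that("ground truth is self-consistent with the generating parameters", {
  spec <- small_spec(noise_sd = 0)
  gen <- generate_series(spec)
  pm <- spec$parenchyma_mask
  hr <- spec$cardiac_rate * 60
  expect_equal(gen$truth$q_map[pm], spec$perf_amp_map[pm] * hr * 100)
  expect_equal(gen$truth$fv_map[pm], spec$fv_map[pm])
  expect_true(all(gen$truth$vent_defect_labels[!pm] == FALSE))
  expect_true(all(gen$truth$perf_defect_labels[!pm] == FALSE))
  expect_equal(gen$truth$heart_rate, hr)
  # 208 frames for 60 s at 288 ms
  expect_identical(dim(gen$series$signal)[4], 208L)
})

test_that("a cardiac rate at or above Nyquist is rejected with a diagnostic", {
  expect_error(small_spec(cardiac_rate = 1.8), "Nyquist")
  expect_error(small_spec(cardiac_rate = 1 / (2 * 0.288)), "alias")
})

test_that("defect masks are subsets of the parenchyma", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 2L))
  expect_true(all(spec$parenchyma_mask[spec$vent_defect_mask]))
  expect_true(all(spec$parenchyma_mask[spec$lag_defect_mask]))
  expect_true(all(spec$parenchyma_mask[spec$perf_defect_mask]))
  expect_false(any(spec$parenchyma_mask & spec$vessel_mask))
})

test_that("crossover table has the stated design and null behaviour", {
  tab <- generate_crossover_table(6, true_effect = 0, period_effect = 0,
                                  patient_sd = 0, noise_sd = 0)
  expect_s3_class(tab, "crossover_table")
  expect_identical(nrow(tab), 24L)  # 6 patients x 2 periods x 2 visits
  # each patient contributes both periods, each with baseline and post
  per <- table(tab$patient_id, tab$period, tab$visit)
  expect_true(all(per == 1L))
  # null model: all post values identical across treatments
  post <- tab[tab$visit == "post", ]
  expect_equal(stats::sd(post$value), 0)
  # equal sequence split
  expect_equal(as.integer(table(tab$sequence[!duplicated(tab$patient_id)])),
               c(3L, 3L))
})

test_that("odd patient counts are rejected", {
  expect_error(generate_crossover_table(7), "even")
  expect_error(generate_crossover_table(1), "at least 2")
})

test_that("crossover tables are deterministic given the seed", {
  expect_identical(generate_crossover_table(10, seed = 3),
                   generate_crossover_table(10, seed = 3))
})
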