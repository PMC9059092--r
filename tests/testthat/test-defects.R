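test_that("thresholding uses a strict less-than comparison", {
  grid <- c(2L, 1L, 1L)
  mask <- array(TRUE, grid)
  d <- threshold_map(array(c(15, 25), grid), 20, "Q", mask)
  expect_equal(as.vector(d$labels), c(1, 0))
  expect_equal(d$defect_pct, 50)

  # all values above threshold: 0% defect
  d2 <- threshold_map(array(0.95, c(4L, 1L, 1L)), 0.9, "FVL-CM",
                      array(TRUE, c(4L, 1L, 1L)))
  expect_equal(d2$defect_pct, 0)

  # values exactly at the cutoff are normal
  d3 <- threshold_map(array(0.9, c(4L, 1L, 1L)), 0.9, "FVL-CM",
                      array(TRUE, c(4L, 1L, 1L)))
  expect_equal(d3$defect_pct, 0)

  expect_error(threshold_map(array(1, grid), 20, "Q", array(FALSE, grid)),
               "empty")
})

test_that("flagged (NA) voxels are excluded from the defect denominator", {
  grid <- c(4L, 1L, 1L)
  d <- threshold_map(array(c(10, 30, NA, NA), grid), 20, "Q",
                     array(TRUE, grid))
  expect_equal(d$n_voxels, 2L)
  expect_equal(d$defect_pct, 50)
})

test_that("lowering a threshold never increases the defect percentage", {
  set.seed(5)
  grid <- c(10L, 10L, 1L)
  map <- array(stats::runif(100, 0, 40), grid)
  mask <- array(TRUE, grid)
  pct <- vapply(seq(5, 35, by = 5),
                function(th) threshold_map(map, th, "Q", mask)$defect_pct,
                numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("VQM matches on the worked inclusion-exclusion example", {
  # 100 voxels: vdp 40%, qdp 30%, defect overlap 20%
  vent <- rep(FALSE, 100); vent[1:40] <- TRUE
  perf <- rep(FALSE, 100); perf[c(1:20, 41:50)] <- TRUE
  res <- compute_vqm(label_map_from(vent), label_map_from(perf, "Q", 20))
  expect_equal(res$vdp, 40)
  expect_equal(res$qdp, 30)
  expect_equal(res$vqm, 0.20 + (1 - 0.40 - 0.30 + 0.20))

  # identical maps match everywhere; complementary maps nowhere
  expect_equal(compute_vqm(label_map_from(vent), label_map_from(vent, "Q", 20))$vqm, 1)
  expect_equal(compute_vqm(label_map_from(vent), label_map_from(!vent, "Q", 20))$vqm, 0)
})

test_that("VQM equals inclusion-exclusion counting on random maps", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    vent <- stats::runif(n) < stats::runif(1)
    perf <- stats::runif(n) < stats::runif(1)
    res <- compute_vqm(label_map_from(vent), label_map_from(perf, "Q", 20))
    overlap <- mean(vent & perf)
    expect_equal(res$vqm, overlap + (1 - mean(vent) - mean(perf) + overlap),
                 tolerance = 1e-12)
    # match + mismatch fractions sum to one
    expect_equal(res$vqm + mean(vent != perf), 1, tolerance = 1e-12)
  }
})

test_that("VQM variant is named from the ventilation source metric", {
  vent <- c(TRUE, FALSE, TRUE, FALSE)
  perf <- c(TRUE, TRUE, FALSE, FALSE)
  cm <- compute_vqm(label_map_from(vent, "FVL-CM", 0.9),
                    label_map_from(perf, "Q", 20))
  rv <- compute_vqm(label_map_from(vent, "RVent", 0.075),
                    label_map_from(perf, "Q", 20))
  expect_equal(cm$variant, "CM")
  expect_equal(rv$variant, "RVent")
  expect_error(
    compute_vqm(label_map_from(vent), label_map_from(c(perf, perf), "Q", 20)),
    "different grids")
})

test_that("QCD matches the sort-based quantile oracle and is scale-free", {
  expect_equal(qcd(rep(7, 10)), 0)
  x <- 1:100
  p25 <- brute_quantile(x, 0.25); p75 <- brute_quantile(x, 0.75)
  expect_equal(qcd(x), (p75 - p25) / (p75 + p25))
  set.seed(8)
  y <- stats::rlnorm(200)
  expect_equal(qcd(3.7 * y), qcd(y), tolerance = 1e-12)
  expect_error(qcd(c(1, 2, 3)), "at least 4")
  expect_error(qcd(c(-5, -4, -3, -2)), "not positive")
})

test_that("phase-lag defects are detected by FVL-CM but missed by static RVent", {
  spec <- small_spec(noise_sd = 0)
  res <- run_pipeline(spec)
  tr <- res$truth
  lag_vox <- which(tr$lag_defect_labels)
  # FVL-CM classifies the lag region as defect ...
  expect_true(all(res$maps$defect_cm[lag_vox] == 1))
  # ... static RVent does not (its FV is normal there)
  expect_true(all(res$maps$defect_rvent[lag_vox] == 0))
  # and conversely the reduced-FV region is an RVent defect only
  low_vox <- which(tr$vent_defect_labels)
  expect_true(all(res$maps$defect_rvent[low_vox] == 1))
  expect_true(all(res$maps$defect_cm[low_vox] == 0))
})
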