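test_that("phantom partial volumes are fractions that sum below one", {
  ph <- make_phantom(c(16, 16, 60), seed = 1)
  pv_sum <- ph$pv_gm + ph$pv_wm + ph$pv_csf
  expect_true(all(pv_sum <= 1 + 1e-12))
  expect_true(all(ph$pv_gm >= 0 & ph$pv_gm <= 1))
  expect_true(all(ph$pv_wm >= 0 & ph$pv_wm <= 1))
  expect_true(all(ph$pv_csf >= 0 & ph$pv_csf <= 1))
  expect_gt(sum(ph$pv_gm >= 0.99), 500)  # enough pure GM for recovery tests
  expect_true(any(ph$csf_mask))
  # constructor echoes the tissue-level ground truth
  expect_equal(ph$f_gm, 60)
  expect_equal(ph$f_wm, 20)
  expect_error(make_phantom(c(16, 16, 30), asl_protocol()), "n_slices")
})

test_that("phantom and simulated dataset are deterministic in the seed", {
  ph1 <- make_phantom(c(12, 12, 60), noise_sd = 0.3, motion_sd = 0.2, seed = 5)
  ph2 <- make_phantom(c(12, 12, 60), noise_sd = 0.3, motion_sd = 0.2, seed = 5)
  expect_identical(ph1$pv_gm, ph2$pv_gm)
  expect_identical(ph1$motion_trace, ph2$motion_trace)
  d1 <- simulate_dataset(ph1)
  d2 <- simulate_dataset(ph2)
  expect_identical(d1$series$data, d2$series$data)
  expect_identical(d1$calib[[1]], d2$calib[[1]])
  ph3 <- make_phantom(c(12, 12, 60), noise_sd = 0.3, motion_sd = 0.2, seed = 6)
  expect_false(identical(simulate_dataset(ph3)$series$data, d1$series$data))
})

test_that("simulated timeseries has the protocol's volume count and calibration pair", {
  cc <- clean_case()
  expect_equal(dim(cc$ds$series$data)[4], 86L)
  expect_length(cc$ds$calib, 2L)
  expect_equal(cc$ds$sidecar$MultibandAccelerationFactor, 6L)
  # without stochastic terms, control volumes repeat exactly within a PLD
  ann <- cc$ds$series$annotations
  ctrl1 <- which(!ann$is_label & ann$pld_index == 1)
  expect_equal(cc$ds$series$data[, , , ctrl1[1]],
               cc$ds$series$data[, , , ctrl1[2]])
  # label never exceeds control in noiseless data (dM >= 0)
  lab1 <- which(ann$is_label & ann$pld_index == 1)
  expect_true(all(cc$ds$series$data[, , , lab1[1]] <=
                  cc$ds$series$data[, , , ctrl1[1]] + 1e-12))
})

test_that("injected within-band gradient appears as an exactly linear slice modulation", {
  pr <- asl_protocol()
  ph_g <- make_phantom(c(12, 12, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = 0.02, abv_value = 0, seed = 2)
  ph_0 <- make_phantom(c(12, 12, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = 0, abv_value = 0, seed = 2)
  cal_g <- simulate_dataset(ph_g)$calib[[1]]
  cal_0 <- simulate_dataset(ph_0)$calib[[1]]
  # ratio of slice means isolates the injected factor 1 + g (p - centre)
  msk <- ph_g$brain_mask
  m_g <- vapply(1:60, function(z) mean(cal_g[, , z][msk[, , z]]), numeric(1))
  m_0 <- vapply(1:60, function(z) mean(cal_0[, , z][msk[, , z]]), numeric(1))
  ratio <- m_g / m_0
  p <- (0:59) %% 10
  for (b in 0:5) {
    sl <- b * 10 + 1:10
    slope <- stats::cov(p[sl], ratio[sl]) / stats::var(p[sl])
    expect_lt(abs(slope - 0.02), 1e-6)
  }
})

test_that("band boundaries show jumps well above within-band steps on the calibration image", {
  pr <- asl_protocol()
  ph <- make_phantom(c(12, 12, 60), pr, noise_sd = 0, bias_amp = 0,
                     empirical_gradient = 0.02, seed = 3)
  cal <- simulate_dataset(ph)$calib[[1]]
  msk <- ph$brain_mask
  m <- vapply(1:60, function(z) mean(cal[, , z][msk[, , z]]), numeric(1))
  jump <- abs(diff(m))
  boundary <- (seq_len(59) %% 10) == 0
  expect_gt(mean(jump[boundary]) / mean(jump[!boundary]), 3)
})

test_that("the two banding mechanisms oppose at the shortest PLD", {
  pr <- asl_protocol()
  slice_profile <- function(g, satrecov) {
    ph <- make_phantom(c(12, 12, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = g, abv_value = 0, seed = 4)
    ds <- simulate_dataset(ph, satrecov = satrecov)
    ann <- ds$series$annotations
    j <- which(!ann$is_label & ann$pld_index == 1)[1]   # a PLD 0.2 control
    vol <- ds$series$data[, , , j]
    msk <- ph$brain_mask
    m <- vapply(1:60, function(z) mean(vol[, , z][msk[, , z]]), numeric(1))
    m / mean(m)
  }
  # gradient magnitude chosen to mirror the saturation-recovery slope at
  # PLD 0.2 s (recovery rises ~1.3%/slice-position for T1 ~ 1.3 s), with
  # the opposite sign so the mechanisms cancel
  g_mimic <- -0.014
  v_sat <- stats::var(slice_profile(0, TRUE))        # satrecov alone
  v_emp <- stats::var(slice_profile(g_mimic, FALSE)) # gradient alone
  v_both <- stats::var(slice_profile(g_mimic, TRUE))
  expect_lt(v_both, v_sat)
  expect_lt(v_both, v_emp)
})
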