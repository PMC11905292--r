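test_that("gradient estimation recovers the injected slope", {
  pr <- asl_protocol()
  cals <- list(); pvg <- list(); pvw <- list()
  for (i in 1:4) {
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = 0.02, seed = i)
    cals[[i]] <- simulate_dataset(ph)$calib[[1]]
    pvg[[i]] <- ph$pv_gm; pvw[[i]] <- ph$pv_wm
  }
  g <- fit_empirical_banding(cals, pvg, pvw, band_size(pr))
  expect_lt(abs(g - 0.02), 1e-4)

  # two cohorts with different gradients pool to the average
  for (i in 1:2) {
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = 0.015, seed = i)
    cals[[i]] <- simulate_dataset(ph)$calib[[1]]
  }
  for (i in 3:4) {
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = 0.025, seed = i)
    cals[[i]] <- simulate_dataset(ph)$calib[[1]]
  }
  g2 <- fit_empirical_banding(cals, pvg, pvw, band_size(pr))
  expect_lt(abs(g2 - 0.020), 1e-4)
})

test_that("flat images yield a zero gradient and empty bands are an error", {
  img <- array(80, c(8, 8, 60))
  pv <- array(0.6, c(8, 8, 60))
  expect_equal(fit_empirical_banding(img, pv, pv, 10), 0)
  expect_error(fit_empirical_banding(img, pv * 0, pv * 0, 10), "masked")
})

test_that("gradient correction is exact, band-mean preserving, and guarded", {
  x <- array(runif(8 * 8 * 60, 50, 150), c(8, 8, 60))
  expect_equal(empirical_correct(x, 0, 10), x)
  expect_error(empirical_correct(x, 0.5, 10), "factor <= 0")
  expect_error(empirical_correct(x, NA_real_, 10), "finite")

  # round trip through the simulator without saturation recovery
  pr <- asl_protocol()
  ph <- make_phantom(c(12, 12, 60), pr, noise_sd = 0, bias_amp = 0,
                     empirical_gradient = 0.02, abv_value = 0, seed = 5)
  ds <- simulate_dataset(ph, satrecov = FALSE)
  cal <- empirical_correct(ds$calib[[1]], 0.02, 10)
  pure <- ph$pv_wm >= 0.999
  m <- vapply(1:60, function(z) {
    msk <- pure[, , z]
    if (!any(msk)) NA_real_ else mean(cal[, , z][msk])
  }, numeric(1))
  m <- m[is.finite(m)]
  expect_lt((max(m) - min(m)) / mean(m), 0.001)

  # correction factors average one per band: the band mean (of slice means)
  # moves by less than 0.01%
  bsl <- 21:30
  m_raw <- vapply(bsl, function(z) mean(ds$calib[[1]][, , z][pure[, , z]]),
                  numeric(1))
  m_cor <- vapply(bsl, function(z) mean(cal[, , z][pure[, , z]]), numeric(1))
  expect_lt(abs(mean(m_cor) - mean(m_raw)) / mean(m_raw), 1e-4)
})

test_that("series-level correction sets provenance and refuses double application", {
  cc <- clean_case()
  ser <- empirical_correct(cc$ds$series, 0.01, 10)
  expect_true("empirical" %in% ser$corrections)
  expect_error(empirical_correct(ser, 0.01, 10), "already")
})
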