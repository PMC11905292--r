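test_that("saturation-recovery signal model evaluates correctly", {
  expect_equal(satrecov_signal(100, 1.3, 0), 0)
  expect_equal(satrecov_signal(100, 1.3, 1e6), 100)
  expect_equal(satrecov_signal(100, 1.3, 1.3), 100 * (1 - exp(-1)),
               tolerance = 1e-10)
  expect_error(satrecov_signal(100, -1, 1), "positive")
  expect_error(satrecov_signal(100, 1.3, -0.1), "non-negative")
})

test_that("noiseless control fit recovers the voxelwise T1 map", {
  cc <- clean_case()
  t1hat <- effective_t1(cc$bm, cc$ph$shape)
  err <- abs(t1hat - cc$ph$t1_tissue)[cc$ph$brain_mask]
  expect_lt(max(err), 1e-3)
  expect_true(all(cc$bm$valid[cc$ph$brain_mask]))
  expect_error(fit_satrecov(cc$ds$series, mask = array(FALSE, cc$ph$shape)),
               "empty")
})

test_that("constant-in-time input pins T1 at the feasibility bound and is flagged", {
  pr <- asl_protocol()
  d <- c(4, 4, 60)
  ser <- structure(list(
    data = array(50, c(d, 86)), protocol = pr,
    annotations = volume_annotations(pr), motion = NULL,
    corrections = character(0)), class = "asl_series")
  bm <- tryCatch(fit_satrecov(ser, mask = array(TRUE, d)),
                 error = function(e) e)
  if (inherits(bm, "error")) {
    expect_match(conditionMessage(bm), "every voxel")
  } else {
    expect_true(any(!bm$valid))
  }
})

test_that("T1 estimation degrades gracefully under noise", {
  pr <- asl_protocol()
  ph <- make_phantom(c(10, 10, 60), pr, noise_sd = 1, bias_amp = 0,
                     empirical_gradient = 0, abv_value = 0, seed = 9)
  ds <- simulate_dataset(ph)  # noise 1 a.u. = 1% of m0 ~ 100
  bm <- fit_satrecov(ds$series, ph$brain_mask)
  sel <- ph$brain_mask & bm$valid & ph$pv_csf < 0.01
  rel_err <- abs(bm$t1t_map[sel] - ph$t1_tissue[sel]) / ph$t1_tissue[sel]
  expect_lt(median(rel_err), 0.05)
})

test_that("correction normalises each band to the nominal-PLD recovery", {
  cc <- clean_case()
  pr <- cc$pr
  # factor is exactly 1 on the first slice of every band
  fld <- smsasl:::satrecov_factor_field(cc$bm, pr, 0.2, cc$ph$shape)
  for (z0 in seq(1, 60, by = 10)) {
    expect_equal(max(abs(fld[, , z0][cc$ph$brain_mask[, , z0]] - 1)), 0,
                 tolerance = 1e-9)
  }
  # and lies in (0, 1] for later within-band positions (recovery overshoot)
  expect_true(all(fld[cc$ph$brain_mask] <= 1 + 1e-12))
  expect_true(all(fld[cc$ph$brain_mask] > 0))
  # corrected control slice profile is flat within bands
  ser <- cc$ser  # already satrecov corrected
  ann <- ser$annotations
  for (k in c(1, 5)) {
    j <- which(!ann$is_label & ann$pld_index == k)[1]
    vol <- ser$data[, , , j]
    pure <- cc$ph$pv_wm >= 0.999
    m <- vapply(1:60, function(z) {
      msk <- pure[, , z]
      if (!any(msk)) NA_real_ else mean(vol[, , z][msk])
    }, numeric(1))
    for (b in 0:5) {
      sl <- b * 10 + 1:10
      mm <- m[sl][is.finite(m[sl])]
      if (length(mm) >= 2)
        expect_lt((max(mm) - min(mm)) / mean(mm), 0.005)
    }
  }
})

test_that("correction magnitude decreases with PLD while the gradient correction does not", {
  cc <- clean_case()
  pr <- cc$pr
  mags <- vapply(pr$plds, function(pld) {
    fld <- smsasl:::satrecov_factor_field(cc$bm, pr, pld, cc$ph$shape)
    max(abs(fld[cc$ph$brain_mask] - 1))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  # the empirical correction field is identical for every PLD by construction
  f1 <- smsasl:::empirical_factor_field(0.02, 10, cc$ph$shape)
  expect_identical(f1, smsasl:::empirical_factor_field(0.02, 10, cc$ph$shape))
})

test_that("double saturation-recovery correction is refused", {
  cc <- clean_case()
  expect_error(satrecov_correct(cc$ser, cc$bm), "already")
})

test_that("corrections applied to label and control create no spurious difference signal", {
  # zero-perfusion banded phantom: label equals control at every slice and
  # PLD, and because the corrections multiply both by the same factor they
  # must cancel exactly in the subtraction
  pr <- asl_protocol()
  ph <- make_phantom(c(10, 10, 60), pr, noise_sd = 0, bias_amp = 0,
                     f_gm = 0, f_wm = 0, abv_value = 0, seed = 2)
  ds <- simulate_dataset(ph)
  bm <- fit_satrecov(ds$series, ph$brain_mask)
  ser <- satrecov_correct(ds$series, bm)
  ser <- empirical_correct(ser, ph$empirical_gradient, band_size(pr))
  diff <- subtract_glm(ser, motion = NULL, mask = ph$brain_mask)
  sel <- ph$brain_mask
  for (k in 1:5)
    expect_lt(max(abs(diff$dm[, , , k][sel])), 1e-9)
})
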