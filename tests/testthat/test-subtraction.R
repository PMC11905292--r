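test_that("subtraction design codes the control-minus-label contrast", {
  ann <- data.frame(volume = 1:4, pld_index = 1L,
                    pld = 0.2, is_label = c(FALSE, FALSE, TRUE, TRUE))
  des <- build_design(ann, 1)
  expect_equal(dim(des$X), c(4L, 2L))
  expect_equal(unname(des$X[, 2]), c(0.5, 0.5, -0.5, -0.5))
  # OLS on this design equals the mean difference (checked against lm)
  y <- c(101, 103, 99, 97)
  beta <- solve(crossprod(des$X), crossprod(des$X, y))
  expect_equal(beta[2], 4.0)
  lmfit <- lm(y ~ 0 + des$X)
  expect_equal(unname(coef(lmfit)[2]), 4.0)
  expect_equal(unname(solve(crossprod(des$X),
                            crossprod(des$X, rep(7, 4)))[2]), 0)
  expect_error(build_design(ann[1:2, ], 1), "label and one control")
})

test_that("zero-motion GLM equals the naive mean difference exactly", {
  cc <- clean_case()
  ser <- cc$ser
  ann <- ser$annotations
  diff <- cc$diff
  vi <- which(cc$ph$brain_mask)[c(1, 50, 500)]
  for (k in c(1, 5)) {
    ctl <- which(!ann$is_label & ann$pld_index == k)
    lab <- which(ann$is_label & ann$pld_index == k)
    naive <- apply(ser$data[, , , ctl, drop = FALSE], 1:3, mean) -
             apply(ser$data[, , , lab, drop = FALSE], 1:3, mean)
    expect_lt(max(abs(diff$dm[, , , k][vi] - naive[vi])), 1e-10)
  }
})

test_that("difference data match the forward model at the effective PLD", {
  cc <- clean_case()
  sel <- cc$ph$brain_mask
  for (k in 1:5) {
    truth <- truth_dm_volume(cc$ph, k)
    expect_lt(max(abs((cc$diff$dm[, , , k] - truth)[sel])), 1e-6)
    # effective PLD never falls below the nominal PLD
    expect_true(all(cc$diff$eff_pld[, , , k] >= cc$pr$plds[k] - 1e-12))
  }
  expect_true(all(cc$diff$n_used <= 2 * cc$pr$repeats))
})

test_that("voxels leaving the FOV in any volume are excluded", {
  cc <- clean_case()
  mot <- matrix(0, 86, 3)
  mot[10, 3] <- 2  # head moves +2 slices for one volume
  diff <- subtract_glm(cc$ser, motion = mot, mask = cc$ph$brain_mask)
  # realigned voxels at the top of the grid sample outside the FOV
  expect_true(all(!diff$valid_mask[, , 59:60]))
  expect_true(any(diff$valid_mask[, , 30]))
  mot_huge <- matrix(200, 86, 3)
  expect_error(subtract_glm(cc$ser, motion = mot_huge,
                            mask = cc$ph$brain_mask), "FOV")
})

test_that("motion-resolved factors track the slice each voxel occupied", {
  cc <- clean_case()
  pr <- cc$pr
  d <- cc$ph$shape
  # uniform-T1 banding model isolates the slice-profile component
  bmu <- cc$bm
  bmu$t1t_map[] <- 1.3
  bmu$valid[] <- TRUE
  f_static <- motion_resolved_factors(bmu, pr, motion = NULL,
                                      g = 0.02, dims = d)
  expect_equal(f_static[, , , 1], f_static[, , , 2])

  mot <- matrix(0, 86, 3); mot[7, 3] <- 1
  f_mot <- motion_resolved_factors(bmu, pr, motion = mot, g = 0.02, dims = d)
  # untouched volumes match the static computation exactly
  expect_equal(f_mot[, , , 1], f_static[, , , 1])
  # the moved volume's field is the static field shifted by one slice
  shifted <- smsasl:::translate_volume(f_static[, , , 7], c(0, 0, -1),
                                       fill = NA_real_)
  ok <- is.finite(shifted)
  expect_lt(max(abs(f_mot[, , , 7] - shifted)[ok]), 1e-12)

  # a half-slice shift interpolates between adjacent slice factors: exact
  # for the gradient component, and to within the (tiny) curvature of the
  # recovery factor across slices for the saturation-recovery component
  mot2 <- matrix(0, 86, 3); mot2[7, 3] <- 0.5
  f_half <- motion_resolved_factors(bmu, pr, motion = mot2, g = 0.02,
                                    dims = d)
  z <- 25  # interior slice
  hand <- (f_static[8, 8, z, 7] + f_static[8, 8, z + 1, 7]) / 2
  expect_equal(f_half[8, 8, z, 7], hand, tolerance = 1e-3)
  fe_static <- motion_resolved_factors(NULL, pr, motion = NULL, g = 0.02,
                                       dims = d)
  fe_half <- motion_resolved_factors(NULL, pr, motion = mot2, g = 0.02,
                                     dims = d)
  hand_e <- (fe_static[8, 8, z, 7] + fe_static[8, 8, z + 1, 7]) / 2
  expect_equal(fe_half[8, 8, z, 7], hand_e, tolerance = 1e-12)
})

test_that("motion-resolved correction beats static correction under slice motion", {
  pr <- asl_protocol()
  ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0, bias_amp = 0, seed = 3)
  set.seed(42)
  mot <- matrix(0, 86, 3)
  mot[, 3] <- sample(c(-1, 0, 1), 86, replace = TRUE)
  mot[1, ] <- 0
  ph$motion_trace <- mot
  ds <- simulate_dataset(ph)
  d <- ph$shape

  # motion-resolved path: gradient first, then satrecov, FOV-aware GLM
  al <- realign_series(ds$series)
  al$data <- al$data * motion_resolved_factors(
    NULL, pr, motion = mot, g = ph$empirical_gradient, dims = d)
  bm <- fit_satrecov(al, ph$brain_mask, motion = mot)
  al$data <- al$data * motion_resolved_factors(bm, pr, motion = mot, dims = d)
  diff_mr <- subtract_glm(al, motion = mot, mask = ph$brain_mask)

  # static path: corrections ignore motion, naive subtraction
  bm_s <- fit_satrecov(ds$series, ph$brain_mask, motion = NULL)
  ser_s <- empirical_correct(satrecov_correct(ds$series, bm_s),
                             ph$empirical_gradient, band_size(pr))
  diff_s <- subtract_glm(realign_series(ser_s), motion = NULL,
                         mask = ph$brain_mask)

  sel <- diff_mr$valid_mask & ph$brain_mask
  for (k in c(1, 3, 5)) {
    truth <- truth_dm_volume(ph, k)
    rmse_mr <- sqrt(mean((diff_mr$dm[, , , k] - truth)[sel]^2))
    rmse_s <- sqrt(mean((diff_s$dm[, , , k] - truth)[sel]^2))
    expect_gt(rmse_s / rmse_mr, 2)
  }
  # no systematic negative perfusion signal on the well-posed phantom
  expect_gt(min(diff_mr$dm[, , , 5][sel]), -3 * 0.01)
})
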