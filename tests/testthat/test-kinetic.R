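test_that("tissue kinetic curve matches its quadrature oracle", {
  f <- 0.01; att <- 1.3; tau <- 1.5; t1app <- 1.1; t1b <- 1.65
  alpha <- 0.85; m0a <- 1
  # pre-arrival and continuity at the bolus tail
  expect_equal(buxton_tissue(att / 2, f, att, tau, t1app, t1b, alpha, m0a), 0)
  eps <- 1e-9
  expect_lt(abs(buxton_tissue(att + tau - eps, f, att, tau, t1app, t1b, alpha, m0a) -
                buxton_tissue(att + tau + eps, f, att, tau, t1app, t1b, alpha, m0a)),
            1e-6)
  tt <- c(1.5, 2.0, 2.8, 3.5, 4.5)
  closed <- buxton_tissue(tt, f, att, tau, t1app, t1b, alpha, m0a)
  quad <- buxton_quadrature(tt, f, att, tau, t1app, t1b, alpha, m0a)
  expect_lt(max(abs(closed - quad) / pmax(quad, 1e-12)), 1e-3)
  expect_error(buxton_tissue(1, f, att, tau, t1app = -1), "positive")
})

test_that("tissue curve is exactly linear in perfusion and blood magnetisation", {
  tt <- seq(0.5, 4, by = 0.25)
  base <- buxton_tissue(tt, 0.01, 1.2)
  expect_equal(buxton_tissue(tt, 0.02, 1.2), 2 * base)
  expect_equal(buxton_tissue(tt, 0.01, 1.2, m0a = 3), 3 * base)
})

test_that("arterial component is a decaying boxcar with the stated amplitude", {
  expect_equal(buxton_arterial(1.0, 0, 0.5), 0)
  expect_equal(buxton_arterial(0.3, 0.01, 0.5), 0)   # before arrival
  expect_equal(buxton_arterial(2.1, 0.01, 0.5), 0)   # after the bolus passes
  val <- buxton_arterial(1.7, 0.01, 0.5, tau = 1.5, t1_blood = 1.65,
                         alpha = 0.85, m0a = 100)
  expect_equal(val, 2 * 0.85 * 100 * 0.01 * exp(-1.7 / 1.65),
               tolerance = 1e-10)
  expect_equal(val, 0.6067, tolerance = 1e-4)
})

test_that("noiseless multi-PLD fit recovers perfusion and transit time", {
  cc <- clean_case()
  sel <- cc$ph$pv_gm >= 0.99
  fit <- fit_kinetic(cc$diff, effective_t1(cc$bm, cc$ph$shape),
                     mask = sel, m0a = cc$ph$m0_blood)
  cal <- calibrate(fit, cc$ph$m0_blood)
  got <- cal$cbf[sel & cal$mask]
  expect_lt(max(abs(got - cc$ph$f_gm)) / cc$ph$f_gm, 0.01)
  expect_lt(max(abs(cal$att[sel & cal$mask] - cc$ph$att_gm)), 0.01)
  # fitted-model methods are consistent with the stored data
  expect_lt(max(abs(residuals(cal))) / max(abs(cal$obs)), 1e-3)
  expect_equal(unname(coef(cal)["att"]), cc$ph$att_gm, tolerance = 1e-3)
})

test_that("seeded noisy fit keeps bias and transit-time error within bounds", {
  # noise at 10% of the peak GM difference signal (~0.8 a.u.)
  nc <- noisy_case()
  sel <- nc$sel
  expect_gt(sum(sel), 500)
  cbf <- nc$fit$cbf[sel & nc$fit$mask]
  att <- nc$fit$att[sel & nc$fit$mask]
  expect_lt(abs(median(cbf) - nc$ph$f_gm) / nc$ph$f_gm, 0.05)
  expect_lt(sqrt(mean((att - nc$ph$att_gm)^2)), 0.1)
})

test_that("uninformative data revert the transit time to its prior mean", {
  rc <- reversion_case()
  expect_lt(abs(mean(rc$fit$att[rc$sel & rc$fit$mask], na.rm = TRUE) - 1.3),
            0.05)
})

test_that("ARD removes the macrovascular component from non-arterial voxels", {
  ac <- ard_case()
  arterial <- ac$ph$abv > 0 & ac$fit$mask
  clean <- ac$ph$abv == 0 & ac$fit$mask
  expect_gt(mean(ac$fit$abv[arterial] > 0, na.rm = TRUE), 0.9)
  expect_gt(mean(ac$fit$abv[clean] == 0, na.rm = TRUE), 0.9)
})
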