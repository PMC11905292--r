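# Lazily built, cached fixtures shared across test files (helpers are
# sourced once per run, so the cache environment persists).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# Noiseless phantom with no banding, bias, motion or macrovascular signal:
# the cleanest setting for subtraction/kinetic ground-truth checks.
clean_case <- function() {
  fixture("clean_case", function() {
    pr <- asl_protocol()
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0, bias_amp = 0,
                       empirical_gradient = 0, abv_value = 0, seed = 1)
    ds <- simulate_dataset(ph)
    bm <- fit_satrecov(ds$series, ph$brain_mask)
    ser <- satrecov_correct(ds$series, bm)
    diff <- subtract_glm(ser, motion = NULL, mask = ph$brain_mask)
    list(pr = pr, ph = ph, ds = ds, bm = bm, ser = ser, diff = diff)
  })
}

# Noiseless phantom with both banding mechanisms, bias field and the
# arterial tube active (the package defaults).
banded_case <- function() {
  fixture("banded_case", function() {
    pr <- asl_protocol()
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0, seed = 1)
    ds <- simulate_dataset(ph)
    list(pr = pr, ph = ph, ds = ds)
  })
}

# Ground-truth difference signal on the reference grid at the effective
# (slice-adjusted) times, by direct evaluation of the forward model.
truth_dm_volume <- function(ph, pld_index) {
  pr <- ph$protocol
  d <- ph$shape
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    te <- pr$label_dur + pr$plds[pld_index] +
      ((z - 1) %% band_size(pr)) * pr$slice_dt
    crv <- smsasl:::phantom_dm_curve(ph, te)
    out[, , z] <- ph$pv_gm[, , z] * crv$gm + ph$pv_wm[, , z] * crv$wm +
      ph$abv[, , z] * crv$art
  }
  out
}

# Independent quadrature oracle for the tissue Buxton curve: numerical
# convolution of the PCASL delivery function with single-exponential decay.
buxton_quadrature <- function(t, f, att, tau, t1app, t1_blood, alpha, m0a) {
  vapply(t, function(tt) {
    if (tt <= att) return(0)
    up <- min(tt, att + tau)
    val <- stats::integrate(function(s)
      exp(-att / t1_blood) * exp(-(tt - s) / t1app),
      lower = att, upper = up, rel.tol = 1e-10)$value
    2 * alpha * m0a * f * val
  }, numeric(1))
}

# Noisy phantom at 10% of the peak GM difference signal, for stochastic
# parameter-recovery checks.
noisy_case <- function() {
  fixture("noisy_case", function() {
    pr <- asl_protocol()
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0.08, bias_amp = 0,
                       empirical_gradient = 0, abv_value = 0, seed = 7)
    ds <- simulate_dataset(ph)
    bm <- fit_satrecov(ds$series, ph$brain_mask)
    diff <- subtract_glm(satrecov_correct(ds$series, bm), motion = NULL,
                         mask = ph$brain_mask)
    sel <- ph$pv_gm >= 0.99
    fit <- calibrate(fit_kinetic(diff, effective_t1(bm, ph$shape),
                                 mask = sel, m0a = ph$m0_blood),
                     ph$m0_blood)
    list(pr = pr, ph = ph, sel = sel, fit = fit)
  })
}

# Zero-perfusion noisy phantom: the difference data are pure noise.
reversion_case <- function() {
  fixture("reversion_case", function() {
    pr <- asl_protocol()
    ph <- make_phantom(c(12, 12, 60), pr, noise_sd = 0.08, bias_amp = 0,
                       empirical_gradient = 0, abv_value = 0,
                       f_gm = 0, f_wm = 0, seed = 8)
    ds <- simulate_dataset(ph)
    bm <- fit_satrecov(ds$series, ph$brain_mask)
    diff <- subtract_glm(satrecov_correct(ds$series, bm), motion = NULL,
                         mask = ph$brain_mask)
    sel <- ph$pv_gm >= 0.9
    fit <- fit_kinetic(diff, effective_t1(bm, ph$shape), mask = sel,
                       ard = FALSE)
    list(ph = ph, sel = sel, fit = fit)
  })
}

# Mixed macrovascular phantom for ARD sensitivity/specificity.
ard_case <- function() {
  fixture("ard_case", function() {
    pr <- asl_protocol()
    ph <- make_phantom(c(16, 16, 60), pr, noise_sd = 0.02, bias_amp = 0,
                       empirical_gradient = 0, abv_value = 0.01, seed = 13)
    ds <- simulate_dataset(ph)
    bm <- fit_satrecov(ds$series, ph$brain_mask)
    diff <- subtract_glm(satrecov_correct(ds$series, bm), motion = NULL,
                         mask = ph$brain_mask)
    sel <- (ph$pv_gm >= 0.9 | ph$pv_wm >= 0.9) | ph$abv > 0
    fit <- fit_kinetic(diff, effective_t1(bm, ph$shape), mask = sel,
                       m0a = ph$m0_blood)
    list(ph = ph, fit = fit)
  })
}

# PVEc and single-compartment fits of the clean case, calibrated.
pvec_case <- function() {
  fixture("pvec_case", function() {
    cc <- clean_case()
    pv <- fit_pvec(cc$diff, cc$ph$pv_gm, cc$ph$pv_wm,
                   m0a = cc$ph$m0_blood, smoothness = 0.1)
    cal <- calibrate(pv, cc$ph$m0_blood)
    single <- calibrate(fit_kinetic(cc$diff,
                                    effective_t1(cc$bm, cc$ph$shape),
                                    mask = cc$ph$brain_mask, ard = FALSE,
                                    m0a = cc$ph$m0_blood), cc$ph$m0_blood)
    list(cc = cc, cal = cal, single = single)
  })
}
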