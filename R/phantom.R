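#' Construct a geometric SMS PCASL phantom with known ground truth
#'
#' Builds a nested-ellipsoid digital head: a grey-matter shell around a
#' white-matter interior with a central ventricular CSF compartment, smooth
#' partial-volume transitions at every boundary, a thin intra-cerebral
#' "artery" carrying macrovascular signal, a smooth multiplicative bias
#' field, a within-band intensity gradient, per-volume rigid translations
#' and Gaussian noise. Every quantity a downstream stage estimates is stored
#' as ground truth so parameter recovery can be measured exactly.
#'
#' Defaults define the study conditions used throughout the package's tests:
#' GM/WM perfusion 60/20 ml/100g/min, GM/WM transit times 1.2/1.5 s,
#' arterial arrival 0.8 s, GM/WM/CSF T1 1.3/1.1/4.3 s, equal GM/WM proton
#' density, and a within-band gradient of -0.02 per slice position (negative,
#' so that it opposes the saturation-recovery slice profile at short PLDs).
#'
#' @param shape Voxel grid dimensions (X, Y, Z); Z must equal the protocol's
#'   slice count.
#' @param protocol An [asl_protocol()].
#' @param ... Ground-truth overrides, any of: `f_gm`, `f_wm` (ml/100g/min),
#'   `att_gm`, `att_wm`, `att_arterial` (s), `abv_value` (blood volume
#'   fraction in the arterial mask), `t1_gm`, `t1_wm`, `t1_csf` (s),
#'   `m0_gm`, `m0_wm`, `m0_blood` (a.u.), `bias_amp` (relative amplitude of
#'   the bias field), `empirical_gradient` (relative slope per within-band
#'   position), `noise_sd` (a.u.), `motion_sd` (voxels; translations drawn
#'   per volume, reference volume fixed at zero), `lam_csf`, `t2_csf`,
#'   `t2_blood` (calibration constants embedded in the CSF signal).
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical phantom and dataset.
#' @return An object of class `asl_phantom`.
#' @examples
#' ph <- make_phantom(c(16, 16, 60), asl_protocol(), seed = 1)
#' range(ph$pv_gm + ph$pv_wm + ph$pv_csf)
#' @export
make_phantom <- function(shape = c(24, 24, 60), protocol = asl_protocol(),
                         ..., seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("'shape' must have length 3")
  if (shape[3] != protocol$n_slices)
    stop("third dimension of 'shape' must equal protocol n_slices")
  p <- list(
    f_gm = 60, f_wm = 20, att_gm = 1.2, att_wm = 1.5,
    att_arterial = 0.8, abv_value = 0.01,
    t1_gm = 1.3, t1_wm = 1.1, t1_csf = 4.3,
    m0_gm = 100, m0_wm = 100, m0_blood = 110,
    bias_amp = 0.1, empirical_gradient = -0.02,
    noise_sd = 0.4, motion_sd = 0,
    lam_csf = 1.15, t2_csf = 0.75, t2_blood = 0.15
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown phantom parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots

  d <- shape
  ctr <- (d - 1) / 2
  ax <- function(i) seq_len(d[i]) - 1 - ctr[i]
  # normalised elliptical radius field for semi-axes a
  radius <- function(a) {
    r2 <- outer(outer((ax(1) / a[1])^2, (ax(2) / a[2])^2, "+"),
                (ax(3) / a[3])^2, "+")
    sqrt(r2)
  }
  soft <- function(r, w = 0.08) pmin(pmax((1 + w - r) / (2 * w), 0), 1)

  # the imaging slab covers the cerebrum axially, so the head extends to the
  # first/last slices (in-plane cross-section shrinking towards the poles)
  a_brain <- c(0.42 * d[1], 0.42 * d[2], 0.58 * d[3])
  a_inner <- 0.72 * a_brain
  a_vent  <- c(0.16 * d[1], 0.16 * d[2], 0.16 * d[3])
  brain <- soft(radius(a_brain))
  inner <- soft(radius(a_inner))
  vent  <- soft(radius(a_vent))

  pv_gm <- pmax(brain - inner, 0)
  pv_csf <- pmin(vent, inner)
  pv_wm <- pmax(inner - pv_csf, 0)

  # CSF proton density chosen so reference-region calibration is exact:
  # S_csf = M0_blood * lam_csf * exp(-TE/T2_csf) * exp(+TE/T2_blood)
  te <- protocol$te
  m0_csf <- p$m0_blood * p$lam_csf * exp(-te / p$t2_csf) * exp(te / p$t2_blood)
  m0_tissue <- pv_gm * p$m0_gm + pv_wm * p$m0_wm + pv_csf * m0_csf

  pv_sum <- pv_gm + pv_wm + pv_csf
  t1_tissue <- array(p$t1_gm, d)
  in_brain <- pv_sum > 1e-6
  t1_tissue[in_brain] <- (pv_gm[in_brain] * p$t1_gm + pv_wm[in_brain] * p$t1_wm +
                          pv_csf[in_brain] * p$t1_csf) / pv_sum[in_brain]

  # thin "artery": vertical tube inside the white matter
  tube_c <- c(ctr[1] - 0.30 * a_inner[1], ctr[2])
  r_inplane <- sqrt(outer((seq_len(d[1]) - 1 - tube_c[1])^2,
                          (seq_len(d[2]) - 1 - tube_c[2])^2, "+"))
  zmid <- abs(ax(3)) < 0.30 * d[3]
  abv <- array(0, d)
  tube <- array(rep(r_inplane < 1.6, times = d[3]), d)
  tube <- tube & array(rep(zmid, each = d[1] * d[2]), d) & (pv_wm > 0.5)
  abv[tube] <- p$abv_value

  # smooth multiplicative bias field: off-centre Gaussian bump
  bc <- ctr + c(0.2, 0.15, 0.1) * d
  g1 <- exp(-((seq_len(d[1]) - 1 - bc[1])^2) / (2 * (0.45 * d[1])^2))
  g2 <- exp(-((seq_len(d[2]) - 1 - bc[2])^2) / (2 * (0.45 * d[2])^2))
  g3 <- exp(-((seq_len(d[3]) - 1 - bc[3])^2) / (2 * (0.45 * d[3])^2))
  bump <- outer(outer(g1, g2), g3)
  bias_field <- 1 + p$bias_amp * (bump - mean(bump))

  nvol <- n_volumes(protocol)
  set.seed(as.integer(seed))
  motion <- matrix(0, nvol, 3)
  if (p$motion_sd > 0) {
    motion[-1, ] <- stats::rnorm(3 * (nvol - 1), sd = p$motion_sd)
  }

  # parcel labels: tissue class x spatial octant (GM 1-8, WM 9-16)
  oct <- (outer(outer(as.integer(ax(1) >= 0), 2L * as.integer(ax(2) >= 0), "+"),
                4L * as.integer(ax(3) >= 0), "+"))
  parcels <- array(0L, d)
  parcels[pv_gm >= 0.5] <- 1L + oct[pv_gm >= 0.5]
  parcels[pv_wm >= 0.5] <- 9L + oct[pv_wm >= 0.5]

  structure(c(list(
    shape = d, protocol = protocol,
    pv_gm = pv_gm, pv_wm = pv_wm, pv_csf = pv_csf,
    abv = abv, t1_tissue = t1_tissue, m0_tissue = m0_tissue,
    m0_csf = m0_csf, bias_field = bias_field,
    motion_trace = motion, parcels = parcels,
    csf_mask = pv_csf >= 0.99, brain_mask = pv_sum > 0.5,
    seed = as.integer(seed)
  ), p), class = "asl_phantom")
}

#' @export
print.asl_phantom <- function(x, ...) {
  cat(sprintf("SMS PCASL phantom %dx%dx%d\n", x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  f (GM/WM)      : %.3g / %.3g ml/100g/min\n", x$f_gm, x$f_wm))
  cat(sprintf("  ATT (GM/WM/art): %.3g / %.3g / %.3g s\n",
              x$att_gm, x$att_wm, x$att_arterial))
  cat(sprintf("  aBV in artery  : %.3g  (%d voxels)\n", x$abv_value,
              sum(x$abv > 0)))
  cat(sprintf("  gradient g     : %.3g /slice-pos; bias amp %.3g; noise sd %.3g\n",
              x$empirical_gradient, x$bias_amp, x$noise_sd))
  cat(sprintf("  motion sd      : %.3g voxels; seed %d\n", x$motion_sd, x$seed))
  invisible(x)
}

# noiseless forward dM (tissue + arterial) for one voxel set at times t
phantom_dm_curve <- function(phantom, t, lam = 0.9, alpha = 0.85,
                             t1_blood = 1.65) {
  f_gm <- phantom$f_gm / 6000
  f_wm <- phantom$f_wm / 6000
  tau <- phantom$protocol$label_dur
  dm_gm <- buxton_tissue(t, f_gm, phantom$att_gm, tau,
                         t1_apparent(phantom$t1_gm, f_gm, lam),
                         t1_blood, alpha, phantom$m0_blood)
  dm_wm <- buxton_tissue(t, f_wm, phantom$att_wm, tau,
                         t1_apparent(phantom$t1_wm, f_wm, lam),
                         t1_blood, alpha, phantom$m0_blood)
  dm_art <- buxton_arterial(t, 1, phantom$att_arterial, tau,
                            t1_blood, alpha, phantom$m0_blood)
  list(gm = dm_gm, wm = dm_wm, art = dm_art)
}

#' Simulate an SMS multi-delay PCASL dataset from a phantom
#'
#' Generates the ASL label/control timeseries and two long-TR calibration
#' images. For each ASL volume the anatomy is rigidly translated by that
#' volume's motion, the static tissue signal is formed by saturation
#' recovery at the slice-specific interval since pre-saturation, label
#' volumes subtract the Buxton-model difference signal evaluated at the
#' slice-adjusted time (modulated by the same slice recovery profile), and
#' the scanner-frame within-band gradient and bias field multiply the
#' result before Gaussian noise is added. Calibration images are treated as
#' fully relaxed (TR > 8 s) but still carry the within-band gradient and
#' the bias field.
#'
#' @param phantom An [make_phantom()] object.
#' @param protocol An [asl_protocol()]; defaults to the phantom's.
#' @param satrecov If `FALSE`, disable the saturation-recovery banding
#'   mechanism (all slices behave as if acquired at the nominal PLD).
#' @param seed Optional seed overriding the phantom's.
#' @return An object of class `asl_dataset`: `series` (an `asl_series` with
#'   4D data, annotations and the true motion trace), `calib` (list of two
#'   3D calibration images), `sidecar` (acquisition metadata), and `truth`
#'   (the phantom).
#' @export
simulate_dataset <- function(phantom, protocol = phantom$protocol,
                             satrecov = TRUE, seed = phantom$seed) {
  d <- phantom$shape
  ann <- volume_annotations(protocol)
  nvol <- nrow(ann)
  B <- band_size(protocol)
  slices <- seq_len(d[3]) - 1
  pos <- slices %% B
  g <- phantom$empirical_gradient
  emp_slice <- 1 + g * (pos - (B - 1) / 2)
  if (any(emp_slice <= 0)) stop("empirical gradient too large: factor <= 0")
  emp3 <- array(rep(emp_slice, each = d[1] * d[2]), d)

  set.seed(as.integer(seed))
  motion <- phantom$motion_trace
  if (nrow(motion) != nvol) stop("motion trace length must match volume count")

  data <- array(0, c(d, nvol))
  moved <- function(vol, m) if (all(m == 0)) vol else translate_volume(vol, m)

  for (j in seq_len(nvol)) {
    m <- motion[j, ]
    m0_s <- moved(phantom$m0_tissue, m)
    t1_s <- moved(phantom$t1_tissue, m)
    pvgm_s <- moved(phantom$pv_gm, m)
    pvwm_s <- moved(phantom$pv_wm, m)
    abv_s <- moved(phantom$abv, m)
    pld <- ann$pld[j]
    t_nom <- protocol$label_dur + pld
    t_eff <- t_nom + pos * protocol$slice_dt           # per scanner slice
    t_sat <- if (satrecov) t_eff else rep(t_nom, d[3])
    tsat3 <- array(rep(t_sat, each = d[1] * d[2]), d)
    rec_sl <- 1 - exp(-tsat3 / t1_s)
    vol <- m0_s * rec_sl
    if (ann$is_label[j]) {
      crv <- phantom_dm_curve(phantom, t_eff)
      dm3 <- pvgm_s * array(rep(crv$gm, each = d[1] * d[2]), d) +
             pvwm_s * array(rep(crv$wm, each = d[1] * d[2]), d) +
             abv_s * array(rep(crv$art, each = d[1] * d[2]), d)
      rec_nom <- 1 - exp(-t_nom / t1_s)
      vol <- vol - dm3 * (rec_sl / rec_nom)
    }
    vol <- vol * emp3 * phantom$bias_field
    if (phantom$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(d), sd = phantom$noise_sd), d)
    data[, , , j] <- vol
  }

  calib <- lapply(1:2, function(k) {
    cv <- phantom$m0_tissue * emp3 * phantom$bias_field
    if (phantom$noise_sd > 0)
      cv <- cv + array(stats::rnorm(prod(d), sd = phantom$noise_sd), d)
    cv
  })

  sidecar <- list(
    LabelingDuration = protocol$label_dur,
    PostLabelingDelays = protocol$plds,
    Repeats = protocol$repeats,
    MultibandAccelerationFactor = protocol$mb_factor,
    SliceReadoutTime = protocol$slice_dt,
    EchoTime = protocol$te,
    VolumeOrder = protocol$volume_order,
    Seed = as.integer(seed)
  )
  series <- structure(list(
    data = data, protocol = protocol, annotations = ann,
    motion = motion, corrections = character(0)
  ), class = "asl_series")
  structure(list(series = series, calib = calib, sidecar = sidecar,
                 truth = phantom), class = "asl_dataset")
}

#' @export
print.asl_dataset <- function(x, ...) {
  d <- dim(x$series$data)
  cat(sprintf("SMS PCASL dataset: %dx%dx%d, %d ASL volumes + %d calibration images\n",
              d[1], d[2], d[3], d[4], length(x$calib)))
  cat(sprintf("  seed %d; corrections applied: %s\n", x$sidecar$Seed,
              if (length(x$series$corrections)) paste(x$series$corrections, collapse = ", ")
              else "none"))
  invisible(x)
}
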