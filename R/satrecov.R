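#' Saturation-recovery signal model
#'
#' Longitudinal magnetisation regrowth after a pre-saturation pulse:
#' `S(t) = m0 * (1 - exp(-t_sat / t1))`. This is the model fitted voxelwise
#' to the control images to estimate tissue T1 and remove the
#' slice-timing-dependent component of the banding artefact.
#'
#' @param m0 Equilibrium signal (a.u.).
#' @param t1 Longitudinal relaxation time, seconds (> 0).
#' @param t_sat Time since saturation, seconds (>= 0).
#' @return Signal in the units of `m0`; vectorised.
#' @examples
#' satrecov_signal(100, 1.3, 1.3)  # 100 * (1 - exp(-1))
#' @export
satrecov_signal <- function(m0, t1, t_sat) {
  if (any(t1 <= 0)) stop("'t1' must be positive")
  if (any(t_sat < 0)) stop("'t_sat' must be non-negative")
  m0 * (1 - exp(-t_sat / t1))
}

# Saturation times for every (voxel, control volume) pair, honouring the
# slice each voxel occupied at acquisition: the per-slice t_sat profile is
# translated by the volume's motion (trilinear, so sub-voxel positions
# interpolate between adjacent slice timings).
satrecov_tsat_fields <- function(protocol, pld, motion = NULL, dims) {
  slices <- seq_len(dims[3]) - 1
  tsat <- sat_time(protocol, pld, slices)
  field <- array(rep(tsat, each = dims[1] * dims[2]), dims)
  if (!is.null(motion) && any(motion != 0))
    field <- translate_volume(field, -motion, fill = NA_real_)
  field
}

#' Fit the saturation-recovery model to the control images
#'
#' Voxelwise bounded nonlinear least squares of [satrecov_signal()] over all
#' control volumes of the timeseries, each evaluated at its slice-specific
#' saturation time (label duration + PLD + within-band readout offset). With
#' a motion trace, the per-slice timing field is translated per volume so the
#' time matches the slice each voxel occupied at acquisition.
#'
#' T1 is constrained to [0.1, 5] s; voxels whose fit fails to converge or
#' pins T1 at a bound are flagged invalid and later corrected with the
#' median T1 of the valid voxels.
#'
#' @param series An `asl_series` (typically motion-corrected).
#' @param mask Logical 3D array of voxels to fit.
#' @param motion Optional per-volume translation matrix (voxels); defaults to
#'   the series' own trace.
#' @param tol,maxit Optimiser tolerance and iteration cap.
#' @return An object of class `banding_model` with `m0t_map`, `t1t_map`,
#'   `valid`, `fit_mask`, `t1_median`, `band_size`, and (once estimated)
#'   `empirical_gradient`.
#' @export
fit_satrecov <- function(series, mask, motion = series$motion,
                         tol = 1e-8, maxit = 50L) {
  protocol <- series$protocol
  ann <- series$annotations
  d <- dim(series$data)[1:3]
  if (!any(mask)) stop("empty fit mask")
  ctrl <- which(!ann$is_label)
  if (length(unique(ann$pld[ctrl])) < 2 && band_size(protocol) < 2)
    stop("need >= 2 distinct saturation times to fit")

  vidx <- which(mask)
  V <- length(vidx)
  obs <- matrix(0, V, length(ctrl))
  tsat <- matrix(0, V, length(ctrl))
  for (k in seq_along(ctrl)) {
    j <- ctrl[k]
    obs[, k] <- series$data[, , , j][vidx]
    m <- if (is.null(motion)) c(0, 0, 0) else motion[j, ]
    tf <- satrecov_tsat_fields(protocol, ann$pld[j], m, d)
    tsat[, k] <- tf[vidx]
  }
  good_t <- is.finite(tsat)
  tsat[!good_t] <- protocol$label_dur  # weight zero below
  w <- matrix(1, V, ncol(obs))
  w[!good_t] <- 0
  obs[!is.finite(obs)] <- 0

  model <- function(par) par[, 1] * (1 - exp(-tsat / par[, 2]))
  x0 <- cbind(apply(obs, 1, max), 1.3)
  fit <- vlm_fit(model, x0, lower = c(0, 0.1), upper = c(Inf, 5),
                 obs = obs, w = w, tol = tol, maxit = maxit)

  t1 <- fit$par[, 2]
  valid_v <- fit$converged & t1 > 0.1 + 1e-6 & t1 < 5 - 1e-6
  if (!any(valid_v)) stop("saturation-recovery fit failed in every voxel")

  m0t <- array(NA_real_, d); t1t <- array(NA_real_, d)
  valid <- array(FALSE, d)
  m0t[vidx] <- fit$par[, 1]
  t1t[vidx] <- t1
  valid[vidx] <- valid_v
  structure(list(
    m0t_map = m0t, t1t_map = t1t, valid = valid, fit_mask = mask,
    t1_median = stats::median(t1[valid_v]),
    band_size = band_size(protocol),
    empirical_gradient = NA_real_
  ), class = "banding_model")
}

#' Voxelwise tissue T1 from a banding model
#'
#' Returns the fitted T1 map with invalid-fit voxels (and voxels outside the
#' fit mask) replaced by the mask-median T1, so downstream corrections and
#' kinetic fits never use an unfitted value.
#'
#' @param model A `banding_model` from [fit_satrecov()].
#' @param dims 3D grid dimensions.
#' @return A 3D array of T1 values in seconds.
#' @export
effective_t1 <- function(model, dims) {
  t1 <- model$t1t_map
  t1[!model$valid | !is.finite(t1)] <- model$t1_median
  t1
}

# Static (zero-motion) satrecov correction field for one PLD:
# C = (1 - exp(-(tau+pld)/t1)) / (1 - exp(-t_sat(slice)/t1)).
satrecov_factor_field <- function(model, protocol, pld, dims,
                                  motion = NULL) {
  t1 <- effective_t1(model, dims)
  t_nom <- protocol$label_dur + pld
  tf <- satrecov_tsat_fields(protocol, pld, motion, dims)
  tf[!is.finite(tf)] <- t_nom
  (1 - exp(-t_nom / t1)) / (1 - exp(-tf / t1))
}

#' Correct the saturation-recovery banding of an ASL timeseries
#'
#' Multiplies every volume (label and control) by the factor that normalises
#' each slice's signal to the value it would have had if all slices were
#' acquired simultaneously at the nominal PLD. Voxels with an invalid T1 fit
#' use the mask-median T1. The series carries a provenance flag; correcting
#' twice is an error.
#'
#' @param series An `asl_series`.
#' @param model A `banding_model` from [fit_satrecov()].
#' @param motion Optional per-volume translations so the correction tracks
#'   the slice each voxel occupied at acquisition; defaults to none (static
#'   correction).
#' @return The corrected `asl_series`.
#' @export
satrecov_correct <- function(series, model, motion = NULL) {
  if ("satrecov" %in% series$corrections)
    stop("series is already saturation-recovery corrected")
  d <- dim(series$data)[1:3]
  ann <- series$annotations
  for (j in seq_len(nrow(ann))) {
    m <- if (is.null(motion)) NULL else motion[j, ]
    fld <- satrecov_factor_field(model, series$protocol, ann$pld[j], d, m)
    series$data[, , , j] <- series$data[, , , j] * fld
  }
  series$corrections <- c(series$corrections, "satrecov")
  series
}
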