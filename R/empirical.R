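#' Estimate the residual within-band intensity gradient
#'
#' The banding that remains after saturation-recovery correction is modelled
#' as a linear function of within-band slice position: for each subject and
#' each band, the mean intensity of the grey+white-matter-masked slices is
#' regressed on within-band position by ordinary least squares, the slope is
#' divided by the band-mean intensity to give a relative gradient, and the
#' relative gradients are averaged across bands and then across subjects to
#' give a single scalar `g`.
#'
#' @param calibs A calibration image (3D array) or a list of them, one per
#'   subject. Images should already be saturation-recovery corrected (for a
#'   long-TR calibration image that correction is the identity).
#' @param pv_gm,pv_wm Tissue partial-volume maps (single arrays shared by all
#'   subjects, or lists parallel to `calibs`).
#' @param band_size Slices per band.
#' @param threshold Mask threshold on `pv_gm + pv_wm` (default 0.7).
#' @return The estimated relative gradient (dimensionless, per within-band
#'   position).
#' @export
fit_empirical_banding <- function(calibs, pv_gm, pv_wm, band_size,
                                  threshold = 0.7) {
  if (!is.list(calibs)) calibs <- list(calibs)
  n <- length(calibs)
  getpv <- function(x, i) if (is.list(x)) x[[i]] else x
  subject_g <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    img <- calibs[[i]]
    mask <- (getpv(pv_gm, i) + getpv(pv_wm, i)) > threshold
    d <- dim(img)
    nb <- d[3] %/% band_size
    band_g <- c()
    for (b in seq_len(nb)) {
      sl <- (b - 1) * band_size + seq_len(band_size)  # 1-based slices
      means <- vapply(sl, function(s) {
        msk <- mask[, , s]
        if (!any(msk)) NA_real_ else mean(img[, , s][msk])
      }, numeric(1))
      ok <- is.finite(means)
      if (sum(ok) < 2) next  # band skipped
      p <- (sl - 1) %% band_size
      slope <- stats::cov(p[ok], means[ok]) / stats::var(p[ok])
      band_g <- c(band_g, slope / mean(means[ok]))
    }
    if (length(band_g)) subject_g[i] <- mean(band_g)
  }
  if (all(is.na(subject_g)))
    stop("no band had >= 2 masked slices in any subject")
  mean(subject_g, na.rm = TRUE)
}

# Multiplicative within-band gradient factor per slice (0-based), normalised
# to average 1 over each band.
empirical_band_factor <- function(g, band_size, slices) {
  p <- slices %% band_size
  1 + g * (p - (band_size - 1) / 2)
}

#' Remove the within-band linear intensity gradient
#'
#' Divides every voxel by `1 + g * (p - (band_size - 1) / 2)` where `p` is
#' the slice's within-band position; the correction factors average to one
#' over each band, so band-mean intensity is preserved. The same correction
#' applies to every volume (it is PLD-independent).
#'
#' @param x A 3D image, a 4D timeseries array, or an `asl_series`.
#' @param g Relative gradient (from [fit_empirical_banding()]).
#' @param band_size Slices per band.
#' @return Corrected object of the same type. An `asl_series` gains an
#'   `"empirical"` provenance flag; correcting a series twice is an error.
#' @export
empirical_correct <- function(x, g, band_size) {
  if (!is.finite(g)) stop("'g' must be finite")
  if (inherits(x, "asl_series")) {
    if ("empirical" %in% x$corrections)
      stop("series is already empirical-banding corrected")
    x$data <- empirical_correct(x$data, g, band_size)
    x$corrections <- c(x$corrections, "empirical")
    return(x)
  }
  d <- dim(x)
  nz <- d[3]
  fac <- empirical_band_factor(g, band_size, seq_len(nz) - 1)
  if (any(fac <= 0)) stop("|g| too large: correction factor <= 0")
  f3 <- array(rep(fac, each = d[1] * d[2]), d[1:3])
  if (length(d) == 3) x / f3 else {
    for (j in seq_len(d[4])) x[, , , j] <- x[, , , j] / f3
    x
  }
}

# Scanner-frame empirical correction field (to multiply), optionally
# translated by a volume's motion so it tracks anatomy.
empirical_factor_field <- function(g, band_size, dims, motion = NULL) {
  fac <- empirical_band_factor(g, band_size, seq_len(dims[3]) - 1)
  fld <- array(rep(1 / fac, each = dims[1] * dims[2]), dims)
  if (!is.null(motion) && any(motion != 0)) {
    fld <- translate_volume(fld, -motion, fill = NA_real_)
    fld[!is.finite(fld)] <- 1
  }
  fld
}

#' @export
print.banding_model <- function(x, ...) {
  cat("ASL banding model\n")
  cat(sprintf("  T1 fit      : %d voxels, %d valid; median T1 %.3f s\n",
              sum(x$fit_mask), sum(x$valid), x$t1_median))
  cat(sprintf("  band size   : %d slices\n", x$band_size))
  if (is.finite(x$empirical_gradient))
    cat(sprintf("  gradient g  : %.5f per slice position\n", x$empirical_gradient))
  invisible(x)
}
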