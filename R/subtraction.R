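#' Design matrix for label-control subtraction at one PLD
#'
#' Two regressors: a static column of ones and a perfusion column coded
#' +1/2 for control and -1/2 for label volumes, so the OLS coefficient of
#' the perfusion column equals the control-minus-label difference dM.
#'
#' @param annotations Volume annotations (see [volume_annotations()]).
#' @param pld_index 1-based index of the PLD.
#' @return A list: `X` (n x 2 design matrix), `volumes` (timeseries indices
#'   of the rows).
#' @export
build_design <- function(annotations, pld_index) {
  rows <- which(annotations$pld_index == pld_index)
  if (!length(rows)) stop("no volumes at that PLD")
  lab <- annotations$is_label[rows]
  if (all(lab) || !any(lab))
    stop("need at least one label and one control volume at each PLD")
  X <- cbind(static = rep(1, length(rows)),
             perfusion = ifelse(lab, -0.5, 0.5))
  list(X = X, volumes = rows)
}

#' Motion-resolved intensity-correction factor fields
#'
#' Builds, for every volume of the timeseries, the multiplicative intensity
#' correction field (saturation-recovery normalisation, within-band gradient
#' removal, and optional bias-field division) evaluated at the slice each
#' voxel occupied at that volume's acquisition: the scanner-frame fields are
#' translated by the volume's motion, so the corrections track anatomy
#' rather than grid position. With zero motion this reduces exactly to the
#' static correction.
#'
#' @param model A `banding_model` (or `NULL` to skip the saturation-recovery
#'   component).
#' @param protocol An [asl_protocol()].
#' @param motion Per-volume translation matrix (voxels), or `NULL`.
#' @param g Within-band gradient (or `NULL` to skip).
#' @param bias Multiplicative bias field to divide out (or `NULL`).
#' @param dims 3D grid dimensions.
#' @return A 4D array of per-volume correction factors (multiply the
#'   motion-corrected data by it).
#' @export
motion_resolved_factors <- function(model, protocol, motion = NULL,
                                    g = NULL, bias = NULL,
                                    dims = dim(model$t1t_map)) {
  ann <- volume_annotations(protocol)
  nvol <- nrow(ann)
  out <- array(1, c(dims, nvol))
  inv_bias <- if (!is.null(bias)) 1 / bias else NULL
  for (j in seq_len(nvol)) {
    m <- if (is.null(motion)) NULL else motion[j, ]
    fld <- array(1, dims)
    if (!is.null(model))
      fld <- fld * satrecov_factor_field(model, protocol, ann$pld[j], dims, m)
    if (!is.null(g) && is.finite(g) && g != 0)
      fld <- fld * empirical_factor_field(g, band_size(protocol), dims, m)
    if (!is.null(inv_bias)) {
      bf <- if (is.null(m) || all(m == 0)) inv_bias else {
        b <- translate_volume(inv_bias, -m, fill = NA_real_)
        b[!is.finite(b)] <- 1
        b
      }
      fld <- fld * bf
    }
    fld[!is.finite(fld)] <- 1
    out[, , , j] <- fld
  }
  out
}

#' Motion-correct an ASL timeseries with a known motion trace
#'
#' Translates each volume back by its motion (trilinear interpolation) and
#' records which voxels had full in-FOV support in every volume.
#'
#' @param series An `asl_series`.
#' @param motion Per-volume translations (voxels); defaults to the series'.
#' @return The series with realigned data (the motion trace is kept so that
#'   [subtract_glm()] can exclude voxels that left the field of view).
#' @export
realign_series <- function(series, motion = series$motion) {
  if (!is.null(motion) && any(motion != 0)) {
    for (j in seq_len(dim(series$data)[4])) {
      m <- motion[j, ]
      if (all(m == 0)) next
      series$data[, , , j] <- translate_volume(series$data[, , , j], -m)
    }
  }
  series$realigned <- TRUE
  series
}

#' GLM label-control subtraction with FOV exclusion
#'
#' Per voxel and per PLD, fits the two-column design of [build_design()] by
#' ordinary least squares to the (corrected, motion-aligned) timeseries.
#' Voxels that left the acquisition field of view in any volume are excluded
#' entirely. The effective PLD of each voxel is the nominal PLD plus the
#' readout offset of the slice it occupies in the reference geometry. The
#' voxelwise noise SD is estimated from the pooled GLM residuals and
#' propagated to a per-PLD variance scale for downstream weighting.
#'
#' @param series A fully intensity-corrected `asl_series` (motion-aligned if
#'   a motion trace exists).
#' @param motion Per-volume translations used for FOV exclusion (voxels);
#'   `NULL` for none.
#' @param mask Optional logical analysis mask.
#' @return An object of class `asl_diff`: `dm` (4D, one 3D volume per PLD),
#'   `eff_pld` (4D), `valid_mask`, `n_used`, `noise_sd` (3D), `var_scale`
#'   (per-PLD multiplier such that var(dM) = noise_sd^2 * var_scale).
#' @export
subtract_glm <- function(series, motion = series$motion, mask = NULL) {
  protocol <- series$protocol
  ann <- series$annotations
  d <- dim(series$data)[1:3]
  npld <- length(protocol$plds)

  valid <- array(TRUE, d)
  if (!is.null(motion)) {
    for (j in seq_len(nrow(ann))) {
      m <- motion[j, ]
      if (all(m == 0)) next
      valid <- valid & translate_valid(d, -m)
    }
  }
  if (!is.null(mask)) valid <- valid & mask
  if (!any(valid)) stop("no voxel remains inside the FOV at every timepoint")

  vidx <- which(valid)
  V <- length(vidx)
  Y <- matrix(0, V, nrow(ann))
  for (j in seq_len(nrow(ann))) Y[, j] <- series$data[, , , j][vidx]

  dm <- array(NA_real_, c(d, npld))
  n_used <- integer(npld)
  var_scale <- numeric(npld)
  rss <- numeric(V)
  dof <- 0L
  for (k in seq_len(npld)) {
    des <- build_design(ann, k)
    X <- des$X
    XtXinv <- solve(crossprod(X))
    beta <- Y[, des$volumes, drop = FALSE] %*% X %*% XtXinv
    resid <- Y[, des$volumes, drop = FALSE] - beta %*% t(X)
    rss <- rss + rowSums(resid^2)
    dof <- dof + length(des$volumes) - 2L
    vol <- array(NA_real_, d)
    vol[vidx] <- beta[, 2]
    dm[, , , k] <- vol
    n_used[k] <- length(des$volumes)
    var_scale[k] <- XtXinv[2, 2]
  }
  noise_sd <- array(NA_real_, d)
  noise_sd[vidx] <- sqrt(rss / max(dof, 1L))

  off <- slice_offset(protocol, seq_len(d[3]) - 1)
  eff <- array(0, c(d, npld))
  for (k in seq_len(npld)) {
    eff[, , , k] <- array(rep(protocol$plds[k] + off, each = d[1] * d[2]), d)
  }
  structure(list(
    dm = dm, eff_pld = eff, valid_mask = valid, n_used = n_used,
    noise_sd = noise_sd, var_scale = var_scale, protocol = protocol
  ), class = "asl_diff")
}

#' @export
print.asl_diff <- function(x, ...) {
  d <- dim(x$dm)
  cat(sprintf("ASL difference data: %dx%dx%d, %d PLDs\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  valid voxels : %d\n", sum(x$valid_mask)))
  cat(sprintf("  volumes used : %s\n", paste(x$n_used, collapse = ", ")))
  cat(sprintf("  median noise SD: %.4g a.u.\n",
              stats::median(x$noise_sd[x$valid_mask])))
  invisible(x)
}
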