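#' @export
print.asl_fit <- function(x, ...) {
  cat("ASL kinetic model fit (MAP, Buxton model + macrovascular ARD)\n")
  cat(sprintf("  voxels fitted : %d (%d non-converged)\n", sum(x$mask),
              sum(!x$converged[x$mask], na.rm = TRUE)))
  s <- summary(x)
  if (x$calibrated)
    cat(sprintf("  median CBF    : %.4g ml/100g/min\n", s["cbf_median"]))
  else
    cat(sprintf("  median f      : %.4g a.u.\n", s["f_median"]))
  cat(sprintf("  median ATT    : %.3f s\n", s["att_median"]))
  cat(sprintf("  aBV > 0       : %d voxels\n", s["abv_positive"]))
  invisible(x)
}

#' Summary statistics of an ASL kinetic fit
#'
#' Perfusion summaries clip negative estimates to zero (negative values are
#' permitted during optimisation to avoid boundary bias, but are not
#' physically meaningful in reports).
#'
#' @param object An `asl_fit`.
#' @param ... Unused.
#' @return Named numeric vector of map summaries.
#' @export
summary.asl_fit <- function(object, ...) {
  msk <- object$mask
  f <- pmax(object$f[msk], 0)
  out <- c(f_median = stats::median(f, na.rm = TRUE),
           att_median = stats::median(object$att[msk], na.rm = TRUE),
           att_mean = mean(object$att[msk], na.rm = TRUE),
           abv_positive = sum(object$abv[msk] > 0, na.rm = TRUE),
           n_voxels = sum(msk))
  if (object$calibrated) {
    cbf <- pmax(object$cbf[msk], 0)
    out <- c(out, cbf_median = stats::median(cbf, na.rm = TRUE),
             cbf_mean = mean(cbf, na.rm = TRUE))
  }
  out
}

#' @export
coef.asl_fit <- function(object, ...) {
  msk <- object$mask
  c(f = mean(object$f[msk], na.rm = TRUE),
    att = mean(object$att[msk], na.rm = TRUE),
    abv = mean(object$abv[msk], na.rm = TRUE),
    att_art = mean(object$att_art[msk], na.rm = TRUE))
}

#' @export
fitted.asl_fit <- function(object, ...) {
  const <- object$constants
  tau <- object$protocol$label_dur
  f <- object$f[object$vidx]; att <- object$att[object$vidx]
  abv <- object$abv[object$vidx]; aa <- object$att_art[object$vidx]
  t1a <- object$t1app[object$vidx]
  buxton_tissue(object$times, f, att, tau, t1a,
                const$t1_blood, const$alpha, 1) +
    buxton_arterial(object$times, abv * object$abv_scale, aa, tau,
                    const$t1_blood, const$alpha, 1)
}

#' @export
residuals.asl_fit <- function(object, ...) {
  object$obs - fitted(object)
}

#' Slice montage of fitted perfusion and transit-time maps
#'
#' @param x An `asl_fit`.
#' @param slice 1-based slice to display (default: middle).
#' @param ... Passed to [graphics::image()].
#' @export
plot.asl_fit <- function(x, slice = NULL, ...) {
  d <- dim(x$f)
  if (is.null(slice)) slice <- d[3] %/% 2
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  fmap <- if (x$calibrated) x$cbf else x$f
  graphics::image(fmap[, , slice], axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "inferno"),
                  main = if (x$calibrated) "CBF (ml/100g/min)" else "f (a.u.)",
                  ...)
  graphics::image(x$att[, , slice], axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "ATT (s)", ...)
  invisible(x)
}
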