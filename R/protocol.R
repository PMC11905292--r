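#' Acquisition protocol for an SMS multi-delay PCASL scan
#'
#' Describes the timing and slice geometry of a simultaneous multi-slice (SMS)
#' pseudo-continuous ASL acquisition: label duration, the post-labelling delay
#' (PLD) schedule with per-PLD repeat counts, the slice/band layout and the
#' per-slice readout time. The protocol is the single source of truth for the
#' slice -> band -> time mapping used by every other module.
#'
#' Slices are grouped into `mb_factor` contiguous bands of
#' `n_slices / mb_factor` slices along the third voxel axis; the slice with
#' within-band position `p` (0-based acquisition order, ascending) is excited
#' `p * slice_dt` seconds after the start of the readout, so its effective PLD
#' is the nominal PLD plus that offset.
#'
#' @param label_dur Label duration tau in seconds.
#' @param plds Post-labelling delays in seconds, strictly increasing.
#' @param repeats Number of label/control pairs acquired at each PLD.
#' @param n_slices Total number of slices (third voxel axis).
#' @param mb_factor Multiband factor, i.e. number of simultaneously excited
#'   bands. Must divide `n_slices`.
#' @param slice_dt Readout time per slice excitation in seconds.
#' @param te Echo time in seconds.
#' @param calib_tr Repetition time of the calibration images in seconds
#'   (long, so they are treated as fully relaxed).
#' @param volume_order Ordering of the ASL timeseries volumes. `"lc"`: for
#'   each PLD in turn, `repeats` label/control pairs (label first);
#'   `"cl"`: control first.
#' @return An object of class `asl_protocol`.
#' @examples
#' p <- asl_protocol()
#' band_size(p)
#' n_volumes(p)
#' @export
asl_protocol <- function(label_dur = 1.5,
                         plds = c(0.2, 0.7, 1.2, 1.7, 2.2),
                         repeats = c(6L, 6L, 6L, 10L, 15L),
                         n_slices = 60L,
                         mb_factor = 6L,
                         slice_dt = 0.059,
                         te = 0.019,
                         calib_tr = 8.0,
                         volume_order = c("lc", "cl")) {
  volume_order <- match.arg(volume_order)
  if (length(plds) != length(repeats))
    stop("'plds' and 'repeats' must have the same length")
  if (any(diff(plds) <= 0)) stop("'plds' must be strictly increasing")
  if (any(repeats < 1)) stop("all 'repeats' must be >= 1")
  if (n_slices %% mb_factor != 0)
    stop("'n_slices' must be divisible by 'mb_factor'")
  if (label_dur <= 0 || slice_dt < 0) stop("invalid timing parameters")
  structure(list(
    label_dur = label_dur, plds = as.numeric(plds),
    repeats = as.integer(repeats), n_slices = as.integer(n_slices),
    mb_factor = as.integer(mb_factor), slice_dt = slice_dt,
    te = te, calib_tr = calib_tr, volume_order = volume_order
  ), class = "asl_protocol")
}

#' @rdname asl_protocol
#' @param protocol An `asl_protocol`.
#' @export
band_size <- function(protocol) protocol$n_slices %/% protocol$mb_factor

#' @rdname asl_protocol
#' @export
n_volumes <- function(protocol) 2L * sum(protocol$repeats)

#' Slice geometry helpers
#'
#' 0-based slice indexing throughout: slice `s` belongs to band
#' `floor(s / band_size)`, its within-band (acquisition-order) position is
#' `s %% band_size`, and its excitation is delayed by `p * slice_dt` seconds
#' relative to the first excitation.
#'
#' @param protocol An `asl_protocol`.
#' @param slice 0-based slice index (vectorised).
#' @return Integer band index, integer within-band position, or offset in
#'   seconds respectively.
#' @export
slice_band <- function(protocol, slice) {
  .check_slice(protocol, slice)
  as.integer(slice) %/% band_size(protocol)
}

#' @rdname slice_band
#' @export
slice_pos <- function(protocol, slice) {
  .check_slice(protocol, slice)
  as.integer(slice) %% band_size(protocol)
}

#' @rdname slice_band
#' @export
slice_offset <- function(protocol, slice) {
  slice_pos(protocol, slice) * protocol$slice_dt
}

.check_slice <- function(protocol, slice) {
  if (any(slice < 0 | slice >= protocol$n_slices))
    stop("slice index out of range [0, n_slices)")
  invisible(TRUE)
}

#' Time since pre-saturation for a given slice and PLD
#'
#' The pre-saturation pulse precedes the labelling module, so the recovery
#' interval at image acquisition is the label duration plus the PLD plus the
#' slice-specific readout offset.
#'
#' @param protocol An `asl_protocol`.
#' @param pld Nominal post-labelling delay in seconds.
#' @param slice 0-based slice index (vectorised).
#' @return Saturation recovery time in seconds.
#' @examples
#' sat_time(asl_protocol(), pld = 0.2, slice = 0)  # 1.7
#' @export
sat_time <- function(protocol, pld, slice) {
  protocol$label_dur + pld + slice_offset(protocol, slice)
}

#' Per-volume annotations of the ASL timeseries
#'
#' @param protocol An `asl_protocol`.
#' @return A data.frame with one row per timeseries volume: `volume` (1-based
#'   index), `pld_index` (1-based), `pld` (seconds), `is_label`.
#' @export
volume_annotations <- function(protocol) {
  npld <- length(protocol$plds)
  pld_index <- rep(seq_len(npld), times = 2L * protocol$repeats)
  first_label <- protocol$volume_order == "lc"
  is_label <- unlist(lapply(protocol$repeats, function(r)
    rep(c(first_label, !first_label), r)))
  data.frame(volume = seq_along(pld_index),
             pld_index = pld_index,
             pld = protocol$plds[pld_index],
             is_label = is_label)
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat("SMS PCASL acquisition protocol\n")
  cat(sprintf("  label duration : %.3g s\n", x$label_dur))
  cat(sprintf("  PLDs (s)       : %s\n", paste(x$plds, collapse = ", ")))
  cat(sprintf("  repeats        : %s  (%d ASL volumes)\n",
              paste(x$repeats, collapse = ", "), n_volumes(x)))
  cat(sprintf("  slices         : %d in %d bands of %d, %.0f ms/slice readout\n",
              x$n_slices, x$mb_factor, band_size(x), 1000 * x$slice_dt))
  cat(sprintf("  TE %.0f ms, calibration TR %.3g s, order '%s'\n",
              1000 * x$te, x$calib_tr, x$volume_order))
  invisible(x)
}
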