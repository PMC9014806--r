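#' Spatiotemporal SVD clutter filter
#'
#' Reshapes the IQ stack into a 2-D Casorati matrix (space along rows,
#' ordered `axial` fastest then `lateral`; slow time along columns), takes
#' its singular value decomposition, zeroes the first `cutoff` (low-order,
#' tissue) singular values, and reconstructs the stack. Tissue echoes are
#' spatially coherent and slowly varying, so they concentrate in the
#' low-order singular components, while flowing microbubbles spread over the
#' higher orders. Only the low-order side is removed; no high-order
#' truncation is applied.
#'
#' With `cutoff = "adaptive"` the cutoff index is chosen by
#' [adaptive_cutoff()] on the singular-value spectrum.
#'
#' @param iq an [iq_ensemble] with at least 2 frames.
#' @param cutoff number of leading singular values to zero (0 = identity), or
#'   `"adaptive"`.
#' @param adaptive_bounds `[min, max]` window passed to [adaptive_cutoff()].
#' @return list with `iq` (filtered ensemble) and `spectrum` (class
#'   `singular_spectrum`: `values`, descending; `cutoff`).
#' @export
svd_clutter_filter <- function(iq, cutoff = "adaptive",
                               adaptive_bounds = c(2L, 40L)) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  d <- dim(iq$data)
  stop_if(d[3] < 2, "clutter filtering needs at least 2 frames")
  nspace <- d[1] * d[2]
  casorati <- matrix(iq$data, nrow = nspace, ncol = d[3])
  sv <- svd(casorati)
  if (identical(cutoff, "adaptive")) {
    cutoff <- adaptive_cutoff(sv$d, bounds = adaptive_bounds)
  }
  stop_if(!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0,
          "`cutoff` must be a non-negative index or \"adaptive\"")
  cutoff <- as.integer(cutoff)
  stop_if(cutoff >= min(nspace, d[3]),
          "cutoff must be below min(space, time) dimension")
  out <- iq
  if (cutoff > 0) {
    dd <- sv$d
    dd[seq_len(cutoff)] <- 0
    rec <- sv$u %*% (dd * Conj(t(sv$v)))
    out$data <- array(rec, dim = d)
  }
  list(iq = out,
       spectrum = structure(list(values = sv$d, cutoff = cutoff),
                            class = "singular_spectrum"))
}

#' Adaptive SVD cutoff from the singular-value spectrum
#'
#' Picks the knee of the spectrum as the point of maximum curvature (largest
#' discrete second difference) of the log singular-value curve, restricted to
#' a configurable index window. The returned cutoff is the number of leading
#' singular values to zero: if the largest curvature sits at spectrum
#' position `i` (the first value of the flat/noise regime), the cutoff is
#' `i - 1`. A spectrum with no knee above `tol` returns the lower bound with
#' a warning.
#'
#' @param values singular values, non-negative and non-increasing (>= 3).
#' @param bounds integer `[min, max]` window for the returned cutoff.
#' @param tol minimum log10-curvature regarded as a knee.
#' @return Integer cutoff index.
#' @export
adaptive_cutoff <- function(values, bounds = c(2L, 40L), tol = 1e-8) {
  stop_if(length(values) < 3, "need at least 3 singular values")
  stop_if(any(values < 0) || is.unsorted(rev(values)),
          "`values` must be non-negative and non-increasing")
  lo <- max(1L, as.integer(bounds[1])); hi <- as.integer(bounds[2])
  hi <- min(hi, length(values) - 2L)
  lv <- log10(pmax(values, .Machine$double.xmin))
  i <- 2:(length(values) - 1L)
  d2 <- lv[i - 1L] - 2 * lv[i] + lv[i + 1L]   # discrete curvature at i
  cut <- i - 1L                                # zeroing i-1 values puts the knee first
  keep <- cut >= lo & cut <= hi
  if (!any(keep) || max(d2[keep]) < tol) {
    warning("no spectral knee found; using configured minimum cutoff")
    return(lo)
  }
  cut[keep][which.max(d2[keep])]
}

#' Depth-dependent noise-equalization profile
#'
#' Applies the same SVD filtering to a bubble-free noise-reference ensemble,
#' computes the temporal mean power per pixel, averages laterally into a
#' per-depth-row profile, smooths it along depth (moving average, window 9
#' rows), and returns the reciprocal-root gain map that normalizes the
#' expected noise power to one everywhere in the field.
#'
#' @param noise_iq noise-reference [iq_ensemble] (same geometry as the data
#'   it will equalize).
#' @param cutoff passed to [svd_clutter_filter()]; use the cutoff applied to
#'   the data so reference and data are filtered identically.
#' @param smooth_window moving-average window (rows) along depth.
#' @return Object of class `noise_profile`: list with `gain` (matrix,
#'   strictly positive), `gain_per_row`, `power_per_row`.
#' @export
estimate_noise_profile <- function(noise_iq, cutoff = 0,
                                   smooth_window = 9L) {
  stop_if(!inherits(noise_iq, "iq_ensemble"), "`noise_iq` must be an iq_ensemble")
  filt <- if (identical(cutoff, 0) || identical(cutoff, 0L)) noise_iq
          else svd_clutter_filter(noise_iq, cutoff)$iq
  pow <- apply(Mod(filt$data)^2, c(1, 2), mean)
  row_pow <- rowMeans(pow)
  row_pow <- moving_average(row_pow, smooth_window)
  stop_if(any(row_pow <= 0), "degenerate noise reference (zero power rows)")
  gain_row <- 1 / sqrt(row_pow)
  gain <- matrix(gain_row, nrow = nrow(pow), ncol = ncol(pow))
  structure(list(gain = gain, gain_per_row = gain_row,
                 power_per_row = row_pow,
                 geometry = dim(noise_iq$data)[1:2]),
            class = "noise_profile")
}

#' Apply a noise-equalization gain map
#'
#' Pixel-wise multiplication of every frame by the gain map; a linear
#' operator that flattens the depth-dependent noise floor so microbubble
#' intensity is comparable throughout the field of view.
#'
#' @param iq an [iq_ensemble].
#' @param profile a [estimate_noise_profile()] result (matching geometry).
#' @return The equalized [iq_ensemble].
#' @export
apply_noise_equalization <- function(iq, profile) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  stop_if(!inherits(profile, "noise_profile"), "`profile` must be a noise_profile")
  stop_if(!identical(dim(iq$data)[1:2], as.integer(profile$geometry)),
          "geometry mismatch between IQ data and noise profile")
  stop_if(any(!is.finite(profile$gain)) || any(profile$gain <= 0),
          "noise-profile gains must be positive and finite")
  out <- iq
  out$data <- iq$data * array(profile$gain, dim = dim(iq$data))
  out
}

#' Diffraction-limited contrast power image (power Doppler)
#'
#' Accumulates per-pixel signal power (squared magnitude) over all frames.
#'
#' @param iq an [iq_ensemble].
#' @return Non-negative numeric matrix `[n_axial, n_lateral]`.
#' @export
power_doppler <- function(iq) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  apply(Mod(iq$data)^2, c(1, 2), sum)
}
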