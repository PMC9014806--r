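#' Upsample an IQ ensemble to the super-resolution grid
#'
#' Interpolates every frame onto a finer regular grid (default 5 um pitch)
#' with a tensor-product cubic interpolating spline. Interpolation is linear
#' in the data, so the operator is precomputed once per axis as an
#' interpolation matrix (spline through each unit impulse) and applied as
#' two matrix products per frame; values at original grid nodes are
#' preserved exactly.
#'
#' @param iq an [iq_ensemble].
#' @param target_pitch_um requested pitch (same for both axes unless a
#'   length-2 vector `[axial, lateral]`); must not exceed the native pitch.
#' @return The upsampled [iq_ensemble].
#' @export
upsample_iq <- function(iq, target_pitch_um = 5) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  tp <- rep(as.numeric(target_pitch_um), length.out = 2)
  stop_if(any(tp <= 0), "target pitch must be > 0")
  stop_if(tp[1] > iq$pitch_axial_um + 1e-9 || tp[2] > iq$pitch_lateral_um + 1e-9,
          "target pitch larger than native pitch")
  d <- dim(iq$data)
  Az <- spline_matrix((seq_len(d[1]) - 1) * iq$pitch_axial_um, tp[1])
  Ax <- spline_matrix((seq_len(d[2]) - 1) * iq$pitch_lateral_um, tp[2])
  out <- array(0 + 0i, dim = c(nrow(Az), nrow(Ax), d[3]))
  tAx <- t(Ax)
  for (f in seq_len(d[3])) {
    fr <- iq$data[, , f]
    out[, , f] <- (Az %*% Re(fr) %*% tAx) + 1i * (Az %*% Im(fr) %*% tAx)
  }
  iq_ensemble(out, tp[1], tp[2], iq$frame_rate_hz, iq$center_freq_mhz)
}

# n_new x n_old cubic-spline interpolation matrix from nodes `xs` to the
# regular grid of pitch `pitch` spanning the same extent
spline_matrix <- function(xs, pitch) {
  xnew <- seq(0, xs[length(xs)], by = pitch)
  A <- matrix(0, length(xnew), length(xs))
  e <- numeric(length(xs))
  for (j in seq_along(xs)) {
    e[] <- 0; e[j] <- 1
    A[, j] <- stats::spline(xs, e, xout = xnew, method = "fmm")$y
  }
  A
}

#' Gaussian microbubble point-spread-function model
#'
#' Separable 2-D Gaussian kernel rendered on the super-resolved grid,
#' truncated at +/- 3 sigma, normalized to unit peak. Represents the system
#' response to a single microbubble; widths are either supplied or fitted
#' from data with [fit_psf_sigma()].
#'
#' @param sigma_axial_um,sigma_lateral_um Gaussian standard deviations (um),
#'   each at least one grid pitch.
#' @param pitch_um rendering pitch (um).
#' @return Object of class `psf_model`: `kernel` (matrix, unit peak),
#'   `sigma_axial_um`, `sigma_lateral_um`, `pitch_um`.
#' @export
build_psf <- function(sigma_axial_um, sigma_lateral_um, pitch_um = 5) {
  assert_scalar_num(sigma_axial_um, "sigma_axial_um", positive = TRUE)
  assert_scalar_num(sigma_lateral_um, "sigma_lateral_um", positive = TRUE)
  assert_scalar_num(pitch_um, "pitch_um", positive = TRUE)
  stop_if(sigma_axial_um < pitch_um || sigma_lateral_um < pitch_um,
          "PSF width below one grid pitch")
  hz <- ceiling(3 * sigma_axial_um / pitch_um)
  hx <- ceiling(3 * sigma_lateral_um / pitch_um)
  gz <- exp(-((-hz:hz) * pitch_um)^2 / (2 * sigma_axial_um^2))
  gx <- exp(-((-hx:hx) * pitch_um)^2 / (2 * sigma_lateral_um^2))
  structure(list(kernel = outer(gz, gx), sigma_axial_um = sigma_axial_um,
                 sigma_lateral_um = sigma_lateral_um, pitch_um = pitch_um),
            class = "psf_model")
}

#' Fit PSF widths from the brightest isolated blob
#'
#' Least-squares Gaussian widths from the intensity-weighted second moments
#' of the magnitude image around its global maximum in the first frame. A
#' reproducible stand-in for manual per-dataset PSF adjustment; override by
#' passing explicit sigmas to [build_psf()].
#'
#' @param iq an [iq_ensemble] (ideally clutter-filtered).
#' @param halfwidth_px half-size of the fitting window, pixels.
#' @return list `sigma_axial_um`, `sigma_lateral_um`.
#' @export
fit_psf_sigma <- function(iq, halfwidth_px = 8L) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  fr <- Mod(iq$data[, , 1])
  pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  zi <- max(1, pk[1] - halfwidth_px):min(nrow(fr), pk[1] + halfwidth_px)
  xi <- max(1, pk[2] - halfwidth_px):min(ncol(fr), pk[2] + halfwidth_px)
  w <- fr[zi, xi]; w <- w / sum(w)
  zc <- sum(rowSums(w) * zi); xc <- sum(colSums(w) * xi)
  sz <- sqrt(sum(rowSums(w) * (zi - zc)^2)) * iq$pitch_axial_um
  sx <- sqrt(sum(colSums(w) * (xi - xc)^2)) * iq$pitch_lateral_um
  list(sigma_axial_um = max(sz, iq$pitch_axial_um),
       sigma_lateral_um = max(sx, iq$pitch_lateral_um))
}

#' Split overlapping microbubble populations in the conical Fourier domain
#'
#' Takes the 3-D FFT over (axial, lateral, slow time) and partitions every
#' spectral voxel into one of three cones by its apparent speed
#' `|f_t| / |k|` (temporal frequency over spatial-frequency magnitude,
#' converted to mm/s) relative to two increasing thresholds; the
#' zero-spatial-frequency plane goes to the slow cone. Each subset is
#' inverse-transformed, and because the cones partition the spectrum the
#' three subsets sum to the input exactly. Separating slow, intermediate and
#' fast bubbles before localization reduces PSF overlap between populations
#' moving at different speeds.
#'
#' @param iq an [iq_ensemble] with at least 8 frames.
#' @param speed_bounds_mm_s two strictly increasing speed thresholds (mm/s).
#' @return list of three [iq_ensemble]s: `slow`, `mid`, `fast`.
#' @export
separate_mb_subsets <- function(iq, speed_bounds_mm_s = c(1, 5)) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  d <- dim(iq$data)
  stop_if(d[3] < 8, "need at least 8 frames for a usable temporal spectrum")
  v1 <- speed_bounds_mm_s[1]; v2 <- speed_bounds_mm_s[2]
  stop_if(!(v1 < v2), "speed thresholds must be strictly increasing")
  kz <- fft_freq(d[1], iq$pitch_axial_um * 1e-3)   # cycles / mm
  kx <- fft_freq(d[2], iq$pitch_lateral_um * 1e-3)
  ft <- fft_freq(d[3], 1 / iq$frame_rate_hz)       # Hz
  kmag <- sqrt(outer(kz^2, kx^2, "+"))
  K <- array(kmag, dim = d)
  FT <- array(rep(abs(ft), each = d[1] * d[2]), dim = d)
  speed <- ifelse(K > 0, FT / K, 0)                # mm/s; k = 0 plane -> slow
  spec <- stats::fft(iq$data)
  inv <- function(m) stats::fft(spec * m, inverse = TRUE) / prod(d)
  mk <- function(a) iq_ensemble(a, iq$pitch_axial_um, iq$pitch_lateral_um,
                                iq$frame_rate_hz, iq$center_freq_mhz)
  list(slow = mk(inv(speed <= v1)),
       mid  = mk(inv(speed > v1 & speed <= v2)),
       fast = mk(inv(speed > v2)))
}

fft_freq <- function(n, dsamp) {
  if (n == 1) return(0)
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * dsamp)
}

#' Localize microbubbles in one super-resolved frame
#'
#' Computes the normalized 2-D cross-correlation of the frame envelope
#' (magnitude) with the Gaussian PSF kernel, discards pixels scoring below
#' `min_corr`, takes 8-connected regional maxima of the surviving map as
#' centroids (plateaus collapse to their centroid), and enforces a minimum
#' separation by keeping the higher-scoring centroid of any close pair.
#' Scores are undefined (no detection) within half a kernel of the frame
#' border.
#'
#' @param frame complex or numeric matrix (one super-resolved frame).
#' @param psf a [build_psf()] model rendered at the frame's pitch.
#' @param min_corr correlation-score threshold in `[-1, 1]` (default 0.6).
#' @param min_sep_um minimum centroid separation; default PSF FWHM / 2.
#' @param pitch_um frame pitch (um), used to report physical positions.
#' @return data.frame with `z_um`, `x_um`, `score` (possibly 0 rows).
#' @export
localize_frame <- function(frame, psf, min_corr = 0.6, min_sep_um = NULL,
                           pitch_um = psf$pitch_um) {
  stop_if(!inherits(psf, "psf_model"), "`psf` must be a psf_model")
  env <- Mod(frame)
  stop_if(any(dim(psf$kernel) >= dim(env)), "PSF must be smaller than the frame")
  if (is.null(min_sep_um)) {
    min_sep_um <- 2.355 * min(psf$sigma_axial_um, psf$sigma_lateral_um) / 2
  }
  cc <- normxcorr2_same(env, psf$kernel)
  cc[!is.na(cc) & cc < min_corr] <- NA_real_
  pk <- regional_maxima(cc)
  if (nrow(pk) == 0) {
    return(data.frame(z_um = numeric(0), x_um = numeric(0), score = numeric(0)))
  }
  out <- data.frame(z_um = (pk[, 1] - 1) * pitch_um,
                    x_um = (pk[, 2] - 1) * pitch_um,
                    score = pk[, 3])
  out <- out[order(-out$score), ]
  enforce_min_separation(out, min_sep_um)
}

# FFT-based valid cross-correlation of img with kern (both real matrices)
xcorr_valid <- function(img, kern) {
  nz <- nrow(img); nx <- ncol(img)
  kz <- nrow(kern); kx <- ncol(kern)
  fz <- nz + kz - 1L; fx <- nx + kx - 1L
  pad <- function(m) { out <- matrix(0, fz, fx); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  conv <- Re(stats::fft(stats::fft(pad(img)) *
                        stats::fft(pad(kern[kz:1, kx:1, drop = FALSE])),
                        inverse = TRUE)) / (fz * fx)
  conv[kz:nz, kx:nx, drop = FALSE]
}

# normalized cross-correlation, result same size as img, NA border where the
# kernel does not fully fit
normxcorr2_same <- function(img, kern) {
  kz <- nrow(kern); kx <- ncol(kern)
  n_win <- kz * kx
  kn <- kern - mean(kern)
  k_ss <- sum(kn^2)
  num <- xcorr_valid(img, kn)
  ones <- matrix(1, kz, kx)
  ws <- xcorr_valid(img, ones)
  wss <- xcorr_valid(img * img, ones)
  var_win <- pmax(wss - ws^2 / n_win, 0)
  denom <- sqrt(var_win * k_ss)
  ncc <- ifelse(denom > 1e-12 * max(denom, 1e-300), num / denom, NA_real_)
  ncc <- pmin(pmax(ncc, -1), 1)
  out <- matrix(NA_real_, nrow(img), ncol(img))
  hz <- (kz - 1L) %/% 2L; hx <- (kx - 1L) %/% 2L
  out[(hz + 1L):(hz + nrow(ncc)), (hx + 1L):(hx + ncol(ncc))] <- ncc
  out
}

# strict 8-connected regional maxima of a matrix with NAs; plateaus collapse
# to their centroid. Returns matrix [row, col, value].
regional_maxima <- function(cc) {
  nz <- nrow(cc); nx <- ncol(cc)
  v <- cc; v[is.na(v)] <- -Inf
  pad <- matrix(-Inf, nz + 2L, nx + 2L)
  pad[2:(nz + 1L), 2:(nx + 1L)] <- v
  cand <- matrix(TRUE, nz, nx)
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    nb <- pad[(2:(nz + 1L)) + dz, (2:(nx + 1L)) + dx, drop = FALSE]
    cand <- cand & (v >= nb)
  }
  cand <- cand & is.finite(v)
  if (!any(cand)) return(matrix(numeric(0), 0, 3))
  lab <- EBImage::bwlabel(cand * 1L)
  out <- matrix(numeric(0), 0, 3)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    val <- v[idx[1, 1], idx[1, 2]]
    # confirm regional max: every non-member neighbor strictly below
    ok <- TRUE
    for (r in seq_len(nrow(idx))) {
      zi <- idx[r, 1]; xi <- idx[r, 2]
      for (dz in -1:1) for (dx in -1:1) {
        z2 <- zi + dz; x2 <- xi + dx
        if (z2 < 1 || z2 > nz || x2 < 1 || x2 > nx) next
        if (lab[z2, x2] != l && v[z2, x2] >= val) ok <- FALSE
      }
    }
    if (ok) out <- rbind(out, c(mean(idx[, 1]), mean(idx[, 2]), val))
  }
  out
}

# greedy minimum-separation pruning; input ordered by descending score
enforce_min_separation <- function(df, min_sep_um) {
  if (nrow(df) <= 1 || min_sep_um <= 0) { rownames(df) <- NULL; return(df) }
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (df$z_um[keep] - df$z_um[i])^2 + (df$x_um[keep] - df$x_um[i])^2
    keep[i] <- all(d2 >= min_sep_um^2)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localize every frame of a super-resolved ensemble
#'
#' Applies [localize_frame()] frame-by-frame and stacks the detections into
#' a centroid table.
#'
#' @inheritParams localize_frame
#' @param iq a super-resolved [iq_ensemble].
#' @param subset label stored with the detections (e.g. `"slow"`).
#' @return data.frame of class `centroid_set`: `frame`, `z_um`, `x_um`,
#'   `score`, `subset`.
#' @export
localize_ensemble <- function(iq, psf, min_corr = 0.6, min_sep_um = NULL,
                              subset = "all") {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  res <- lapply(seq_len(n_frames(iq)), function(f) {
    df <- localize_frame(iq$data[, , f], psf, min_corr, min_sep_um,
                         pitch_um = iq$pitch_axial_um)
    if (nrow(df)) cbind(frame = f, df) else
      data.frame(frame = integer(0), z_um = numeric(0), x_um = numeric(0),
                 score = numeric(0))
  })
  out <- do.call(rbind, res)
  out$subset <- if (nrow(out)) subset else character(0)
  class(out) <- c("centroid_set", "data.frame")
  out
}
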