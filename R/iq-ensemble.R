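#' Complex IQ frame ensemble
#'
#' The transport container of the pipeline: a stack of complex in-phase /
#' quadrature (IQ) demodulated frames on a regular physical grid, together
#' with the acquisition metadata needed downstream (pixel pitch, effective
#' frame rate, transmit center frequency).
#'
#' Internally the stack is a complex array of dimension
#' `n_axial x n_lateral x n_frames`; axial = depth (increasing downward),
#' lateral = width. Positions are measured in mm from the first pixel center
#' (0-based pixel index times pitch).
#'
#' @param data complex (or numeric) array `[n_axial, n_lateral, n_frames]`;
#'   a matrix is treated as a single frame.
#' @param pitch_axial_um,pitch_lateral_um pixel pitch in micrometers (> 0).
#' @param frame_rate_hz effective (post-compounding) frame rate in Hz.
#' @param center_freq_mhz transmit center frequency in MHz.
#' @return An object of class `iq_ensemble`.
#' @export
iq_ensemble <- function(data, pitch_axial_um, pitch_lateral_um,
                        frame_rate_hz = 1000, center_freq_mhz = 20) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stop_if(!is.array(data) || length(dim(data)) != 3L,
          "`data` must be an [n_axial, n_lateral, n_frames] array")
  stop_if(dim(data)[3] < 1L, "ensemble must contain at least one frame")
  if (!is.complex(data)) data <- data + 0i
  stop_if(any(!is.finite(Re(data))) || any(!is.finite(Im(data))),
          "IQ data must be finite")
  assert_scalar_num(pitch_axial_um, "pitch_axial_um", positive = TRUE)
  assert_scalar_num(pitch_lateral_um, "pitch_lateral_um", positive = TRUE)
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  assert_scalar_num(center_freq_mhz, "center_freq_mhz", positive = TRUE)
  structure(list(
    data = data,
    pitch_axial_um = pitch_axial_um,
    pitch_lateral_um = pitch_lateral_um,
    frame_rate_hz = frame_rate_hz,
    center_freq_mhz = center_freq_mhz
  ), class = "iq_ensemble")
}

#' @export
print.iq_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<iq_ensemble> %d x %d pixels, %d frames\n  pitch %.1f x %.1f um, %g Hz, %g MHz\n",
    d[1], d[2], d[3], x$pitch_axial_um, x$pitch_lateral_um,
    x$frame_rate_hz, x$center_freq_mhz))
  invisible(x)
}

#' @export
dim.iq_ensemble <- function(x) dim(x$data)

n_frames <- function(iq) dim(iq$data)[3]

same_geometry <- function(a, b) {
  identical(dim(a$data)[1:2], dim(b$data)[1:2]) &&
    isTRUE(all.equal(a$pitch_axial_um, b$pitch_axial_um)) &&
    isTRUE(all.equal(a$pitch_lateral_um, b$pitch_lateral_um))
}

#' Write / read an IQ ensemble to disk
#'
#' The on-disk form is a raw little-endian float64 binary holding the real
#' plane followed by the imaginary plane (column-major, frame-by-frame), with
#' a JSON sidecar (`<path>.json`) recording array dimensions, pixel pitch,
#' frame rate and center frequency.
#'
#' @param iq an [iq_ensemble].
#' @param path path of the binary payload; sidecar written at `<path>.json`.
#' @return `write_iq` returns `path` invisibly; `read_iq` an [iq_ensemble].
#' @export
write_iq <- function(iq, path) {
  stop_if(!inherits(iq, "iq_ensemble"), "`iq` must be an iq_ensemble")
  meta <- list(
    dim = dim(iq$data),
    pitch_axial_um = iq$pitch_axial_um,
    pitch_lateral_um = iq$pitch_lateral_um,
    frame_rate_hz = iq$frame_rate_hz,
    center_freq_mhz = iq$center_freq_mhz
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(Re(iq$data)), con, size = 8, endian = "little")
  writeBin(as.numeric(Im(iq$data)), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_iq
#' @export
read_iq <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  re <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  im <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  iq_ensemble(array(complex(real = re, imaginary = im), dim = meta$dim),
              meta$pitch_axial_um, meta$pitch_lateral_um,
              meta$frame_rate_hz, meta$center_freq_mhz)
}
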