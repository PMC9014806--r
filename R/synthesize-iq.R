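#' Render a synthetic IQ ensemble from microbubble trajectories
#'
#' Inverse imaging model of the localization stage: every bubble is rendered
#' as a complex Gaussian point-spread function at its sub-pixel position with
#' the carrier phase implied by its depth (4*pi*z/lambda), on top of
#' (a) low-rank tissue clutter - a sum of `clutter_rank` outer products of
#' smooth random spatial modes with slow (< 20 Hz) complex temporal modes,
#' scaled `clutter_db` dB above the mean bubble amplitude - and (b) circular
#' Gaussian noise whose variance grows with depth as
#' `exp(depth / noise_tau_mm)`.
#'
#' @param traj an [mb_trajectory_set] (may contain zero bubbles).
#' @param network the generating [vessel_network] (kept as ground truth).
#' @param config a [scene_config].
#' @return A list of class `synth_scene`: `iq` (full ensemble), `iq_bubbles`
#'   (bubble-only stack, ground truth), `traj`, `network`, `config`,
#'   `noise_sd_per_row`.
#' @export
synthesize_iq <- function(traj, network, config) {
  stop_if(!inherits(config, "scene_config"), "`config` must be a scene_config")
  stop_if(config$psf_sigma_axial_um < config$pitch_axial_um ||
          config$psf_sigma_lateral_um < config$pitch_lateral_um,
          "unresolvable rendering: PSF width smaller than one pixel pitch")
  g <- config_grid(config)
  nz <- g$n_axial; nx <- g$n_lateral; nf <- config$n_frames
  if (nrow(traj) > 0) {
    stop_if(any(traj$z_mm < -1e-9) || any(traj$z_mm > config$depth_mm + 1e-9) ||
            any(traj$x_mm < -1e-9) || any(traj$x_mm > config$width_mm + 1e-9),
            "trajectories fall outside the field of view")
  }
  with_seed(config$seed + 2L, function() {
    bub <- render_bubbles(traj, config, nz, nx, nf)
    out <- bub
    if (config$clutter_rank > 0) {
      cl <- render_clutter(config, nz, nx, nf)
      out <- out + cl
    }
    sd_row <- config$noise_sigma0 *
      exp((seq_len(nz) - 1) * config$pitch_axial_um / 1000 /
            (2 * config$noise_tau_mm))
    if (config$noise_sigma0 > 0) {
      noise <- array(complex(
        real = stats::rnorm(nz * nx * nf),
        imaginary = stats::rnorm(nz * nx * nf)), dim = c(nz, nx, nf))
      noise <- noise * array(sd_row, dim = c(nz, nx, nf))
      out <- out + noise
    }
    mk <- function(a) iq_ensemble(a, config$pitch_axial_um,
                                  config$pitch_lateral_um,
                                  config$frame_rate_hz, 20)
    structure(list(iq = mk(out), iq_bubbles = mk(bub), traj = traj,
                   network = network, config = config,
                   noise_sd_per_row = sd_row),
              class = "synth_scene")
  })
}

render_bubbles <- function(traj, config, nz, nx, nf) {
  out <- array(0 + 0i, dim = c(nz, nx, nf))
  if (nrow(traj) == 0) return(out)
  pz <- config$pitch_axial_um; px <- config$pitch_lateral_um
  sz <- config$psf_sigma_axial_um; sx <- config$psf_sigma_lateral_um
  hz <- ceiling(3 * sz / pz); hx <- ceiling(3 * sx / px)
  lambda_um <- 1540 / 20  # c / f0 at 20 MHz, in um (1540 m/s)
  phase0 <- stats::runif(max(traj$bubble), 0, 2 * pi)
  for (k in seq_len(nrow(traj))) {
    z_um <- traj$z_mm[k] * 1000; x_um <- traj$x_mm[k] * 1000
    iz <- round(z_um / pz) + 1L; ix <- round(x_um / px) + 1L
    zi <- max(1L, iz - hz):min(nz, iz + hz)
    xi <- max(1L, ix - hx):min(nx, ix + hx)
    if (!length(zi) || !length(xi)) next
    gz <- exp(-((zi - 1) * pz - z_um)^2 / (2 * sz^2))
    gx <- exp(-((xi - 1) * px - x_um)^2 / (2 * sx^2))
    ph <- 4 * pi * z_um / lambda_um + phase0[traj$bubble[k]]
    out[zi, xi, traj$frame[k]] <- out[zi, xi, traj$frame[k]] +
      traj$amplitude[k] * exp(1i * ph) * outer(gz, gx)
  }
  out
}

render_clutter <- function(config, nz, nx, nf) {
  r <- config$clutter_rank
  z <- (seq_len(nz) - 1) / max(nz - 1, 1)
  x <- (seq_len(nx) - 1) / max(nx - 1, 1)
  t <- (seq_len(nf) - 1) / config$frame_rate_hz
  # smooth random spatial modes, orthonormalized so the Casorati rank is
  # exactly r with a clean knee
  U <- vapply(seq_len(r), function(k) {
    fz <- stats::runif(1, 0.3, 2.5); fx <- stats::runif(1, 0.3, 2.5)
    as.vector(outer(cos(2 * pi * fz * z + stats::runif(1, 0, 2 * pi)),
                    cos(2 * pi * fx * x + stats::runif(1, 0, 2 * pi))))
  }, numeric(nz * nx))
  U <- qr.Q(qr(U))
  # slow complex temporal modes (< clutter_max_hz), orthonormalized
  TM <- vapply(seq_len(r), function(k) {
    ft <- stats::runif(1, 0.5, config$clutter_max_hz)
    exp(1i * (2 * pi * ft * t + stats::runif(1, 0, 2 * pi)))
  }, complex(nf))
  TM <- qr.Q(qr(TM))
  # mode strengths: mild decay, scaled so per-voxel clutter RMS sits
  # clutter_db above the mean bubble amplitude
  w <- seq(1, 0.5, length.out = r)
  target <- exp(config$mb_amp_meanlog) * 10^(config$clutter_db / 20)
  s <- target * sqrt(nz * nx * nf / sum(w^2))
  cas <- U %*% ((s * w) * Conj(t(TM)))
  array(cas, dim = c(nz, nx, nf))
}
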