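# shared fixtures and independent oracles

# small scene in the tissue-clutter regime of a tumor acquisition, scaled to
# a 1.5 x 2 mm field and 200 frames
paper_regime_config <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(depth_mm = 1.5, width_mm = 2, n_frames = 200, branch_depth = 2,
         seed = seed),
    list(...))
  do.call(scene_config, args)
}

make_scene <- function(config) {
  net <- generate_vessel_network(config)
  traj <- simulate_mb_trajectories(net, config)
  synthesize_iq(traj, net, config)
}

# hand-built trajectory table (bypasses the network generator)
manual_traj <- function(bubble, frame, z_mm, x_mm, amplitude = 1) {
  df <- data.frame(bubble = bubble, frame = frame, z_mm = z_mm, x_mm = x_mm,
                   amplitude = amplitude, segment = 1L)
  class(df) <- c("mb_trajectory_set", "data.frame")
  df
}

# two straight axial vessels 50 um apart laterally, bubbles staggered in
# depth so axial collisions are rare; speed 2 mm/s, recirculating
two_vessel_scene <- function(n_frames = 240, noise_sigma0 = 0.03, seed = 9) {
  rows <- lapply(1:6, function(b) {
    x <- if (b %% 2) 0.250 else 0.300
    z0 <- 0.08 + 0.17 * b
    fr <- seq_len(n_frames)
    z <- 0.05 + (z0 + 0.002 * fr) %% 1.05
    data.frame(bubble = b, frame = fr, z_mm = z, x_mm = x,
               amplitude = 1, segment = 1L)
  })
  traj <- do.call(rbind, rows)
  class(traj) <- c("mb_trajectory_set", "data.frame")
  cfg <- scene_config(depth_mm = 1.2, width_mm = 0.55, n_frames = n_frames,
                      n_bubbles = 6, clutter_rank = 0,
                      noise_sigma0 = noise_sigma0, seed = seed)
  net <- generate_vessel_network(cfg)
  list(scene = synthesize_iq(traj, net, cfg), traj = traj, cfg = cfg,
       x_vessels_um = c(250, 300))
}

# Sierpinski gasket by dyadic subdivision (3 copies at scale 1/2)
sierpinski_gasket <- function(iterations = 9) {
  g <- matrix(1L, 1, 1)
  for (i in seq_len(iterations)) {
    g <- rbind(cbind(g, g), cbind(g, matrix(0L, nrow(g), ncol(g))))
  }
  g
}

# exhaustive optimum of the gated assignment objective:
# sum of linked squared distances + gate^2 per unlinked point (both sides)
brute_force_assignment_cost <- function(a, b, gate_um) {
  na <- nrow(a); nb <- nrow(b)
  g2 <- gate_um^2
  d2 <- if (na && nb)
    outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 else
    matrix(0, 0, 0)
  best <- Inf
  recurse <- function(i, used_b, cost) {
    if (cost >= best) return()
    if (i > na) {
      total <- cost + g2 * sum(!used_b)
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1L, used_b, cost + g2)          # leave row i unlinked
    for (j in seq_len(nb)) {
      if (!used_b[j] && d2[i, j] <= g2) {
        ub <- used_b; ub[j] <- TRUE
        recurse(i + 1L, ub, cost + d2[i, j])
      }
    }
  }
  recurse(1L, rep(FALSE, max(nb, 1))[seq_len(nb)], 0)
  best
}

# brute-force nearest-vascular-pixel distance map
brute_force_distance <- function(vasc) {
  idx <- which(vasc, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(vasc), ncol(vasc))
  for (i in seq_len(nrow(vasc))) {
    for (j in seq_len(ncol(vasc))) {
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
  }
  out
}

# single rendered bubble frame at native pitch with complex white noise
single_bubble_frame <- function(z0_um, x0_um, nz = 27, nx = 14,
                                pitch_z = 19.25, pitch_x = 38.5,
                                sigma_z = 25, sigma_x = 40,
                                noise_sd = 0.1) {
  gz <- exp(-(((seq_len(nz)) - 1) * pitch_z - z0_um)^2 / (2 * sigma_z^2))
  gx <- exp(-(((seq_len(nx)) - 1) * pitch_x - x0_um)^2 / (2 * sigma_x^2))
  fr <- outer(gz, gx) * exp(1i * stats::runif(1, 0, 2 * pi))
  fr + complex(real = stats::rnorm(nz * nx), imaginary = stats::rnorm(nz * nx)) *
    noise_sd / sqrt(2)
}
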