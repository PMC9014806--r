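#' Simulate recirculating microbubble trajectories
#'
#' Advects a constant population of microbubbles along the network
#' centerlines at each segment's flow speed. A bubble keeps a fixed radial
#' offset (|offset| <= radius) plus optional small per-frame radial jitter,
#' so every position stays inside its vessel tube. When a bubble reaches the
#' end of a segment it continues into a random child segment, or re-enters at
#' the root when the segment is a leaf (recirculation): the number of
#' bubbles in the field is constant over time, emulating a recirculating
#' contrast bolus.
#'
#' @param network a [generate_vessel_network] result.
#' @param config a [scene_config]; `frame_rate_hz` must be > 0.
#' @return Object of class `mb_trajectory_set`: data.frame with columns
#'   `bubble`, `frame`, `z_mm`, `x_mm`, `amplitude`, `segment`, plus a
#'   `birth`/`death` attribute per bubble.
#' @export
simulate_mb_trajectories <- function(network, config) {
  stop_if(!inherits(network, "vessel_network"), "`network` must be a vessel_network")
  stop_if(length(network$segments) == 0, "network is empty")
  stop_if(config$frame_rate_hz <= 0, "frame rate must be > 0")
  with_seed(config$seed + 1L, function() advect_bubbles(network, config))
}

advect_bubbles <- function(network, config) {
  n_seg <- length(network$segments)
  cums <- lapply(network$segments, polyline_arclength)
  lens <- vapply(cums, function(cc) cc[length(cc)], numeric(1))
  children <- lapply(seq_len(n_seg), function(i) which(network$parent == i))
  nb <- config$n_bubbles
  nf <- config$n_frames
  dt <- 1 / config$frame_rate_hz
  amp <- stats::rlnorm(nb, config$mb_amp_meanlog, config$mb_amp_sdlog)
  if (nb == 0) {
    out <- data.frame(bubble = integer(0), frame = integer(0),
                      z_mm = numeric(0), x_mm = numeric(0),
                      amplitude = numeric(0), segment = integer(0))
    attr(out, "birth") <- integer(0)
    attr(out, "death") <- integer(0)
    class(out) <- c("mb_trajectory_set", "data.frame")
    return(out)
  }
  # initial state: segment weighted by length, uniform arc position
  seg <- sample.int(n_seg, nb, replace = TRUE, prob = pmax(lens, 1e-9))
  s <- stats::runif(nb) * lens[seg]
  u <- stats::runif(nb, -1, 1)                       # radial offset fraction
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    z <- x <- numeric(nb)
    for (b in seq_len(nb)) {
      at <- polyline_at(network$segments[[seg[b]]], cums[[seg[b]]], s[b])
      r_mm <- network$radius_um[seg[b]] / 1000
      off <- u[b] * r_mm
      if (config$radial_jitter_frac > 0 && r_mm > 0) {
        off <- off + stats::runif(1, -1, 1) * config$radial_jitter_frac * r_mm
        off <- min(max(off, -r_mm), r_mm)
      }
      p <- at$point + off * at$normal
      z[b] <- min(max(p[1], 0), config$depth_mm)
      x[b] <- min(max(p[2], 0), config$width_mm)
      # advance for next frame
      s[b] <- s[b] + network$speed_mm_s[seg[b]] * dt
      while (s[b] >= lens[seg[b]]) {
        rem <- s[b] - lens[seg[b]]
        kids <- children[[seg[b]]]
        seg[b] <- if (length(kids)) kids[sample.int(length(kids), 1)] else 1L
        s[b] <- rem
        if (lens[seg[b]] <= 0) break
      }
    }
    rows[[f]] <- data.frame(bubble = seq_len(nb), frame = f, z_mm = z,
                            x_mm = x, amplitude = amp, segment = seg)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$bubble, out$frame), ]
  rownames(out) <- NULL
  attr(out, "birth") <- rep(1L, nb)
  attr(out, "death") <- rep(nf, nb)
  class(out) <- c("mb_trajectory_set", "data.frame")
  out
}

#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(
    traj[, c("bubble", "frame", "z_mm", "x_mm")], path, row.names = FALSE)
  invisible(path)
}
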