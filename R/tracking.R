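#' Link per-frame centroids into microbubble trajectories
#'
#' Frame-to-frame global nearest-neighbor linking: for every consecutive
#' frame pair, active track ends are matched to new detections by an optimal
#' linear assignment minimizing total squared displacement, with links
#' longer than `max_disp_um` forbidden. The assignment problem is augmented
#' with per-particle "no link" alternatives of cost `max_disp_um^2`, so the
#' minimized objective is
#' `sum(linked squared displacements) + max_disp_um^2 * n_unlinked`;
#' unmatched detections start new tracks and unmatched tracks terminate
#' (no gap closing: track frames are consecutive). Linking is performed
#' per subset label, then pooled.
#'
#' @param centroids a `centroid_set` (columns `frame`, `z_um`, `x_um`,
#'   `score`, optional `subset`), sorted by frame.
#' @param max_disp_um hard gating distance (um) for a single frame-to-frame
#'   link.
#' @return Object of class `track_set`: data.frame `track`, `frame`, `z_um`,
#'   `x_um`, `subset`.
#' @export
link_centroids <- function(centroids, max_disp_um) {
  assert_scalar_num(max_disp_um, "max_disp_um", positive = TRUE)
  cols <- c("frame", "z_um", "x_um")
  stop_if(!all(cols %in% names(centroids)), "missing centroid columns")
  if (!"subset" %in% names(centroids)) centroids$subset <- "all"
  pieces <- lapply(split(centroids, centroids$subset), link_one_subset,
                   max_disp_um = max_disp_um)
  offset <- 0L
  for (i in seq_along(pieces)) {
    if (nrow(pieces[[i]])) {
      pieces[[i]]$track <- pieces[[i]]$track + offset
      offset <- max(pieces[[i]]$track)
    }
  }
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(track = integer(0), frame = integer(0),
                                      z_um = numeric(0), x_um = numeric(0),
                                      subset = character(0))
  out <- out[order(out$track, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

link_one_subset <- function(cen, max_disp_um) {
  empty <- data.frame(track = integer(0), frame = integer(0),
                      z_um = numeric(0), x_um = numeric(0),
                      subset = character(0))
  if (nrow(cen) == 0) return(empty)
  subset_lab <- cen$subset[1]
  frames <- sort(unique(cen$frame))
  byf <- split(cen, cen$frame)
  # state: open tracks with last position and last frame
  pts <- vector("list", 0)   # per track: matrix of (frame, z, x)
  open <- integer(0)         # indices into pts of tracks open at `prev_frame`
  prev_frame <- NULL
  for (f in frames) {
    det <- byf[[as.character(f)]]
    nd <- nrow(det)
    if (is.null(prev_frame) || f != prev_frame + 1L || length(open) == 0L) {
      open <- integer(0)
      assigned <- rep(NA_integer_, nd)
    } else {
      last <- t(vapply(pts[open], function(m) m[nrow(m), 2:3], numeric(2)))
      assigned <- gated_assignment(last, cbind(det$z_um, det$x_um), max_disp_um)
    }
    new_open <- integer(0)
    for (j in seq_len(nd)) {
      ti <- assigned[j]
      if (!is.na(ti)) {
        tid <- open[ti]
        pts[[tid]] <- rbind(pts[[tid]], c(f, det$z_um[j], det$x_um[j]))
        new_open <- c(new_open, tid)
      } else {
        pts[[length(pts) + 1L]] <- matrix(c(f, det$z_um[j], det$x_um[j]), 1)
        new_open <- c(new_open, length(pts))
      }
    }
    open <- new_open
    prev_frame <- f
  }
  if (!length(pts)) return(empty)
  out <- do.call(rbind, lapply(seq_along(pts), function(i) {
    m <- pts[[i]]
    data.frame(track = i, frame = as.integer(m[, 1]), z_um = m[, 2],
               x_um = m[, 3], subset = subset_lab)
  }))
  out
}

# optimal gated assignment of previous positions (rows of `a`) to detections
# (rows of `b`); returns for each detection the index of its matched previous
# position or NA. Augmented square LAP: alternatives cost gate^2.
gated_assignment <- function(a, b, gate_um) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(rep(NA_integer_, nb))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  g2 <- gate_um^2
  big <- 1e12
  n <- na + nb
  cost <- matrix(0, n, n)
  cost[seq_len(na), seq_len(nb)] <- ifelse(d2 <= g2, d2, big)
  tr <- matrix(big, na, na); diag(tr) <- g2
  cost[seq_len(na), nb + seq_len(na)] <- tr
  bl <- matrix(big, nb, nb); diag(bl) <- g2
  cost[na + seq_len(nb), seq_len(nb)] <- bl
  sol <- solve_lap_cpp(cost)
  out <- rep(NA_integer_, nb)
  for (i in seq_len(na)) {
    j <- sol[i]
    if (j <= nb && d2[i, j] <= g2) out[j] <- i
  }
  out
}

# total objective value of a gated assignment (used by tests and reports)
assignment_cost <- function(a, b, gate_um) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 && nb == 0) return(0)
  assigned <- gated_assignment(a, b, gate_um)
  d2 <- if (na && nb)
    outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 else
    matrix(0, 0, 0)
  linked <- which(!is.na(assigned))
  cost <- sum(vapply(linked, function(j) d2[assigned[j], j], numeric(1)))
  cost + gate_um^2 * (na - length(linked) + nb - length(linked))
}

#' Persistence filter for microbubble tracks
#'
#' Removes tracks linked over fewer than `min_persistence` frames; the
#' pairing-persistence criterion suppresses spurious single-frame
#' detections. Survivors are returned unchanged.
#'
#' @param tracks a `track_set`.
#' @param min_persistence minimum number of linked frames (default 10).
#' @return Filtered `track_set`.
#' @export
filter_tracks <- function(tracks, min_persistence = 10L) {
  stop_if(!is.data.frame(tracks) || !"track" %in% names(tracks),
          "`tracks` must be a track_set")
  len <- table(tracks$track)
  keep <- names(len)[len >= min_persistence]
  out <- tracks[tracks$track %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

#' Per-step track speeds
#'
#' Smooths positions with a centered moving average (default window 3) to
#' suppress differencing amplification of localization jitter, then computes
#' per-step speed = step length x frame rate, and attaches a per-point speed
#' (mean of adjacent step speeds) plus the per-track mean.
#'
#' @param tracks a `track_set` (no zero-length tracks).
#' @param frame_rate_hz acquisition frame rate (> 0).
#' @param smooth_window centered moving-average window (odd; 1 = no
#'   smoothing).
#' @return `track_set` with added columns `speed_mm_s` (per point) and
#'   `mean_speed_mm_s` (per track, repeated).
#' @export
track_velocities <- function(tracks, frame_rate_hz, smooth_window = 3L) {
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  stop_if(!is.data.frame(tracks) || nrow(tracks) == 0,
          "zero-length track set")
  out <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    z <- moving_average(tr$z_um, smooth_window)
    x <- moving_average(tr$x_um, smooth_window)
    if (n >= 2) {
      step_um <- sqrt(diff(z)^2 + diff(x)^2)
      step_speed <- step_um * frame_rate_hz / 1000   # mm/s
      pt <- c(step_speed[1], (step_speed[-1] + step_speed[-(n - 1)]) / 2,
              step_speed[n - 1])[seq_len(n)]
      if (n == 2) pt <- rep(step_speed, 2)
      tr$speed_mm_s <- pt
      tr$mean_speed_mm_s <- mean(step_speed)
    } else {
      tr$speed_mm_s <- 0
      tr$mean_speed_mm_s <- 0
    }
    tr
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(out) <- c("track_set", "data.frame")
  out
}

#' Accumulate super-resolved density and velocity maps
#'
#' Every track point increments the count of its super-pixel (pixel centers
#' at `(i - 1) * pitch`); the velocity raster is the count-weighted mean of
#' the per-point speeds in each super-pixel (`NA` where the density is 0).
#' Total density equals the number of track points, exactly.
#'
#' @param tracks a `track_set`, ideally with velocities attached.
#' @param n_axial,n_lateral raster size (super-pixels).
#' @param pitch_um super-pixel pitch (default 5 um).
#' @return Object of class `sr_maps`: list with `density` (integer matrix),
#'   `velocity` (matrix, mm/s), `pitch_um`.
#' @export
accumulate_maps <- function(tracks, n_axial, n_lateral, pitch_um = 5) {
  stop_if(!is.data.frame(tracks), "`tracks` must be a track_set")
  dens <- matrix(0L, n_axial, n_lateral)
  vsum <- matrix(0, n_axial, n_lateral)
  if (nrow(tracks)) {
    iz <- round(tracks$z_um / pitch_um) + 1L
    ix <- round(tracks$x_um / pitch_um) + 1L
    stop_if(any(iz < 1 | iz > n_axial | ix < 1 | ix > n_lateral),
            "track points fall outside the map grid")
    sp <- if ("speed_mm_s" %in% names(tracks)) tracks$speed_mm_s else
      rep(0, nrow(tracks))
    for (k in seq_len(nrow(tracks))) {
      dens[iz[k], ix[k]] <- dens[iz[k], ix[k]] + 1L
      vsum[iz[k], ix[k]] <- vsum[iz[k], ix[k]] + sp[k]
    }
  }
  vel <- ifelse(dens > 0, vsum / pmax(dens, 1L), NA_real_)
  structure(list(density = dens, velocity = vel, pitch_um = pitch_um),
            class = "sr_maps")
}

#' @export
print.sr_maps <- function(x, ...) {
  cat(sprintf("<sr_maps> %d x %d super-pixels at %.1f um, %d counts\n",
              nrow(x$density), ncol(x$density), x$pitch_um, sum(x$density)))
  invisible(x)
}

#' Write SR maps as 32-bit TIFF rasters
#'
#' @param maps an `sr_maps` object.
#' @param density_path,velocity_path output TIFF paths.
#' @export
write_sr_maps <- function(maps, density_path, velocity_path = NULL) {
  scale <- max(maps$density, 1)
  tiff::writeTIFF(maps$density / scale, density_path, bits.per.sample = 32L)
  if (!is.null(velocity_path)) {
    v <- maps$velocity; v[is.na(v)] <- 0
    vscale <- max(v, 1)
    tiff::writeTIFF(v / vscale, velocity_path, bits.per.sample = 32L)
  }
  invisible(density_path)
}
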