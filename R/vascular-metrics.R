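#' Tumor long-axis diameter of an ROI
#'
#' Longest distance between two boundary points of the ROI, analogous to
#' the RECIST long-axis diameter. Computed as the diameter of the convex
#' hull (exhaustive pairwise search over hull vertices), which equals the
#' maximum over all boundary point pairs.
#'
#' @param roi an [roi_from_control_points()] result.
#' @return Diameter in mm.
#' @export
max_diameter <- function(roi) {
  stop_if(!inherits(roi, "roi"), "`roi` must be an roi")
  p <- roi$boundary[-nrow(roi$boundary), , drop = FALSE]
  h <- p[grDevices::chull(p[, 2], p[, 1]), , drop = FALSE]
  d2 <- outer(h[, 1], h[, 1], "-")^2 + outer(h[, 2], h[, 2], "-")^2
  sqrt(max(d2))
}

#' Contrast power within an ROI
#'
#' Sum of the diffraction-limited contrast power raster over the ROI mask.
#'
#' @param power matrix from [power_doppler()].
#' @param roi an [roi] object.
#' @param pitch_mm pixel pitch of `power` in mm (scalar or `[axial,
#'   lateral]`).
#' @return Accumulated power (a.u.).
#' @export
contrast_power <- function(power, roi, pitch_mm) {
  mask <- rasterize_roi(roi, nrow(power), ncol(power), pitch_mm)
  stop_if(!any(mask), "ROI mask is empty on this raster")
  sum(power[mask])
}

#' Blood volume surrogate within an ROI
#'
#' Total number of localized microbubble centroids (track points) falling in
#' ROI super-pixels of the density map.
#'
#' @param maps an `sr_maps` object (or a density matrix).
#' @param roi an [roi] object.
#' @return Integer count.
#' @export
blood_volume <- function(maps, roi) {
  dens <- if (inherits(maps, "sr_maps")) maps$density else maps
  pitch_mm <- if (inherits(maps, "sr_maps")) maps$pitch_um / 1000 else
    stop("supply an sr_maps object")
  mask <- rasterize_roi(roi, nrow(dens), ncol(dens), pitch_mm)
  stop_if(!any(mask), "ROI mask is empty on this raster")
  as.integer(sum(dens[mask]))
}

#' Intervessel distance within an ROI
#'
#' Binarizes the centroid density map (count >= `min_count` marks a
#' vascularized pixel), computes the exact Euclidean distance transform of
#' the avascular pixels to the nearest vascularized pixel, and summarizes it
#' over the avascular pixels of the ROI. A surrogate for diffusion distance
#' to the nearest perfused vessel (and hence local hypoxia).
#'
#' @param maps an `sr_maps` object.
#' @param roi an [roi] object, or `NULL` to use the whole raster.
#' @param min_count binarization threshold (default 1).
#' @return list `mean_um`, `median_um`, `distance_um` (matrix, `NA` outside
#'   the ROI).
#' @export
intervessel_distance <- function(maps, roi = NULL, min_count = 1L) {
  stop_if(!inherits(maps, "sr_maps"), "`maps` must be an sr_maps")
  vasc <- maps$density >= min_count
  mask <- if (is.null(roi)) matrix(TRUE, nrow(vasc), ncol(vasc)) else
    rasterize_roi(roi, nrow(vasc), ncol(vasc), maps$pitch_um / 1000)
  stop_if(!any(vasc & mask) && !any(vasc),
          "no vascularized pixel available for the distance transform")
  stop_if(!any(vasc), "no vascularized pixel in the map")
  dist_px <- euclidean_distance_to(vasc)
  dist_um <- dist_px * maps$pitch_um
  dist_um[!mask] <- NA_real_
  avasc <- mask & !vasc
  vals <- dist_um[avasc]
  list(mean_um = if (length(vals)) mean(vals) else 0,
       median_um = if (length(vals)) stats::median(vals) else 0,
       distance_um = dist_um)
}

# exact Euclidean distance (pixels) from every pixel to the nearest TRUE
# pixel of `target`
euclidean_distance_to <- function(target) {
  # EBImage::distmap gives each positive pixel its distance to the nearest
  # zero pixel, so invert: background = target
  EBImage::distmap((!target) * 1, metric = "euclidean")@.Data
}

#' Distance metric (DM) of a vessel path
#'
#' Path arclength divided by the Euclidean distance between its endpoints;
#' the classic low-frequency tortuosity index, >= 1, equal to 1 for a
#' straight vessel.
#'
#' @param path matrix of ordered centerline points (>= 2 rows, any unit).
#' @return Unitless DM.
#' @export
distance_metric <- function(path) {
  path <- as.matrix(path)
  stop_if(nrow(path) < 2, "need at least 2 path points")
  steps <- sqrt(rowSums(diff(path)^2))
  chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  stop_if(chord == 0, "DM undefined: coincident path endpoints")
  sum(steps) / chord
}

#' Sum-of-angles metric (SOAM) of a vessel path
#'
#' Sum over interior vertices of the unsigned turning angle between
#' consecutive segment directions, divided by total path length: the
#' high-frequency tortuosity index in rad per unit length (rad/mm when the
#' path is in mm). Zero-length segments are removed first. This is the 2-D
#' restriction of the 3-D formulation (no torsion term exists in-plane).
#'
#' @param path matrix of ordered centerline points (>= 3 rows).
#' @return SOAM in rad per path unit.
#' @export
soam <- function(path) {
  path <- as.matrix(path)
  stop_if(nrow(path) < 3, "need at least 3 path points")
  d <- diff(path)
  len <- sqrt(rowSums(d^2))
  d <- d[len > 0, , drop = FALSE]
  total <- sum(len)
  stop_if(total == 0, "SOAM undefined: zero-length path")
  if (nrow(d) < 2) return(0)
  a <- atan2(d[, 2], d[, 1])
  turn <- abs(diff(a))
  turn <- pmin(turn, 2 * pi - turn)
  sum(turn) / total
}

#' Box-counting (Hausdorff) fractal dimension of a binary raster
#'
#' Counts occupied boxes `N(s)` for dyadic box sizes `s = 2^0 ... 2^k`
#' (`k = floor(log2(min side)) - 1`), grid anchored at the raster origin,
#' and fits a least-squares line to `log N(s)` vs `log s`. The dimension is
#' the negative slope over the configured scale range. By default the three
#' smallest scales (s = 1, 2, 4) and the largest scale are dropped: box
#' sizes comparable to the one-pixel width of rendered structures sit below
#' the set's inner cutoff and bias the slope toward 1, while the largest
#' boxes probe the outer cutoff. The fit R^2 is reported as a quality flag;
#' an exactly self-similar set (line, plane, dyadic Sierpinski gasket) gives
#' the same slope for any window.
#'
#' @param raster binary matrix (any nonzero value = occupied); min side
#'   >= 64 (with the default window, >= 256 is needed for 3 usable scales;
#'   reduce `drop_small` for smaller rasters).
#' @param drop_small,drop_large number of smallest / largest dyadic scales
#'   excluded from the fit (defaults 3 and 1).
#' @return list `dimension`, `r_squared`, `sizes`, `counts`.
#' @export
box_counting_dimension <- function(raster, drop_small = 3L, drop_large = 1L) {
  raster <- (as.matrix(raster) != 0)
  stop_if(!any(raster), "raster has no occupied pixel")
  stop_if(min(dim(raster)) < 64, "raster side must be >= 64")
  kmax <- floor(log2(min(dim(raster)))) - 1L
  sizes <- 2^(0:kmax)
  counts <- vapply(sizes, function(s) count_boxes(raster, s), numeric(1))
  use <- seq_along(sizes)
  if (drop_small > 0) use <- setdiff(use, seq_len(drop_small))
  if (drop_large > 0) use <- setdiff(use, length(sizes) - seq_len(drop_large) + 1L)
  stop_if(length(use) < 3, "fewer than 3 usable scales for the fit")
  fit <- stats::lm(log(counts[use]) ~ log(sizes[use]))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((log(counts[use]) - mean(log(counts[use])))^2)
  list(dimension = -unname(stats::coef(fit)[2]),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       sizes = sizes, counts = counts)
}

count_boxes <- function(raster, s) {
  if (s == 1) return(sum(raster))
  m <- raster * 1
  m2 <- rowsum(m, (seq_len(nrow(m)) - 1L) %/% s)
  m3 <- rowsum(t(m2), (seq_len(ncol(m)) - 1L) %/% s)
  sum(m3 > 0)
}

#' Extract vessel centerline paths from a density map
#'
#' Binarizes the super-resolved density map, skeletonizes it (Zhang-Suen
#' thinning), cuts the skeleton at branch points (pixels with more than two
#' 8-neighbors), decomposes it into simple paths, and discards paths shorter
#' than `min_length_um`. Paths are returned in physical coordinates and are
#' the inputs of the tortuosity metrics [distance_metric()] and [soam()].
#'
#' @param maps an `sr_maps` object (or binary matrix with `pitch_um` given).
#' @param min_count binarization threshold on the density (default 1).
#' @param min_length_um minimum path arclength kept (default 50 um).
#' @param pitch_um pitch override when `maps` is a plain matrix.
#' @return list of two-column matrices (`z_um`, `x_um`), possibly empty.
#' @export
extract_vessel_paths <- function(maps, min_count = 1L, min_length_um = 50,
                                 pitch_um = NULL) {
  if (inherits(maps, "sr_maps")) {
    mask <- maps$density >= min_count
    pitch_um <- maps$pitch_um
  } else {
    stop_if(is.null(pitch_um), "supply `pitch_um` with a plain matrix")
    mask <- as.matrix(maps) != 0
  }
  if (!any(mask)) return(list())
  skel <- zhang_suen_thin(mask)
  paths <- skeleton_paths(skel)
  out <- lapply(paths, function(p) {
    cbind(z_um = (p[, 1] - 1) * pitch_um, x_um = (p[, 2] - 1) * pitch_um)
  })
  keep <- vapply(out, function(p) {
    nrow(p) >= 2 && sum(sqrt(rowSums(diff(p)^2))) >= min_length_um
  }, logical(1))
  out[keep]
}

# Zhang-Suen binary thinning to a 1-pixel-wide 8-connected skeleton
zhang_suen_thin <- function(mask) {
  m <- mask * 1L
  nz <- nrow(m); nx <- ncol(m)
  pad <- matrix(0L, nz + 2L, nx + 2L)
  pad[2:(nz + 1L), 2:(nx + 1L)] <- m
  shift <- function(p, dz, dx) p[(2:(nz + 1L)) + dz, (2:(nx + 1L)) + dx]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1);  p6 <- shift(pad, 1, 0);  p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cur <- pad[2:(nz + 1L), 2:(nx + 1L)]
      if (phase == 1) {
        del <- cur == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        del <- cur == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(del)) {
        cur[del] <- 0L
        pad[2:(nz + 1L), 2:(nx + 1L)] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nz + 1L), 2:(nx + 1L)] == 1L
}

# decompose an 8-connected skeleton into simple paths cut at branch points.
# Diagonal adjacencies that are shortcut by an orthogonal 2-path are dropped
# so staircase pixels do not masquerade as junctions.
skeleton_paths <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(list())
  nz <- nrow(skel)
  id_of <- matrix(0L, nrow(skel), ncol(skel))
  id_of[idx] <- seq_len(n)
  inb <- function(z, x) z >= 1 & z <= nrow(skel) & x >= 1 & x <= ncol(skel)
  adj <- vector("list", n)
  for (v in seq_len(n)) {
    z <- idx[v, 1]; x <- idx[v, 2]
    nbrs <- integer(0)
    for (dz in -1:1) for (dx in -1:1) {
      if (dz == 0 && dx == 0) next
      z2 <- z + dz; x2 <- x + dx
      if (!inb(z2, x2) || id_of[z2, x2] == 0L) next
      if (dz != 0 && dx != 0) {
        # skip diagonal if an orthogonal 2-path exists
        if ((inb(z2, x) && id_of[z2, x] > 0L) ||
            (inb(z, x2) && id_of[z, x2] > 0L)) next
      }
      nbrs <- c(nbrs, id_of[z2, x2])
    }
    adj[[v]] <- nbrs
  }
  deg <- lengths(adj)
  ekey <- function(a, b) paste0(min(a, b), "-", max(a, b))
  seen <- new.env(hash = TRUE)
  paths <- list()
  trace_from <- function(v, w) {
    # walk edge v->w through degree-2 vertices until a terminal vertex
    path <- c(v, w)
    assign(ekey(v, w), TRUE, envir = seen)
    prev <- v; cur <- w
    while (deg[cur] == 2) {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) != 1) break
      if (exists(ekey(cur, nxt), envir = seen)) break
      assign(ekey(cur, nxt), TRUE, envir = seen)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  terminals <- which(deg != 2)
  for (v in terminals) {
    for (w in adj[[v]]) {
      if (!exists(ekey(v, w), envir = seen)) {
        paths[[length(paths) + 1L]] <- trace_from(v, w)
      }
    }
  }
  # leftover pure cycles (every vertex degree 2)
  for (v in seq_len(n)) {
    for (w in adj[[v]]) {
      if (!exists(ekey(v, w), envir = seen)) {
        paths[[length(paths) + 1L]] <- trace_from(v, w)
      }
    }
  }
  lapply(paths, function(p) idx[p, , drop = FALSE])
}
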