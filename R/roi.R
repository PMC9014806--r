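#' Region of interest from Bezier control points (Hobby spline)
#'
#' Builds a smooth closed curve through ordered control points with Hobby's
#' algorithm (the interpolating Bezier spline of METAFONT, unit tension):
#' departure/arrival angles at every node are chosen by solving the cyclic
#' tridiagonal "mock curvature" system, cubic Bezier control handles follow
#' from Hobby's velocity function, and each Bezier segment is discretized so
#' the full boundary has at least `n_boundary` points. The result mimics a
#' manually traced tumor cross-section outline.
#'
#' @param points numeric matrix / data.frame with >= 3 rows of `(z, x)`
#'   control points in mm, ordered along the outline (not repeated at the
#'   end).
#' @param n_boundary minimum number of discretized boundary points (>= 200).
#' @return Object of class `roi`: list with `boundary` (closed polygon,
#'   first point repeated last), `control_points`.
#' @export
roi_from_control_points <- function(points, n_boundary = 256L) {
  points <- as.matrix(points)
  stop_if(!is.numeric(points) || ncol(points) != 2 || nrow(points) < 3,
          "need at least 3 (z, x) control points")
  stop_if(anyDuplicated(points) > 0, "control points must be distinct")
  n_boundary <- max(200L, as.integer(n_boundary))
  z <- complex(real = points[, 1], imaginary = points[, 2])
  bez <- hobby_closed(z)
  per_seg <- ceiling(n_boundary / nrow(points))
  pts <- do.call(rbind, lapply(bez, function(b) {
    t <- seq(0, 1, length.out = per_seg + 1L)[-(per_seg + 1L)]
    p <- (1 - t)^3 * b[1] + 3 * (1 - t)^2 * t * b[2] +
      3 * (1 - t) * t^2 * b[3] + t^3 * b[4]
    cbind(Re(p), Im(p))
  }))
  boundary <- rbind(pts, pts[1, , drop = FALSE])
  stop_if(polygon_self_intersects(boundary),
          "control points produce a self-intersecting outline")
  stop_if(abs(polygon_area(boundary)) <= 0, "ROI area must be > 0")
  structure(list(boundary = boundary, control_points = points),
            class = "roi")
}

# Hobby's algorithm for a closed path through complex nodes (tension 1).
# Returns a list of Bezier segments c(p0, c1, c2, p1).
hobby_closed <- function(z) {
  n <- length(z)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  chord <- z[nxt] - z
  d <- Mod(chord)
  stop_if(any(d == 0), "coincident consecutive control points")
  # turning angle at node i between incoming and outgoing chords
  psi <- Arg(chord / chord[prv])
  # cyclic tridiagonal mock-curvature system in the departure angles theta:
  # (1/d[i-1]) theta[i-1] + 2(1/d[i-1] + 1/d[i]) theta[i] + (1/d[i]) theta[i+1]
  #   = -2 psi[i]/d[i-1] - psi[i+1]/d[i]
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 1:n) {
    A[i, prv[i]] <- A[i, prv[i]] + 1 / d[prv[i]]
    A[i, i] <- A[i, i] + 2 * (1 / d[prv[i]] + 1 / d[i])
    A[i, nxt[i]] <- A[i, nxt[i]] + 1 / d[i]
    rhs[i] <- -2 * psi[i] / d[prv[i]] - psi[nxt[i]] / d[i]
  }
  theta <- solve(A, rhs)
  phi <- -psi - theta   # arrival angles (phi at node i, of segment i-1)
  lapply(1:n, function(i) {
    th <- theta[i]; ph <- phi[nxt[i]]
    c1 <- z[i] + d[i] * hobby_velocity(th, ph) * exp(1i * (Arg(chord[i]) + th))
    c2 <- z[nxt[i]] - d[i] * hobby_velocity(ph, th) *
      exp(1i * (Arg(chord[i]) - ph))
    c(z[i], c1, c2, z[nxt[i]])
  })
}

# Hobby's velocity (handle-length) function, tension 1
hobby_velocity <- function(theta, phi) {
  a <- sqrt(2); b <- 1 / 16
  num <- 2 + a * (sin(theta) - b * sin(phi)) * (sin(phi) - b * sin(theta)) *
    (cos(theta) - cos(phi))
  den <- 3 * (1 + (sqrt(5) - 1) / 2 * cos(theta) + (3 - sqrt(5)) / 2 * cos(phi))
  num / den
}

# shoelace signed area of a closed polygon (first point repeated last)
polygon_area <- function(p) {
  n <- nrow(p) - 1L
  sum(p[1:n, 1] * p[2:(n + 1), 2] - p[2:(n + 1), 1] * p[1:n, 2]) / 2
}

# O(n^2) proper-crossing check on a closed polygon
polygon_self_intersects <- function(p) {
  n <- nrow(p) - 1L
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- cross2(b2 - b1, a1 - b1); d2 <- cross2(b2 - b1, a2 - b1)
    d3 <- cross2(a2 - a1, b1 - a1); d4 <- cross2(a2 - a1, b2 - a1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in 1:(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Rasterize an ROI to a pixel mask
#'
#' Even-odd (crossing-parity) fill: a pixel belongs to the mask when its
#' center lies inside the boundary polygon. Pixel centers sit at
#' `(i - 1) * pitch`.
#'
#' @param roi an [roi_from_control_points()] result.
#' @param n_axial,n_lateral raster size.
#' @param pitch_mm pixel pitch in mm (scalar or `[axial, lateral]`).
#' @return Logical matrix `[n_axial, n_lateral]`.
#' @export
rasterize_roi <- function(roi, n_axial, n_lateral, pitch_mm) {
  stop_if(!inherits(roi, "roi"), "`roi` must be an roi")
  pitch_mm <- rep(pitch_mm, length.out = 2)
  zb <- roi$boundary[, 1]; xb <- roi$boundary[, 2]
  zc <- (seq_len(n_axial) - 1) * pitch_mm[1]
  xc <- (seq_len(n_lateral) - 1) * pitch_mm[2]
  mask <- matrix(FALSE, n_axial, n_lateral)
  ne <- length(zb) - 1L
  for (i in seq_len(n_axial)) {
    # horizontal ray crossing parity per boundary edge, vectorized over edges
    z0 <- zc[i]
    y1 <- zb[1:ne]; y2 <- zb[2:(ne + 1L)]
    x1 <- xb[1:ne]; x2 <- xb[2:(ne + 1L)]
    crosses <- (y1 > z0) != (y2 > z0)
    if (!any(crosses)) next
    xi <- x1[crosses] + (z0 - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    cnt <- vapply(xc, function(x0) sum(xi > x0), numeric(1))
    mask[i, ] <- (cnt %% 2) == 1
  }
  mask
}
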