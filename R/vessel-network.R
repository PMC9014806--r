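#' Generate a ground-truth branching vessel network
#'
#' Builds a connected vessel tree rooted at the "membrane" (top) edge of the
#' field, emulating the columnar microvasculature that grows downward from a
#' perfused surface membrane into an engrafted tumor. Three morphological
#' presets support treatment-regime tests: `"chaotic"` (tortuous branches at
#' random orientations), `"columnar"` (near-straight descending columns), and
#' `"pruned"` (chaotic, but vessels confined to one lateral half so that the
#' other half is avascular).
#'
#' Every node spawns exactly `n_children` children down to `branch_depth`
#' generations, so a network has `sum(n_children^(0:branch_depth))` segments.
#' Segments are polylines in physical (z = depth, x = lateral) mm
#' coordinates, clipped to the field of view; radii and speeds decay
#' geometrically with generation.
#'
#' @param config a [scene_config].
#' @return An object of class `vessel_network`: list with `segments` (list of
#'   two-column `z`/`x` matrices, mm), `radius_um`, `speed_mm_s`, `parent`
#'   (0 for the root), `generation`.
#' @export
generate_vessel_network <- function(config) {
  stop_if(!inherits(config, "scene_config"), "`config` must be a scene_config")
  Z <- config$depth_mm; X <- config$width_mm
  min_len <- 4 * config$root_radius_um / 1000
  stop_if(Z <= min_len,
          "infeasible geometry: field depth too small for the requested vessels")
  with_seed(config$seed, function() build_network(config, Z, X))
}

build_network <- function(config, Z, X) {
  morph <- config$morphology
  x_max <- if (morph == "pruned") X / 2 else X  # avascular right half
  clip <- function(p) {
    p[, 1] <- pmin(pmax(p[, 1], 0), Z)
    p[, 2] <- pmin(pmax(p[, 2], 0), x_max)
    p
  }
  # polyline from start point along unit direction with preset waviness
  grow_segment <- function(start, dir, len, gen) {
    n_pts <- 24L
    step <- len / (n_pts - 1L)
    wig <- switch(morph, chaotic = 0.5, columnar = 0.06, pruned = 0.5)
    pts <- matrix(NA_real_, n_pts, 2)
    pts[1, ] <- start
    ang <- atan2(dir[2], dir[1])
    for (k in 2:n_pts) {
      ang <- ang + stats::rnorm(1, 0, wig * step * 6)
      # bias back toward descending so vessels keep filling depth
      if (morph != "columnar") ang <- 0.9 * ang + 0.1 * 0
      pts[k, ] <- pts[k - 1, ] + step * c(cos(ang), sin(ang))
    }
    clip(pts)
  }
  seg_len <- Z / (config$branch_depth + 1.2)
  root_x <- stats::runif(1, 0.25 * x_max, 0.75 * x_max)
  segments <- list(grow_segment(c(0, root_x), c(1, 0), seg_len, 0L))
  parent <- 0L; generation <- 0L
  radius <- config$root_radius_um
  speed <- config$root_speed_mm_s
  if (config$branch_depth > 0) {
    frontier <- 1L
    for (gen in seq_len(config$branch_depth)) {
      new_frontier <- integer(0)
      for (pid in frontier) {
        pp <- segments[[pid]]
        for (ch in seq_len(config$n_children)) {
          # child anchored on the distal half of the parent centerline
          at <- sample(seq(ceiling(nrow(pp) / 2), nrow(pp)), 1)
          base_dir <- pp[min(at + 1, nrow(pp)), ] - pp[max(at - 1, 1), ]
          base_ang <- atan2(base_dir[2], base_dir[1])
          ang <- switch(morph,
            columnar = stats::rnorm(1, 0, 0.15),      # keep descending
            base_ang + stats::runif(1, -1.1, 1.1) * (if (ch %% 2) 1 else -1))
          segments[[length(segments) + 1L]] <-
            grow_segment(pp[at, ], c(cos(ang), sin(ang)),
                         seg_len * 0.8^gen, gen)
          parent <- c(parent, pid)
          generation <- c(generation, gen)
          new_frontier <- c(new_frontier, length(segments))
        }
      }
      frontier <- new_frontier
    }
  }
  structure(list(
    segments = segments,
    radius_um = config$root_radius_um * config$radius_decay^generation,
    speed_mm_s = config$root_speed_mm_s * config$speed_decay^generation,
    parent = parent,
    generation = generation,
    field_mm = c(depth = Z, width = X)
  ), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d segments, generations 0..%d, field %.2f x %.2f mm\n",
              length(x$segments), max(x$generation), x$field_mm[1], x$field_mm[2]))
  invisible(x)
}

#' @export
write_vessel_network <- function(network, path) {
  jsonlite::write_json(list(
    segments = lapply(network$segments, function(s)
      list(z_mm = s[, 1], x_mm = s[, 2])),
    radius_um = network$radius_um,
    speed_mm_s = network$speed_mm_s,
    parent = network$parent,
    generation = network$generation,
    field_mm = as.list(network$field_mm)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# cumulative arclength of a polyline (mm)
polyline_arclength <- function(p) {
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  c(0, cumsum(d))
}

# point and unit normal at arclength s along polyline
polyline_at <- function(p, cum, s) {
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(p) - 1L)
  seg <- p[i + 1L, ] - p[i, ]
  len <- sqrt(sum(seg^2))
  t <- if (len > 0) (s - cum[i]) / len else 0
  pt <- p[i, ] + t * seg
  tang <- if (len > 0) seg / len else c(1, 0)
  list(point = pt, normal = c(-tang[2], tang[1]))
}
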