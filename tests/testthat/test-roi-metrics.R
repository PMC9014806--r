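circle_points <- function(n = 8, r = 1, ctr = c(1.5, 1.5)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

test_that("Hobby-spline ROI interpolates its control points", {
  pts <- rbind(c(0.5, 0.5), c(0.5, 1.5), c(1.5, 1.5), c(1.5, 0.5))
  roi <- roi_from_control_points(pts)
  for (k in seq_len(nrow(pts))) {
    d <- sqrt((roi$boundary[, 1] - pts[k, 1])^2 +
              (roi$boundary[, 2] - pts[k, 2])^2)
    expect_lt(min(d), 0.01)
  }
  expect_gte(nrow(roi$boundary), 200)
})

test_that("near-circular ROI area and rasterization match the analytic disc", {
  roi <- roi_from_control_points(circle_points(10))
  area <- abs(vasculm:::polygon_area(roi$boundary))
  expect_equal(area, pi, tolerance = 0.02)
  mask <- rasterize_roi(roi, 300, 300, 0.01)
  expect_equal(sum(mask) * 1e-4, pi, tolerance = 0.02)
  # reversing control-point order gives the identical mask
  roi_rev <- roi_from_control_points(circle_points(10)[10:1, ])
  expect_equal(rasterize_roi(roi_rev, 300, 300, 0.01), mask)
})

test_that("degenerate control-point sets are rejected", {
  expect_error(roi_from_control_points(rbind(c(0, 0), c(1, 1))), "at least 3")
  # figure-eight ordering forces a self-intersection
  expect_error(roi_from_control_points(rbind(c(0, 0), c(1, 1), c(0, 1),
                                             c(1, 0))),
               "self-intersecting")
})

test_that("max diameter equals the exhaustive pairwise oracle", {
  roi <- roi_from_control_points(circle_points(12, r = 0.7, ctr = c(1, 1)))
  expect_equal(max_diameter(roi), 1.4, tolerance = 0.01)
  # 3:1 ellipse -> major axis
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ell <- roi_from_control_points(cbind(2 + 1.5 * cos(th), 2 + 0.5 * sin(th)))
  expect_equal(max_diameter(ell), 3, tolerance = 0.02)
  # random blob: exact agreement with O(n^2) brute force
  set.seed(6)
  th2 <- sort(stats::runif(9, 0, 2 * pi))
  blob <- roi_from_control_points(
    cbind(1 + stats::runif(9, 0.5, 1) * cos(th2),
          1 + stats::runif(9, 0.5, 1) * sin(th2)))
  b <- blob$boundary[-nrow(blob$boundary), ]
  d2 <- outer(b[, 1], b[, 1], "-")^2 + outer(b[, 2], b[, 2], "-")^2
  expect_equal(max_diameter(blob), sqrt(max(d2)), tolerance = 1e-12)
})

test_that("contrast power sums the raster over the mask and is additive", {
  roi_a <- roi_from_control_points(circle_points(8, 0.4, c(0.7, 0.7)))
  roi_b <- roi_from_control_points(circle_points(8, 0.4, c(2.2, 2.2)))
  pw <- matrix(3, 300, 300)
  m <- sum(rasterize_roi(roi_a, 300, 300, 0.01))
  expect_equal(contrast_power(pw, roi_a, 0.01), 3 * m)
  set.seed(1)
  pw2 <- matrix(stats::runif(300 * 300), 300, 300)
  both <- roi_from_control_points(rbind(circle_points(4, 0.45, c(0.7, 0.7))))
  expect_equal(contrast_power(pw2, roi_a, 0.01) +
                 contrast_power(pw2, roi_b, 0.01),
               sum(pw2[rasterize_roi(roi_a, 300, 300, 0.01) |
                       rasterize_roi(roi_b, 300, 300, 0.01)]))
  outside <- roi_from_control_points(circle_points(6, 0.3, c(90, 90)))
  expect_error(contrast_power(pw, outside, 0.01), "empty")
})

test_that("blood volume counts track points inside the ROI", {
  tr <- data.frame(track = 1, frame = 1:30,
                   z_um = seq(200, 750, length.out = 30), x_um = 500,
                   subset = "all")
  maps <- accumulate_maps(tr, 300, 300, 5)
  roi_all <- roi_from_control_points(circle_points(8, 0.6, c(0.5, 0.5)))
  expect_equal(blood_volume(maps, roi_all), 30L)
  roi_off <- roi_from_control_points(circle_points(8, 0.1, c(1.3, 1.3)))
  expect_equal(blood_volume(maps, roi_off), 0L)
})

test_that("intervessel distance matches analytic and brute-force oracles", {
  # fully vascularized ROI -> 0
  tr <- expand.grid(z_um = (0:59) * 5, x_um = (0:59) * 5)
  tr <- data.frame(track = 1, frame = seq_len(nrow(tr)), tr, subset = "all")
  maps_full <- accumulate_maps(tr, 60, 60, 5)
  ivd0 <- intervessel_distance(maps_full)
  expect_equal(ivd0$mean_um, 0)

  # single vertical vessel line: mean distance = analytic mean of |x - x0|
  trl <- data.frame(track = 1, frame = 1:64, z_um = (0:63) * 5,
                    x_um = 30 * 5, subset = "all")
  maps_line <- accumulate_maps(trl, 64, 64, 5)
  ivd <- intervessel_distance(maps_line)
  cols <- 1:64
  expected <- mean(abs(cols[-31] - 31)) * 5
  expect_equal(ivd$mean_um, expected, tolerance = 1e-9)

  # exact equality with the O(n^2) brute-force search on a 64 x 64 map
  set.seed(8)
  dens <- matrix(0L, 64, 64)
  dens[sample(64 * 64, 25)] <- 1L
  maps_toy <- structure(list(density = dens, velocity = dens * NA_real_,
                             pitch_um = 5), class = "sr_maps")
  ivd_toy <- intervessel_distance(maps_toy)
  bf <- brute_force_distance(dens >= 1) * 5
  expect_equal(ivd_toy$distance_um, bf, tolerance = 1e-12)

  # no vascular pixels -> explicit failure
  maps_none <- structure(list(density = matrix(0L, 8, 8),
                              velocity = matrix(NA_real_, 8, 8),
                              pitch_um = 5), class = "sr_maps")
  expect_error(intervessel_distance(maps_none), "vascular")
})

test_that("adding vessels can only shorten intervessel distances", {
  set.seed(10)
  dens1 <- matrix(0L, 64, 64); dens1[sample(64 * 64, 10)] <- 1L
  dens2 <- dens1; dens2[sample(which(dens2 == 0), 10)] <- 1L
  mk <- function(d) structure(list(density = d, velocity = d * NA_real_,
                                   pitch_um = 5), class = "sr_maps")
  d1 <- intervessel_distance(mk(dens1))$distance_um
  d2 <- intervessel_distance(mk(dens2))$distance_um
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("DM matches closed forms and is reversal-invariant", {
  straight <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_identical(distance_metric(straight), 1)
  th <- seq(0, pi, length.out = 100)
  semi <- cbind(cos(th), sin(th))
  expect_equal(distance_metric(semi), pi / 2, tolerance = 1e-3)
  set.seed(2)
  poly <- cbind(cumsum(stats::rnorm(20)), cumsum(stats::rnorm(20)))
  # independent re-implementation
  oracle <- sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)) /
    sqrt(sum((poly[20, ] - poly[1, ])^2))
  expect_equal(distance_metric(poly), oracle, tolerance = 1e-12)
  expect_equal(distance_metric(poly[20:1, ]), distance_metric(poly))
  expect_gte(distance_metric(poly), 1)
  expect_error(distance_metric(rbind(c(0, 0), c(1, 1), c(0, 0))),
               "coincident")
})

test_that("SOAM matches closed forms and transforms correctly", {
  expect_equal(soam(cbind(0:5, rep(0, 6))), 0)
  # full circle radius r: total angle 2 pi over length 2 pi r -> 1/r
  th <- seq(0, 2 * pi, length.out = 400)
  for (r in c(0.5, 2)) {
    expect_equal(soam(cbind(r * cos(th), r * sin(th))), 1 / r,
                 tolerance = 0.02 / r)
  }
  # right-angle bend of total length L -> (pi/2)/L
  bend <- rbind(c(0, 0), c(2, 0), c(2, 3))
  expect_equal(soam(bend), (pi / 2) / 5, tolerance = 1e-12)
  # rigid-motion invariance; 1/c scaling under uniform scaling
  set.seed(3)
  poly <- cbind(cumsum(stats::rnorm(15)), cumsum(stats::rnorm(15)))
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- sweep(poly %*% R, 2, c(3, -2), "+")
  expect_equal(soam(moved), soam(poly), tolerance = 1e-9)
  expect_equal(soam(poly * 2), soam(poly) / 2, tolerance = 1e-9)
})

test_that("box-counting dimension matches analytic sets", {
  plane <- matrix(1L, 512, 512)
  expect_equal(box_counting_dimension(plane)$dimension, 2, tolerance = 0.05)
  line <- matrix(0L, 512, 512); line[256, ] <- 1L
  expect_equal(box_counting_dimension(line)$dimension, 1, tolerance = 0.05)
  g <- sierpinski_gasket(9)
  fd <- box_counting_dimension(g)
  expect_equal(fd$dimension, log(3) / log(2), tolerance = 0.05)
  # translation by sub-box offsets moves the estimate < 0.05
  shifted <- matrix(0L, 512, 512)
  shifted[4:512, 3:512] <- g[1:509, 1:510]
  expect_equal(box_counting_dimension(shifted)$dimension, fd$dimension,
               tolerance = 0.05)
  expect_error(box_counting_dimension(matrix(0L, 64, 64)), "no occupied")
  small <- matrix(1L, 70, 70)
  expect_error(box_counting_dimension(small), "usable scales")
})

test_that("vessel paths are extracted from skeletons with correct topology", {
  # single straight vessel -> one path with DM ~ 1
  m <- matrix(0L, 80, 80); m[10:70, 40] <- 1L
  p <- extract_vessel_paths(m, pitch_um = 5)
  expect_equal(length(p), 1)
  expect_equal(distance_metric(p[[1]]), 1, tolerance = 1e-6)
  # Y-junction -> 3 paths meeting at one branch point
  m2 <- matrix(0L, 100, 100)
  m2[10:50, 50] <- 1L
  for (k in 0:30) { m2[50 + k, 50 - k] <- 1L; m2[50 + k, 50 + k] <- 1L }
  p2 <- extract_vessel_paths(m2, pitch_um = 5, min_length_um = 20)
  expect_equal(length(p2), 3)
  ends <- do.call(rbind, lapply(p2, function(q) rbind(q[1, ], q[nrow(q), ])))
  hub <- c((50 - 1) * 5, (50 - 1) * 5)
  at_hub <- rowSums(abs(sweep(ends, 2, hub)) <= 10) == 2
  expect_equal(sum(at_hub), 3)
  # sinusoidal vessel: arclength within 5% of the analytic curve
  t <- seq(0, 4 * pi, length.out = 400)
  zz <- round(20 + t * 6); xx <- round(50 + 10 * sin(t))
  m3 <- matrix(0L, 120, 100); m3[cbind(zz, xx)] <- 1L
  p3 <- extract_vessel_paths(m3, pitch_um = 5, min_length_um = 20)
  len <- sum(vapply(p3, function(q) sum(sqrt(rowSums(diff(q)^2))), numeric(1)))
  arc <- sum(sqrt(rowSums(diff(cbind(zz * 5, xx * 5))^2)))
  expect_equal(len, arc, tolerance = 0.05)
  expect_equal(extract_vessel_paths(matrix(0L, 30, 30), pitch_um = 5), list())
})

test_that("vascular pruning raises intervessel distance across seeds", {
  higher <- 0
  for (s in 1:10) {
    mk <- function(morph) {
      cfg <- scene_config(depth_mm = 1, width_mm = 1.4, morphology = morph,
                          branch_depth = 2, n_frames = 40, n_bubbles = 40,
                          seed = s)
      net <- generate_vessel_network(cfg)
      traj <- simulate_mb_trajectories(net, cfg)
      nz <- 100; nx <- 140
      iz <- pmin(pmax(round(traj$z_mm * 100) + 1, 1), nz)
      ix <- pmin(pmax(round(traj$x_mm * 100) + 1, 1), nx)
      dens <- matrix(0L, nz, nx)
      for (k in seq_along(iz)) dens[iz[k], ix[k]] <- dens[iz[k], ix[k]] + 1L
      maps <- structure(list(density = dens, velocity = dens * NA_real_,
                             pitch_um = 10), class = "sr_maps")
      intervessel_distance(maps)$mean_um
    }
    higher <- higher + (mk("pruned") > mk("chaotic"))
  }
  expect_gte(higher, 8)
})
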