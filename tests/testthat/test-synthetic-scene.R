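test_that("vessel networks have the constructed segment count and topology", {
  cfg <- scene_config(branch_depth = 3, n_children = 2, seed = 7)
  net <- generate_vessel_network(cfg)
  expect_equal(length(net$segments), 1 + 2 + 4 + 8)
  # child start coincides with a point on its parent
  for (i in which(net$parent > 0)) {
    pp <- net$segments[[net$parent[i]]]
    child_start <- net$segments[[i]][1, ]
    d <- sqrt((pp[, 1] - child_start[1])^2 + (pp[, 2] - child_start[2])^2)
    expect_lt(min(d), 1e-9)
  }
  expect_true(all(net$radius_um > 0))
  expect_true(all(net$speed_mm_s > 0))
  # all points inside the field
  allp <- do.call(rbind, net$segments)
  expect_true(all(allp[, 1] >= 0 & allp[, 1] <= cfg$depth_mm))
  expect_true(all(allp[, 2] >= 0 & allp[, 2] <= cfg$width_mm))
})

test_that("depth-0 network is a single root segment", {
  net <- generate_vessel_network(scene_config(branch_depth = 0))
  expect_equal(length(net$segments), 1L)
  expect_equal(net$parent, 0L)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- scene_config(branch_depth = 3, seed = 7)
  expect_identical(generate_vessel_network(cfg), generate_vessel_network(cfg))
  net <- generate_vessel_network(cfg)
  cfg2 <- paper_regime_config(seed = 7, n_frames = 20, n_bubbles = 5)
  net2 <- generate_vessel_network(cfg2)
  expect_identical(simulate_mb_trajectories(net2, cfg2),
                   simulate_mb_trajectories(net2, cfg2))
  expect_identical(generate_dla_cluster(500, seed = 11),
                   generate_dla_cluster(500, seed = 11))
})

test_that("infeasible geometry is rejected", {
  expect_error(generate_vessel_network(
    scene_config(depth_mm = 0.1, root_radius_um = 100)), "infeasible")
})

test_that("bubbles advect at speed/frame-rate along the centerline", {
  cfg <- scene_config(depth_mm = 3, width_mm = 2, branch_depth = 0,
                      n_frames = 50, n_bubbles = 4, root_speed_mm_s = 1,
                      frame_rate_hz = 1000, radial_jitter_frac = 0,
                      root_radius_um = 0.001, seed = 2)
  net <- generate_vessel_network(cfg)
  traj <- simulate_mb_trajectories(net, cfg)
  for (b in unique(traj$bubble)) {
    tb <- traj[traj$bubble == b, ]
    step <- sqrt(diff(tb$z_mm)^2 + diff(tb$x_mm)^2) * 1000  # um
    # 1 mm/s at 1000 Hz = 1 um/frame (recirculation jumps excluded)
    expect_true(all(abs(step[step < 10] - 1) < 0.05))
  }
})

test_that("radius-0 vessels put every bubble exactly on the centerline", {
  cfg <- scene_config(branch_depth = 0, n_frames = 20, n_bubbles = 5,
                      root_radius_um = 1e-6, radial_jitter_frac = 0, seed = 4)
  net <- generate_vessel_network(cfg)
  traj <- simulate_mb_trajectories(net, cfg)
  seg <- net$segments[[1]]
  for (k in seq_len(nrow(traj))) {
    d <- min(sqrt((seg[, 1] - traj$z_mm[k])^2 + (seg[, 2] - traj$x_mm[k])^2))
    # within one polyline discretization step of the centerline
    expect_lt(d, 0.08)
  }
})

test_that("bubble occupancy stays inside vessel tubes and count is conserved", {
  cfg <- paper_regime_config(seed = 5, n_frames = 60, n_bubbles = 50)
  net <- generate_vessel_network(cfg)
  traj <- simulate_mb_trajectories(net, cfg)
  # point-in-tube oracle: distance to assigned segment centerline <= radius
  # (+ small slack for polyline discretization and field clamping)
  for (k in sample.int(nrow(traj), 300)) {
    seg <- net$segments[[traj$segment[k]]]
    d_mm <- min(sqrt((seg[, 1] - traj$z_mm[k])^2 + (seg[, 2] - traj$x_mm[k])^2))
    expect_lt(d_mm * 1000, net$radius_um[traj$segment[k]] + 40)
  }
  # recirculation: constant bubble count per frame
  expect_true(all(table(traj$frame) == cfg$n_bubbles))
})

test_that("IQ synthesis renders bubbles, clutter, and noise as configured", {
  # 0 bubbles, 0 clutter, 0 noise -> all-zero stack
  cfg0 <- scene_config(depth_mm = 0.6, width_mm = 0.6, n_frames = 5,
                       n_bubbles = 0, clutter_rank = 0, noise_sigma0 = 0,
                       seed = 1)
  net0 <- generate_vessel_network(cfg0)
  sc0 <- synthesize_iq(simulate_mb_trajectories(net0, cfg0), net0, cfg0)
  expect_equal(max(Mod(sc0$iq$data)), 0)

  # 1 static bubble, no clutter/noise -> per-frame argmax at nearest pixel
  traj <- manual_traj(1L, 1:5, 0.31, 0.33)
  sc1 <- synthesize_iq(traj, net0, cfg0)
  for (f in 1:5) {
    pk <- which(Mod(sc1$iq$data[, , f]) == max(Mod(sc1$iq$data[, , f])),
                arr.ind = TRUE)
    expect_equal(as.integer(pk[1, 1]), round(310 / cfg0$pitch_axial_um) + 1)
    expect_equal(as.integer(pk[1, 2]), round(330 / cfg0$pitch_lateral_um) + 1)
  }

  # clutter rank 3, no bubbles/noise -> numerical Casorati rank is 3
  cfg3 <- scene_config(depth_mm = 0.8, width_mm = 0.8, n_frames = 40,
                       n_bubbles = 0, clutter_rank = 3, noise_sigma0 = 0,
                       seed = 6)
  net3 <- generate_vessel_network(cfg3)
  sc3 <- synthesize_iq(simulate_mb_trajectories(net3, cfg3), net3, cfg3)
  sv <- svd(matrix(sc3$iq$data, ncol = 40))$d
  expect_gt(sv[3] / sv[1], 1e-6)
  expect_lt(sv[4] / sv[1], 1e-10)

  # PSF narrower than the grid is unrenderable
  expect_error(synthesize_iq(traj, net0,
                             scene_config(psf_sigma_axial_um = 5)),
               "unresolvable")
})

test_that("rendered PSFs per frame equal alive bubbles per frame", {
  cfg <- scene_config(depth_mm = 1, width_mm = 1, n_frames = 10,
                      n_bubbles = 3, clutter_rank = 0, noise_sigma0 = 0,
                      branch_depth = 0, seed = 8)
  net <- generate_vessel_network(cfg)
  traj <- simulate_mb_trajectories(net, cfg)
  sc <- synthesize_iq(traj, net, cfg)
  for (f in c(1, 5, 10)) {
    energy <- sum(Mod(sc$iq$data[, , f])^2)
    expect_gt(energy, 0)
    expect_equal(sum(traj$frame == f), 3)
  }
})

test_that("DLA clusters are 4-connected, deterministic, and n=1 degenerate", {
  expect_equal(sum(generate_dla_cluster(1, seed = 1)), 1)
  expect_error(generate_dla_cluster(0), "positive")
  d <- generate_dla_cluster(400, seed = 3)
  expect_equal(sum(d), 400)
  lab <- EBImage::bwlabel(d)  # 8-connected labels; 4-connectivity is stricter
  expect_equal(max(lab), 1)
  # strict 4-connectivity: every particle (except seed) touches another
  idx <- which(d == 1, arr.ind = TRUE)
  pad <- matrix(0L, nrow(d) + 2, ncol(d) + 2)
  pad[2:(nrow(d) + 1), 2:(ncol(d) + 1)] <- d
  touch <- pad[cbind(idx[, 1], idx[, 2] + 1)] +
    pad[cbind(idx[, 1] + 2, idx[, 2] + 1)] +
    pad[cbind(idx[, 1] + 1, idx[, 2])] +
    pad[cbind(idx[, 1] + 1, idx[, 2] + 2)]
  expect_true(all(touch >= 1))
})

test_that("DLA mass-radius exponent agrees with box-counting dimension", {
  d <- generate_dla_cluster(10000, seed = 1)
  fd <- box_counting_dimension(d)
  idx <- which(d == 1, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  rs <- 2^(3:floor(log2(max(r))))
  nr <- vapply(rs, function(R) sum(r <= R), numeric(1))
  mr <- unname(stats::coef(stats::lm(log(nr) ~ log(rs)))[2])
  expect_lt(abs(mr - fd$dimension), 0.15)
})

test_that("trajectory and network exports round-trip through disk", {
  cfg <- scene_config(depth_mm = 1, width_mm = 1, n_frames = 4, n_bubbles = 2,
                      branch_depth = 1, seed = 2)
  net <- generate_vessel_network(cfg)
  traj <- simulate_mb_trajectories(net, cfg)
  tf <- tempfile(fileext = ".csv"); nf <- tempfile(fileext = ".json")
  write_trajectories(traj, tf)
  back <- utils::read.csv(tf)
  expect_equal(back$z_mm, traj$z_mm)
  write_vessel_network(net, nf)
  j <- jsonlite::read_json(nf, simplifyVector = FALSE)
  expect_equal(length(j$segments), length(net$segments))
})
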