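#' Run the full ULM pipeline on a synthetic scene
#'
#' Orchestrates the stages in acquisition order — clutter filter, noise
#' equalization, power imaging, spline upsampling, Fourier subset
#' separation, localization, tracking, map accumulation, vascular metrics —
#' over one or more acquisitions of the same scene, pooling all tracked
#' points of a session into one super-resolved reconstruction. Artifacts
#' (centroid/track CSVs, map TIFFs, metrics JSON, manifest, log) are written
#' under `out_dir`.
#'
#' @param config a [scene_config], a YAML file path describing one, or a
#'   list of `scene_config`s (one per acquisition; pooled).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param cutoff SVD cutoff policy (index or `"adaptive"`).
#' @param speed_bounds_mm_s Fourier-cone speed thresholds, mm/s.
#' @param min_corr,min_persistence localization / tracking thresholds.
#' @param max_disp_um link gating distance; default
#'   `1.5 * max segment speed / frame rate`.
#' @param sr_pitch_um super-resolution pitch (default 5).
#' @param use_subsets localize the three Fourier subsets separately (the
#'   full pipeline) or the unseparated stack (faster for small scenes).
#' @param verbose print stage progress and timings.
#' @return list of class `ulm_run`: `maps` (`sr_maps`), `tracks`,
#'   `centroids`, `power` (diffraction-limited raster), `metrics`
#'   (per-tumor scalar read-outs), `spectrum`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cutoff = "adaptive",
                         speed_bounds_mm_s = c(1, 5), min_corr = 0.6,
                         min_persistence = 10L, max_disp_um = NULL,
                         sr_pitch_um = 5, use_subsets = TRUE,
                         verbose = FALSE) {
  if (is.character(config)) config <- config_from_yaml(config)
  configs <- if (inherits(config, "scene_config")) list(config) else config
  stop_if(!all(vapply(configs, inherits, logical(1), "scene_config")),
          "`config` must be scene_config(s) or a YAML path")
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  all_tracks <- list(); all_cent <- list()
  power_sum <- NULL; spectrum <- NULL
  psf <- NULL
  grid_sr <- NULL
  for (a in seq_along(configs)) {
    cfg <- configs[[a]]
    say("acquisition %d/%d: synthesizing scene (seed %d)", a,
        length(configs), cfg$seed)
    net <- generate_vessel_network(cfg)
    traj <- simulate_mb_trajectories(net, cfg)
    scene <- synthesize_iq(traj, net, cfg)
    say("clutter filtering (%d frames)", cfg$n_frames)
    filt <- svd_clutter_filter(scene$iq, cutoff)
    spectrum <- filt$spectrum
    say("cutoff %d", filt$spectrum$cutoff)
    # noise reference: bubble- and clutter-free twin of the scene
    ncfg <- cfg; ncfg$n_bubbles <- 0L; ncfg$clutter_rank <- 0L
    ncfg$seed <- cfg$seed + 7777L
    nref <- synthesize_iq(simulate_mb_trajectories(net, ncfg), net, ncfg)
    prof <- estimate_noise_profile(nref$iq, filt$spectrum$cutoff)
    eq <- apply_noise_equalization(filt$iq, prof)
    pw <- power_doppler(eq)
    power_sum <- if (is.null(power_sum)) pw else power_sum + pw
    say("upsampling to %.1f um", sr_pitch_um)
    sr <- upsample_iq(eq, sr_pitch_um)
    grid_sr <- dim(sr$data)[1:2]
    if (is.null(psf)) {
      psf <- build_psf(cfg$psf_sigma_axial_um, cfg$psf_sigma_lateral_um,
                       sr_pitch_um)
    }
    say("localizing")
    cent <- if (use_subsets && cfg$n_frames >= 8) {
      subs <- separate_mb_subsets(sr, speed_bounds_mm_s)
      do.call(rbind, Map(function(s, lab)
        localize_ensemble(s, psf, min_corr, subset = lab),
        subs, names(subs)))
    } else {
      localize_ensemble(sr, psf, min_corr)
    }
    say("%d centroids", nrow(cent))
    if (is.null(max_disp_um)) {
      # 1.5x the largest per-frame advection plus a localization-jitter
      # allowance of two super-pixels
      max_disp_um <- 1.5 * max(net$speed_mm_s) / cfg$frame_rate_hz * 1000 +
        2 * sr_pitch_um
    }
    tr <- link_centroids(cent, max_disp_um)
    tr <- filter_tracks(tr, min_persistence)
    if (nrow(tr)) tr <- track_velocities(tr, cfg$frame_rate_hz)
    say("%d track points after persistence filter", nrow(tr))
    if (nrow(tr)) {
      tr$acquisition <- a
      all_tracks[[a]] <- tr
    }
    all_cent[[a]] <- cent
  }
  tracks <- if (length(all_tracks)) {
    pooled <- all_tracks[[1]]
    if (length(all_tracks) > 1) for (k in 2:length(all_tracks)) {
      t2 <- all_tracks[[k]]
      t2$track <- t2$track + max(pooled$track)
      pooled <- rbind(pooled, t2)
    }
    class(pooled) <- c("track_set", "data.frame")
    pooled
  } else {
    data.frame(track = integer(0), frame = integer(0), z_um = numeric(0),
               x_um = numeric(0), subset = character(0),
               speed_mm_s = numeric(0))
  }
  maps <- accumulate_maps(tracks, grid_sr[1], grid_sr[2], sr_pitch_um)
  say("maps accumulated: %d counts", sum(maps$density))
  metrics <- compute_scene_metrics(maps, power_sum, tracks)
  manifest <- list(stages = c("filter", "equalize", "power", "upsample",
                              if (use_subsets) "separate", "localize",
                              "track", "maps", "metrics"),
                   n_acquisitions = length(configs),
                   cutoff = spectrum$cutoff,
                   n_tracks = length(unique(tracks$track)),
                   n_track_points = nrow(tracks))
  res <- structure(list(maps = maps, tracks = tracks,
                        centroids = do.call(rbind, all_cent),
                        power = power_sum, metrics = metrics,
                        spectrum = spectrum, manifest = manifest,
                        log = log_lines),
                   class = "ulm_run")
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# whole-field scalar read-outs of a reconstruction (ROI-free variants; the
# ROI-based metrics live in vascular-metrics.R)
compute_scene_metrics <- function(maps, power, tracks) {
  vasc <- maps$density >= 1
  ivd <- if (any(vasc)) {
    d <- euclidean_distance_to(vasc) * maps$pitch_um
    mean(d[!vasc])
  } else NA_real_
  paths <- extract_vessel_paths(maps)
  # closed loops have no chord; DM is defined on open paths only
  open_paths <- paths[vapply(paths, function(p)
    sum((p[1, ] - p[nrow(p), ])^2) > 0, logical(1))]
  dms <- vapply(open_paths, function(p) distance_metric(p), numeric(1))
  soams <- vapply(paths[vapply(paths, nrow, integer(1)) >= 3],
                  function(p) soam(p / 1000), numeric(1))  # rad/mm
  fd <- if (any(vasc) && min(dim(vasc)) >= 64)
    box_counting_dimension(vasc) else list(dimension = NA_real_,
                                           r_squared = NA_real_)
  list(
    contrast_power = sum(power),
    blood_volume = sum(maps$density),
    intervessel_distance_um = ivd,
    mean_velocity_mm_s = if (nrow(tracks) && "speed_mm_s" %in% names(tracks))
      mean(maps$velocity[maps$density > 0], na.rm = TRUE) else NA_real_,
    dm = if (length(dms)) stats::median(dms) else NA_real_,
    soam_rad_mm = if (length(soams)) stats::median(soams) else NA_real_,
    hausdorff_dim = fd$dimension,
    hausdorff_r2 = fd$r_squared,
    n_vessel_paths = length(paths)
  )
}

write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(res$centroids, p("centroids.csv"), row.names = FALSE)
  utils::write.csv(res$tracks, p("tracks.csv"), row.names = FALSE)
  write_sr_maps(res$maps, p("density.tiff"), p("velocity.tiff"))
  jsonlite::write_json(res$metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- c(res$manifest,
                list(artifacts = c("centroids.csv", "tracks.csv",
                                   "density.tiff", "velocity.tiff",
                                   "metrics.json", "run.log")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  writeLines(res$log, p("run.log"))
  invisible(out_dir)
}

config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scene_config, y)
}

#' @export
print.ulm_run <- function(x, ...) {
  cat(sprintf("<ulm_run> %d tracks (%d points), cutoff %d\n",
              x$manifest$n_tracks, x$manifest$n_track_points,
              x$manifest$cutoff))
  invisible(x)
}
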