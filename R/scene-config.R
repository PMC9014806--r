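#' Synthetic acquisition configuration
#'
#' Bundles every knob of the synthetic scene generator. Defaults reproduce
#' the acquisition geometry the pipeline targets: a ~2.93 mm deep by ~8.82 mm
#' wide field imaged at 20 MHz with a post-compounding effective frame rate
#' of 1000 Hz and 1600 frames per acquisition, microbubbles flowing through a
#' branching vessel network embedded in low-rank moving tissue clutter with
#' depth-dependent noise.
#'
#' @param depth_mm,width_mm field of view (axial depth, lateral width), mm.
#' @param pitch_axial_um,pitch_lateral_um native IQ grid pitch, micrometers.
#' @param frame_rate_hz effective frame rate (Hz).
#' @param n_frames frames per acquisition.
#' @param morphology vessel-network preset: `"chaotic"` (tortuous, randomly
#'   oriented branches), `"columnar"` (near-parallel columns descending from
#'   the membrane edge), or `"pruned"` (chaotic but with an avascular lateral
#'   region, emulating vascular disruption).
#' @param branch_depth branching generations below the root (0 = root only).
#' @param n_children children per segment node.
#' @param root_radius_um,radius_decay vessel radius at the root (um) and
#'   per-generation multiplicative decay.
#' @param root_speed_mm_s,speed_decay flow speed at the root (mm/s) and decay.
#' @param n_bubbles circulating microbubbles (constant count; recirculation).
#' @param mb_amp_meanlog,mb_amp_sdlog log-normal amplitude distribution
#'   across bubbles (constant within a track).
#' @param radial_jitter_frac per-frame radial jitter as a fraction of the
#'   vessel radius.
#' @param psf_sigma_axial_um,psf_sigma_lateral_um Gaussian PSF standard
#'   deviations of the rendered microbubble echo (um).
#' @param clutter_rank number of spatiotemporal tissue-clutter modes.
#' @param clutter_db clutter amplitude above the mean microbubble amplitude
#'   (dB; tissue dominates contrast signal by >= 20 dB).
#' @param clutter_max_hz maximum temporal frequency of clutter motion (< 20).
#' @param noise_sigma0 noise standard deviation at zero depth (per channel).
#' @param noise_tau_mm depth constant of the noise law:
#'   variance proportional to `exp(depth / noise_tau_mm)`.
#' @param seed RNG seed used by the generators.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(depth_mm = 2.93, width_mm = 8.82,
                         pitch_axial_um = 19.25, pitch_lateral_um = 38.5,
                         frame_rate_hz = 1000, n_frames = 1600,
                         morphology = c("chaotic", "columnar", "pruned"),
                         branch_depth = 3, n_children = 2,
                         root_radius_um = 50, radius_decay = 0.7,
                         root_speed_mm_s = 3, speed_decay = 0.8,
                         n_bubbles = 50,
                         mb_amp_meanlog = 0, mb_amp_sdlog = 0.5,
                         radial_jitter_frac = 0.1,
                         psf_sigma_axial_um = 25, psf_sigma_lateral_um = 40,
                         clutter_rank = 15, clutter_db = 30,
                         clutter_max_hz = 15,
                         noise_sigma0 = 0.05, noise_tau_mm = 1.5,
                         seed = 1L) {
  morphology <- match.arg(morphology)
  assert_scalar_num(depth_mm, "depth_mm", positive = TRUE)
  assert_scalar_num(width_mm, "width_mm", positive = TRUE)
  assert_scalar_num(pitch_axial_um, "pitch_axial_um", positive = TRUE)
  assert_scalar_num(pitch_lateral_um, "pitch_lateral_um", positive = TRUE)
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  stop_if(n_frames < 1, "`n_frames` must be >= 1")
  stop_if(branch_depth < 0, "`branch_depth` must be >= 0")
  stop_if(clutter_max_hz >= 20, "clutter motion must stay below 20 Hz")
  structure(as.list(environment()), class = "scene_config")
}

# pixel grid implied by a scene_config
config_grid <- function(config) {
  list(
    n_axial = max(2L, floor(config$depth_mm * 1000 / config$pitch_axial_um) + 1L),
    n_lateral = max(2L, floor(config$width_mm * 1000 / config$pitch_lateral_um) + 1L)
  )
}
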