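#' Grow a 2-D lattice diffusion-limited aggregation (DLA) cluster
#'
#' Standard on-lattice DLA: a seed particle sits at the center, random
#' walkers are launched one at a time from a birth circle of radius
#' (current cluster radius + 5), take 4-neighbor unit steps, stick on
#' 4-contact with the cluster, and are discarded beyond a kill radius of
#' 3x the birth radius. DLA clusters are the diffusion-limited growth limit
#' of tumor angiogenesis models and have a box-counting fractal dimension of
#' about 1.71 in two dimensions, which makes them the reference fixture for
#' the fractal-dimension estimator.
#'
#' @param n_particles number of particles in the cluster (>= 1).
#' @param seed RNG seed; clusters are bit-identical per seed.
#' @return Binary integer matrix (occupied-site mask, cropped to the
#'   cluster's bounding box).
#' @seealso [box_counting_dimension()]
#' @export
generate_dla_cluster <- function(n_particles, seed = 1L) {
  stop_if(!is.numeric(n_particles) || length(n_particles) != 1L ||
          n_particles < 1, "`n_particles` must be a positive count")
  with_seed(seed, function() dla_grow_cpp(as.integer(n_particles)))
}
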