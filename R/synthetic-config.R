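#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic-data module into a validated list.
#' Defaults mirror the study conditions the pipeline is designed for: 43
#' subjects viewing 36 foods drawn from 5 naturalistic categories, 17
#' food-responsive ROIs of which 6 form a "prefrontal-like" network, 10 a
#' "limbic-like" network, and 1 is an outlier region with an unrelated
#' representational geometry (emulating early visual cortex).
#'
#' @param seed Integer seed used by generators that accept a config.
#' @param n_subjects Number of simulated subjects.
#' @param n_items Number of food items (conditions).
#' @param n_categories Number of latent food categories.
#' @param latent_dims Dimensionality of the latent food-property space.
#' @param n_rois_net1,n_rois_net2 ROI counts for the two planted networks.
#' @param n_outlier_rois Number of planted outlier ROIs.
#' @param voxels_per_roi Voxel count per simulated ROI.
#' @param pattern_noise_sd SD of i.i.d. Gaussian noise added to voxel patterns.
#' @param choice_temperature Softmax temperature of the odd-one-out choice
#'   model; lower values give more deterministic choices.
#' @param triplet_reps Number of simulated responses per unique triplet.
#' @param volume_shape Integer triple, shape of simulated beta volumes.
#' @param truth_frac Approximate fraction of the searchlight volume occupied
#'   by the planted signal cuboid.
#' @param tr_seconds Repetition time of the simulated acquisition, seconds.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_subjects = 43L,
                         n_items = 36L,
                         n_categories = 5L,
                         latent_dims = 2L,
                         n_rois_net1 = 6L,
                         n_rois_net2 = 10L,
                         n_outlier_rois = 1L,
                         voxels_per_roi = 120L,
                         pattern_noise_sd = 0.6,
                         choice_temperature = 0.15,
                         triplet_reps = 5L,
                         volume_shape = c(16L, 16L, 10L),
                         truth_frac = 0.3,
                         tr_seconds = 2.5) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_items = as.integer(n_items),
    n_categories = as.integer(n_categories),
    latent_dims = as.integer(latent_dims),
    n_rois_net1 = as.integer(n_rois_net1),
    n_rois_net2 = as.integer(n_rois_net2),
    n_outlier_rois = as.integer(n_outlier_rois),
    voxels_per_roi = as.integer(voxels_per_roi),
    pattern_noise_sd = pattern_noise_sd,
    choice_temperature = choice_temperature,
    triplet_reps = as.integer(triplet_reps),
    volume_shape = as.integer(volume_shape),
    truth_frac = truth_frac,
    tr_seconds = tr_seconds
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  counts <- c("n_subjects", "n_items", "n_categories", "latent_dims",
              "n_rois_net1", "n_rois_net2", "voxels_per_roi", "triplet_reps")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("synth_config: `", f, "` must be a count >= 1")
  }
  if (cfg$n_outlier_rois < 0L)
    stop("synth_config: `n_outlier_rois` must be >= 0")
  if (cfg$n_items < 3L)
    stop("synth_config: `n_items` must be >= 3")
  if (cfg$pattern_noise_sd < 0)
    stop("synth_config: `pattern_noise_sd` must be non-negative")
  if (cfg$choice_temperature <= 0)
    stop("synth_config: `choice_temperature` must be positive")
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 1L))
    stop("synth_config: `volume_shape` must be a positive integer triple")
  if (cfg$truth_frac <= 0 || cfg$truth_frac >= 1)
    stop("synth_config: `truth_frac` must lie in (0, 1)")
  if (cfg$tr_seconds <= 0)
    stop("synth_config: `tr_seconds` must be positive")
  invisible(cfg)
}
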