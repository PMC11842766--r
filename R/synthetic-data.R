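# Synthetic cohort with planted ground truth. Every downstream stage of the
# pipeline (behavioural similarity, neural RDMs, network clustering, RSA,
# searchlight, modulated GLM) can be exercised against structure planted here.

# Within-category spread of item coordinates around their centroid. Adjacent
# centroid separation in the default layout (~0.95) is >= 4x this value, so
# planted categories are well separated but not degenerate.
.within_category_sd <- 0.09

# Centroid layout in the latent food-property space: K categories on an
# ellipse stretched along dimension 1 (the "processing" axis, the dominant
# axis of food similarity). The gentle overall scale keeps the exp(-distance)
# similarity kernel in its quasi-linear regime, so the first two principal
# components of the resulting similarity structure carry ~80% of its variance
# while the K categories stay well separated.
.category_centroids <- function(n_categories, latent_dims) {
  K <- n_categories
  centroids <- matrix(0, K, latent_dims)
  if (latent_dims == 1L) {
    centroids[, 1] <- if (K == 1L) 0 else seq(-0.9, 0.9, length.out = K)
    return(centroids)
  }
  theta <- pi / 2 + (seq_len(K) - 1L) * 2 * pi / K
  centroids[, 1] <- 0.9 * cos(theta)
  centroids[, 2] <- 0.7 * sin(theta)
  centroids
}

#' Generate a latent food-property space
#'
#' Draws `n_items` items around `n_categories` centroids in a low-dimensional
#' latent space. Dimension 1 plays the role of the food-processing axis;
#' ground-truth similarity between items is `exp(-d)` for Euclidean latent
#' distance `d`, so similarity lies in (0, 1] like a proportion-valued
#' behavioural similarity matrix. Each item also carries an independent
#' standard-normal `hedonic_score` used by the rating-task generator.
#'
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed; defaults to `cfg$seed`.
#' @return A list of class `food_space` with elements `coords`
#'   (`n_items x latent_dims`), `category_label`, `processing_score`,
#'   `hedonic_score` and the ground-truth similarity matrix `sim`.
#' @export
gen_food_space <- function(cfg, seed = cfg$seed) {
  validate_synth_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_items
  K <- cfg$n_categories
  centroids <- .category_centroids(K, cfg$latent_dims)
  label <- sort(rep_len(seq_len(K), n))
  spread <- if (K == 1L) 0 else .within_category_sd
  coords <- centroids[label, , drop = FALSE] +
    matrix(stats::rnorm(n * cfg$latent_dims, sd = spread), n, cfg$latent_dims)
  dmat <- as.matrix(stats::dist(coords))
  space <- list(
    coords = coords,
    category_label = label,
    processing_score = coords[, 1],
    hedonic_score = stats::rnorm(n),
    sim = exp(-dmat)
  )
  class(space) <- "food_space"
  space
}

#' Simulate odd-one-out triplet responses
#'
#' Enumerates all `choose(n, 3)` unordered triplets of items, repeats each
#' `reps` times, and for every presentation samples the "odd one out" under a
#' Luce/softmax choice model: item `x` is chosen odd with probability
#' proportional to `exp(sim(y, z) / temperature)` where `{y, z}` are the other
#' two items — the pair left over is the most-similar-looking pair. As
#' `temperature -> 0` the choice becomes the argmax of pair similarity.
#'
#' @param space A `food_space`.
#' @param reps Repetitions per unique triplet.
#' @param temperature Positive softmax temperature.
#' @param seed Optional integer seed.
#' @return A data frame with columns `item_a`, `item_b`, `item_c`, `odd`
#'   (`odd` is one of the three item ids).
#' @export
gen_triplet_responses <- function(space, reps = 5L, temperature = 0.15,
                                  seed = NULL) {
  stopifnot(inherits(space, "food_space"))
  n <- nrow(space$sim)
  if (n < 3L) stop("need at least 3 items to form triplets")
  if (temperature <= 0) stop("`temperature` must be positive")
  if (!is.null(seed)) set.seed(seed)
  trip <- t(utils::combn(n, 3L))
  trip <- trip[rep(seq_len(nrow(trip)), times = reps), , drop = FALSE]
  S <- space$sim
  # utility of declaring column k odd = similarity of the remaining pair
  u_a <- S[trip[, c(2, 3), drop = FALSE]]
  u_b <- S[trip[, c(1, 3), drop = FALSE]]
  u_c <- S[trip[, c(1, 2), drop = FALSE]]
  U <- cbind(u_a, u_b, u_c) / temperature
  U <- exp(U - apply(U, 1, max))
  P <- U / rowSums(U)
  r <- stats::runif(nrow(P))
  pick <- 1L + (r > P[, 1]) + (r > P[, 1] + P[, 2])
  data.frame(
    item_a = trip[, 1], item_b = trip[, 2], item_c = trip[, 3],
    odd = trip[cbind(seq_len(nrow(trip)), pick)]
  )
}

# Exponential kernel on a 1-D score vector: positive definite, entries in
# (0, 1], diagonal 1. `scale` multiplies distances (larger scale -> faster
# decay -> larger correlation distances).
.kernel_1d <- function(score, scale = 1) {
  exp(-scale * as.matrix(stats::dist(score)))
}

# Matrix square root of a symmetric PSD matrix via eigendecomposition.
# Signals an error when the matrix is materially non-PSD, which would indicate
# a generator bug (kernels used here are positive definite by construction).
.psd_sqrt <- function(C, tol = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values)))
    stop("target correlation structure is not positive semi-definite")
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Draw a condition x voxel pattern whose inter-condition correlation matrix
# approximates `C`: mix i.i.d. normal voxel columns by sqrt(C), then add
# i.i.d. noise.
.patterns_from_target <- function(sqrtC, n_voxels, noise_sd) {
  n <- nrow(sqrtC)
  P <- sqrtC %*% matrix(stats::rnorm(n * n_voxels), n, n_voxels)
  if (noise_sd > 0)
    P <- P + matrix(stats::rnorm(n * n_voxels, sd = noise_sd), n, n_voxels)
  P
}

#' Generate per-subject ROI voxel patterns with a planted network structure
#'
#' ROIs split into two networks with distinct target representational
#' geometries plus optional outlier ROIs. Network-1 targets derive from
#' latent dimension 1 (the processing axis): target condition correlation is
#' `exp(-|x_i - x_j|)`. Network-2 targets derive from the independent hedonic
#' score. Outlier ROIs get an unrelated random geometry with a 3x distance
#' scale, mimicking an early-visual-cortex region dominated by low-level image
#' features. Condition patterns are drawn by mixing i.i.d. voxel noise with
#' the matrix square root of the target structure, then adding i.i.d. noise
#' of sd `cfg$pattern_noise_sd`.
#'
#' @param cfg A [synth_config()].
#' @param space A `food_space` (provides the planted geometries).
#' @param seed Optional integer seed; defaults to `cfg$seed + 1`.
#' @param subject_jitter Between-subject representational variability: each
#'   subject's network geometry derives from the base score vector perturbed
#'   by Gaussian noise of sd `subject_jitter * sd(score)`. Without it, every
#'   subject shares one exact geometry and group t-tests treat even
#'   chance-level RDM overlaps as systematic effects; real cohorts vary.
#' @return A list with `patterns` (`patterns[[subject]][[roi_id]]` is a
#'   condition x voxel matrix), `roi_ids`, `network` (named character vector:
#'   `"net1"`, `"net2"` or `"outlier"`), and `target_rdms` (named list of the
#'   planted group-level RDMs, `1 - C`).
#' @export
gen_roi_patterns <- function(cfg, space, seed = cfg$seed + 1L,
                             subject_jitter = 1.5) {
  validate_synth_config(cfg)
  stopifnot(inherits(space, "food_space"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_items
  scores <- list(
    net1 = space$coords[, 1],
    net2 = space$hedonic_score,
    outlier = stats::rnorm(n)
  )
  scales <- c(net1 = 1, net2 = 1, outlier = 3)
  targets <- lapply(names(scores), function(g)
    .kernel_1d(scores[[g]], scale = scales[g]))
  names(targets) <- names(scores)
  network <- c(rep("net1", cfg$n_rois_net1),
               rep("net2", cfg$n_rois_net2),
               rep("outlier", cfg$n_outlier_rois))
  roi_ids <- sprintf("roi%02d", seq_along(network))
  names(network) <- roi_ids
  cond <- sprintf("food%02d", seq_len(n))
  patterns <- vector("list", cfg$n_subjects)
  names(patterns) <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  for (s in seq_len(cfg$n_subjects)) {
    # subject-specific geometry: one jittered score vector per network
    sqrts <- lapply(names(scores), function(g) {
      sc <- scores[[g]]
      if (subject_jitter > 0)
        sc <- sc + stats::rnorm(n, sd = subject_jitter * stats::sd(sc))
      .psd_sqrt(.kernel_1d(sc, scale = scales[g]))
    })
    names(sqrts) <- names(scores)
    subj <- vector("list", length(roi_ids))
    names(subj) <- roi_ids
    for (r in seq_along(roi_ids)) {
      P <- .patterns_from_target(sqrts[[network[r]]], cfg$voxels_per_roi,
                                 cfg$pattern_noise_sd)
      rownames(P) <- cond
      subj[[r]] <- P
    }
    patterns[[s]] <- subj
  }
  target_rdms <- lapply(targets, function(C) {
    d <- 1 - C
    dimnames(d) <- list(cond, cond)
    d
  })
  list(patterns = patterns, roi_ids = roi_ids, network = network,
       target_rdms = target_rdms)
}

#' Generate a searchlight test volume with an embedded signal region
#'
#' Builds small condition-wise beta volumes in which an axis-aligned cuboid
#' sub-region encodes a target RDM in its local voxel patterns (same mixing
#' construction as [gen_roi_patterns()]); all voxels outside the cuboid are
#' i.i.d. noise. The target geometry derives from dimension 1 of an internally
#' generated food space.
#'
#' @param cfg A [synth_config()]; `volume_shape` must be at least 8 in every
#'   dimension.
#' @param seed Optional integer seed; defaults to `cfg$seed + 2`.
#' @param n_subjects Number of subjects to simulate; the default keeps the
#'   volume-level fixture small enough for desk-scale group analysis.
#' @param noise_sd Noise sd inside the signal cuboid; defaults to
#'   `cfg$pattern_noise_sd`.
#' @return A list with `betas` (per subject, a condition x voxel matrix),
#'   `shape`, `mask` (logical 3-D array), `target_rdm`, and `truth`
#'   (logical 3-D array marking the signal cuboid).
#' @export
gen_searchlight_dataset <- function(cfg, seed = cfg$seed + 2L,
                                    n_subjects = 12L,
                                    noise_sd = cfg$pattern_noise_sd) {
  validate_synth_config(cfg)
  if (any(cfg$volume_shape < 8L))
    stop("`volume_shape` must be >= 8 in every dimension")
  if (!is.null(seed)) set.seed(seed)
  shape <- cfg$volume_shape
  space <- gen_food_space(cfg, seed = NULL)
  C <- .kernel_1d(space$coords[, 1])
  sqrtC <- .psd_sqrt(C)
  n <- cfg$n_items
  cond <- sprintf("food%02d", seq_len(n))

  side <- pmax(1L, pmin(shape, as.integer(round(shape * cfg$truth_frac^(1 / 3)))))
  lo <- pmax(1L, as.integer(floor((shape - side) / 2)) + 1L)
  hi <- lo + side - 1L
  if (any(hi > shape)) stop("signal cuboid does not fit inside the volume")
  truth <- array(FALSE, shape)
  truth[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  in_truth <- which(truth)

  V <- prod(shape)
  betas <- vector("list", n_subjects)
  names(betas) <- sprintf("sub%02d", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    B <- matrix(stats::rnorm(n * V), n, V)
    B[, in_truth] <- .patterns_from_target(sqrtC, length(in_truth), noise_sd)
    rownames(B) <- cond
    betas[[s]] <- B
  }
  target_rdm <- 1 - C
  dimnames(target_rdm) <- list(cond, cond)
  list(betas = betas, shape = shape, mask = array(TRUE, shape),
       target_rdm = target_rdm, truth = truth)
}

# Planted modulation pattern of the rating task: network-1 ROIs respond
# positively to self-control ratings and negatively to pleasantness ratings;
# network-2 ROIs respond equally positively in both conditions; outlier ROIs
# are unmodulated.
.psc_true_beta <- function(network, condition, strength) {
  sign <- ifelse(network == "net2", 1,
          ifelse(network == "outlier", 0,
                 ifelse(condition == "self_control", 1, -1)))
  sign * strength
}

#' Generate a rating-modulated (pleasantness / self-control) dataset
#'
#' Simulates, per subject, item ratings in two task conditions derived from
#' the items' hedonic scores plus subject-level taste and condition-level
#' noise (so within-subject inter-condition rating correlation is ~0.99 and
#' between-subject correlation ~0.9), together with rating-modulated ROI
#' responses following the planted network pattern: network-2 responses scale
#' positively with ratings in both conditions, network-1 responses scale
#' positively with self-control and negatively with pleasantness ratings.
#'
#' In `"betas"` mode the modulated regression coefficients are returned
#' directly with additive noise. In `"timeseries"` mode each subject x ROI x
#' condition yields a BOLD time series built by convolving event amplitudes
#' with the gamma-variate HRF (see [gamma_hrf()]) plus white noise, from which
#' the coefficients can be re-estimated with [fit_glm()].
#'
#' @param cfg A [synth_config()].
#' @param space A `food_space`.
#' @param seed Optional integer seed; defaults to `cfg$seed + 3`.
#' @param mode `"betas"` or `"timeseries"`.
#' @param mod_strength Magnitude of the planted modulated response.
#' @param beta_noise_sd Noise sd on returned betas (`"betas"` mode).
#' @param rating_subject_sd,rating_cond_sd SDs of subject-level and
#'   condition-level rating noise.
#' @param n_vols Volumes per simulated run (`"timeseries"` mode).
#' @param ts_noise_sd White-noise sd of the simulated time series.
#' @return A list with `ratings` (long data frame: subject, item, condition,
#'   rating), `network`, `roi_ids`, `truth` (planted beta per roi x
#'   condition), and either `betas` (long data frame) or `series`
#'   (per subject, per condition: `y` matrix `n_vols x n_rois`, `onsets`,
#'   `modulators`).
#' @export
gen_psc_dataset <- function(cfg, space, seed = cfg$seed + 3L,
                            mode = c("betas", "timeseries"),
                            mod_strength = 0.8,
                            beta_noise_sd = 0.3,
                            rating_subject_sd = 0.25,
                            rating_cond_sd = 0.1,
                            n_vols = 206L,
                            ts_noise_sd = 0.1) {
  validate_synth_config(cfg)
  stopifnot(inherits(space, "food_space"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_items
  conditions <- c("pleasantness", "self_control")
  network <- c(rep("net1", cfg$n_rois_net1),
               rep("net2", cfg$n_rois_net2),
               rep("outlier", cfg$n_outlier_rois))
  roi_ids <- sprintf("roi%02d", seq_along(network))
  names(network) <- roi_ids

  ratings <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(s) {
    taste <- space$hedonic_score +
      stats::rnorm(n, sd = rating_subject_sd)   # subject's stable taste
    do.call(rbind, lapply(conditions, function(cnd) {
      r <- 4 + 1.2 * (taste + stats::rnorm(n, sd = rating_cond_sd))
      data.frame(subject = sprintf("sub%02d", s), item = seq_len(n),
                 condition = cnd, rating = r)
    }))
  }))

  truth <- expand.grid(roi = roi_ids, condition = conditions,
                       stringsAsFactors = FALSE)
  truth$network <- network[truth$roi]
  truth$beta <- .psc_true_beta(truth$network, truth$condition, mod_strength)

  out <- list(ratings = ratings, network = network, roi_ids = roi_ids,
              truth = truth)
  if (mode == "betas") {
    betas <- merge(
      expand.grid(subject = unique(ratings$subject), roi = roi_ids,
                  condition = conditions, stringsAsFactors = FALSE),
      truth[, c("roi", "condition", "network", "beta")],
      by = c("roi", "condition")
    )
    betas$beta <- betas$beta + stats::rnorm(nrow(betas), sd = beta_noise_sd)
    out$betas <- betas[order(betas$subject, betas$roi, betas$condition), ]
    rownames(out$betas) <- NULL
    return(out)
  }

  # timeseries mode: one run per condition, events evenly spaced
  tr <- cfg$tr_seconds
  run_len <- n_vols * tr
  onsets <- seq(10, run_len - 20, length.out = n)
  series <- lapply(seq_len(cfg$n_subjects), function(s) {
    subj_ratings <- ratings[ratings$subject == sprintf("sub%02d", s), ]
    per_cond <- lapply(conditions, function(cnd) {
      r <- subj_ratings$rating[subj_ratings$condition == cnd]
      X <- build_modulated_design(onsets, r, tr = tr, n_vols = n_vols,
                                  polort = 3L)
      y <- sapply(roi_ids, function(roi) {
        b <- .psc_true_beta(network[roi], cnd, mod_strength)
        2 * X$design[, "onset"] + b * X$design[, "modulated"] +
          stats::rnorm(n_vols, sd = ts_noise_sd)
      })
      list(y = y, onsets = onsets, modulators = r)
    })
    names(per_cond) <- conditions
    per_cond
  })
  names(series) <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  out$series <- series
  out
}
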