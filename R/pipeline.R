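# Umbrella pipeline: run the synthetic cohort through every stage with one
# seeded configuration and collect stage outputs plus a reproducibility
# manifest. The numbered scripts under analysis/ are thin drivers over this.

#' Default pipeline configuration
#'
#' Stage parameters with their documented defaults: 10,000 permutations and
#' searchlight radius 3 as used in the analyses the pipeline reproduces,
#' cubic polynomial trends, and an outlier threshold of z >= 2. Desk-scale
#' runs usually lower `n_perm` and the searchlight subject count.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides for any listed parameter or for [synth_config()]
#'   fields (passed through).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_perm = 10000L,
    radius = 3,
    min_voxels = 10L,
    polort = 3L,
    z_threshold = 2.0,
    k_range = 2:8,
    kmeans_k_range = 2:10,
    cluster_method = "kmeans",
    searchlight_subjects = 12L,
    fdr_q = 0.05
  )
  synth_args <- list(seed = cfg$seed)
  dots <- list(...)
  known_synth <- setdiff(names(formals(synth_config)), "seed")
  for (nm in names(dots)) {
    if (nm %in% names(cfg)) cfg[[nm]] <- dots[[nm]]
    else if (nm %in% known_synth) synth_args[[nm]] <- dots[[nm]]
    else stop("unknown pipeline parameter: ", nm)
  }
  cfg$synth <- do.call(synth_config, synth_args)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; listed keys override the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full synthetic pipeline
#'
#' Executes, as toggled: cohort simulation, behavioural similarity + PCA +
#' category discovery, neural RDMs + network clustering with outlier
#' exclusion, permutation RSA with network-level tests, searchlight mapping
#' with group inference, and the rating-task network x condition analysis.
#' Returns all stage outputs plus a manifest of parameters and seeds that
#' suffices to reproduce the run exactly.
#'
#' @param config A `pipeline_config`.
#' @param stages Character vector of stages to run (default all):
#'   `"behav"`, `"cluster"`, `"rsa"`, `"searchlight"`, `"glm"`.
#' @param out_dir Optional directory; when given, stage tables are written
#'   beneath it (CSV/TSV/JSON).
#' @return A list with one element per executed stage and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("behav", "cluster", "rsa",
                                    "searchlight", "glm"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  scfg <- config$synth
  res <- list()
  space <- gen_food_space(scfg)
  triplets <- gen_triplet_responses(space, reps = scfg$triplet_reps,
                                    temperature = scfg$choice_temperature,
                                    seed = scfg$seed + 10L)
  res$space <- space

  if ("behav" %in% stages) {
    S <- triplet_similarity_matrix(triplets, scfg$n_items)
    pca <- pca_similarity(S)
    km <- select_k_kmeans(pca$scores[, 1:2, drop = FALSE],
                          k_range = config$kmeans_k_range,
                          seed = scfg$seed + 11L)
    res$behav <- list(
      similarity = S, pca = pca, categories = km,
      models = list(
        similarity = similarity_rdm(S),
        pc1 = pc_rdm(pca, 1L),
        pc2 = pc_rdm(pca, 2L)
      ))
  }

  if (any(c("cluster", "rsa") %in% stages)) {
    roi_data <- gen_roi_patterns(scfg, space)
    subject_rdms <- lapply(roi_data$patterns,
                           function(subj) lapply(subj, compute_rdm))
    group_rdms <- lapply(roi_data$roi_ids, function(r) {
      average_rdms(lapply(subject_rdms, `[[`, r))
    })
    names(group_rdms) <- roi_data$roi_ids
    outliers <- detect_outlier_rois(group_rdms,
                                    z_threshold = config$z_threshold)
    keep <- names(which(!outliers$excluded))
    S2 <- roi_similarity_matrix(group_rdms[keep])
    partition <- cluster_rois(S2, method = config$cluster_method,
                              k_range = config$k_range,
                              seed = scfg$seed + 12L)
    res$cluster <- list(roi_data = roi_data, subject_rdms = subject_rdms,
                        group_rdms = group_rdms, outliers = outliers,
                        roi_similarity = S2, partition = partition)
  }

  if ("rsa" %in% stages) {
    models <- res$behav$models
    if (is.null(models))
      models <- list(similarity = similarity_rdm(
        triplet_similarity_matrix(triplets, scfg$n_items)))
    kept_rdms <- lapply(res$cluster$subject_rdms, function(subj)
      subj[names(res$cluster$partition$labels)])
    stats <- rsa_all(kept_rdms, models, n_perm = config$n_perm,
                     seed = scfg$seed + 13L)
    res$rsa <- list(stats = stats,
                    tests = network_level_tests(stats,
                                                res$cluster$partition))
  }

  if ("searchlight" %in% stages) {
    sl <- gen_searchlight_dataset(scfg,
                                  n_subjects = config$searchlight_subjects)
    maps <- lapply(sl$betas, function(B)
      run_searchlight(list(data = B, shape = sl$shape), sl$mask,
                      sl$target_rdm, radius = config$radius,
                      min_voxels = config$min_voxels))
    grp <- group_searchlight(maps, q = config$fdr_q)
    res$searchlight <- list(
      dataset = sl, maps = maps, group = grp,
      dice = dice_coefficient(grp$significant, sl$truth))
  }

  if ("glm" %in% stages) {
    psc <- gen_psc_dataset(scfg, space, mode = "betas")
    two_net <- psc$betas[psc$network[psc$betas$roi] != "outlier", ]
    labels <- psc$network[psc$network != "outlier"]
    res$glm <- list(psc = psc,
                    anova = psc_network_anova(two_net, labels))
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("foodnet")),
    seed = scfg$seed,
    parameters = config[setdiff(names(config), "synth")],
    synth = unclass(scfg),
    stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$behav)) {
    write_rdm_csv(res$behav$similarity$values,
                  file.path(out_dir, "similarity.csv"))
    utils::write.csv(res$behav$pca$scores,
                     file.path(out_dir, "pca_scores.csv"))
    utils::write.csv(
      data.frame(item = seq_along(res$behav$categories$labels),
                 category = res$behav$categories$labels),
      file.path(out_dir, "categories.csv"), row.names = FALSE)
  }
  if (!is.null(res$cluster)) {
    write_rdm_csv(res$cluster$roi_similarity,
                  file.path(out_dir, "roi_similarity.csv"))
    jsonlite::write_json(
      list(labels = as.list(res$cluster$partition$labels),
           chosen_k = res$cluster$partition$chosen_k,
           silhouette_by_k = as.list(res$cluster$partition$silhouette_by_k),
           modularity_q = res$cluster$partition$modularity_q),
      file.path(out_dir, "partition.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(z = as.data.frame(res$cluster$outliers$z),
           excluded = names(which(res$cluster$outliers$excluded))),
      file.path(out_dir, "outliers.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$rsa)) {
    utils::write.table(res$rsa$stats, file.path(out_dir, "rsa_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$rsa$tests, file.path(out_dir, "group_tests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$glm)) {
    utils::write.table(res$glm$psc$betas, file.path(out_dir, "psc_betas.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$glm$anova, file.path(out_dir, "psc_anova.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
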