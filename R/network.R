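# Second-level analysis of ROI representational geometry: the RDM-of-RDMs
# similarity matrix, multivariate outlier screening, and partitioning of ROIs
# into sub-networks validated by silhouette (k-means path) or modularity
# (graph path).

#' Second-level ROI similarity matrix
#'
#' Pearson correlations between the upper-triangle vectors of each pair of
#' ROI group-average RDMs.
#'
#' @param group_rdms Named list (>= 3) of equally-labelled RDM matrices.
#' @return Symmetric correlation matrix with unit diagonal, ROI ids as
#'   dimnames.
#' @export
roi_similarity_matrix <- function(group_rdms) {
  if (length(group_rdms) < 3L) stop("need >= 3 ROIs")
  V <- sapply(group_rdms, upper_tri)
  if (any(apply(V, 2L, stats::sd) == 0))
    stop("constant RDM upper-triangle vector")
  s <- stats::cor(V)
  diag(s) <- 1
  dimnames(s) <- list(names(group_rdms), names(group_rdms))
  s
}

# Mean distance of each column of V (one ROI's RDM vector) to all others
# under a given metric.
.mean_roi_distance <- function(V, metric) {
  m <- ncol(V)
  D <- switch(metric,
    correlation = 1 - stats::cor(V),
    euclidean = as.matrix(stats::dist(t(V))),
    mahalanobis = {
      # the full RDM-vector covariance over ~17 ROIs is singular; work in a
      # PCA-reduced space of at most m - 2 components
      sc <- stats::prcomp(t(V), center = TRUE, scale. = FALSE)
      n_keep <- min(m - 2L, sum(sc$sdev > 1e-10 * sc$sdev[1]))
      if (n_keep < 1L)
        stop("degenerate ROI set: identical RDM vectors")
      keep <- seq_len(n_keep)
      X <- sc$x[, keep, drop = FALSE]
      S_inv <- solve(stats::cov(X))
      D2 <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j) {
        dv <- X[i, ] - X[j, ]
        sqrt(drop(t(dv) %*% S_inv %*% dv))
      }))
      D2
    },
    stop("unknown metric: ", metric))
  diag(D) <- NA
  rowMeans(D, na.rm = TRUE)
}

#' Screen ROIs for outlying representational geometry
#'
#' For each ROI, computes its mean multivariate distance to every other ROI
#' under correlation, Euclidean and (PCA-reduced) Mahalanobis metrics,
#' z-scores each metric's mean distances across ROIs, and flags ROIs whose
#' correlation-metric z meets the threshold. This mirrors the screen that
#' removes an early-visual-cortex region whose geometry reflects low-level
#' image features rather than food information.
#'
#' @param rdm_vectors Named list of ROI RDM upper-triangle vectors, or a
#'   named list of RDMs (vectorized internally).
#' @param z_threshold Exclusion threshold on the correlation-metric z-score.
#' @return A list of class `outlier_report` with `mean_distance` (ROI x
#'   metric), `z` (ROI x metric), `excluded` (logical) and `z_threshold`.
#' @export
detect_outlier_rois <- function(rdm_vectors, z_threshold = 2.0) {
  if (length(rdm_vectors) < 4L) stop("need >= 4 ROIs for outlier screening")
  V <- sapply(rdm_vectors, function(x) if (is.matrix(x)) upper_tri(x) else x)
  metrics <- c("correlation", "euclidean", "mahalanobis")
  md <- sapply(metrics, function(m) .mean_roi_distance(V, m))
  rownames(md) <- colnames(V)
  z <- apply(md, 2L, function(x) {
    s <- stats::sd(x)
    if (s == 0) stop("degenerate ROI set: identical mean distances")
    (x - mean(x)) / s
  })
  structure(list(
    mean_distance = md,
    z = z,
    excluded = z[, "correlation"] >= z_threshold,
    z_threshold = z_threshold
  ), class = "outlier_report")
}

#' Mean silhouette coefficient of a partition
#'
#' Standard silhouette on a precomputed distance matrix:
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean within-cluster
#' distance and `b` the mean distance to the nearest other cluster; singleton
#' clusters score 0.
#'
#' @param distance Square symmetric distance matrix.
#' @param labels Integer cluster labels (>= 2 nonempty clusters).
#' @return Mean silhouette width.
#' @export
silhouette_mean <- function(distance, labels) {
  distance <- as.matrix(distance)
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette requires >= 2 clusters")
  sil <- cluster::silhouette(labels, dmatrix = distance)
  mean(sil[, "sil_width"])
}

# ---- modularity -----------------------------------------------------------

#' Weighted Newman modularity of a partition
#'
#' `Q = (1 / 2w) * sum_ij (A_ij - k_i k_j / 2w) [c_i == c_j]` over off-diagonal
#' weights, where `k` are weighted degrees and `2w` the total weight.
#'
#' @param W Symmetric non-negative weight matrix (diagonal ignored).
#' @param labels Community labels.
#' @return Modularity Q.
#' @export
modularity_q <- function(W, labels) {
  W <- as.matrix(W)
  diag(W) <- 0
  k <- rowSums(W)
  two_w <- sum(k)
  same <- outer(labels, labels, `==`)
  sum((W - outer(k, k) / two_w) * same) / two_w
}

# Enumerate set partitions of 1..m as restricted-growth strings, applying FUN
# to each label vector. Bell(10) ~ 1.16e5 keeps this tractable in pure R.
.for_each_partition <- function(m, FUN) {
  labels <- integer(m)
  recurse <- function(i, maxlab) {
    if (i > m) { FUN(labels); return(invisible(NULL)) }
    for (lab in seq_len(maxlab + 1L)) {
      labels[i] <<- lab
      recurse(i + 1L, max(maxlab, lab))
    }
  }
  recurse(1L, 0L)
}

# Exact maximum-modularity partition by exhaustive set-partition search.
.modularity_exact <- function(W) {
  m <- nrow(W)
  best <- list(q = -Inf, labels = NULL)
  .for_each_partition(m, function(lab) {
    q <- modularity_q(W, lab)
    if (q > best$q) best <<- list(q = q, labels = lab)
  })
  best
}

# Greedy agglomeration (merge the pair of communities with the best Q gain
# while positive) followed by single-node local refinement passes.
.modularity_greedy <- function(W, max_passes = 20L) {
  m <- nrow(W)
  labels <- seq_len(m)
  repeat {
    comms <- unique(labels)
    best_gain <- 0; best_pair <- NULL
    q0 <- modularity_q(W, labels)
    if (length(comms) > 1L) {
      for (a in seq_along(comms)[-length(comms)]) {
        for (b in seq((a + 1L), length(comms))) {
          lab2 <- labels
          lab2[lab2 == comms[b]] <- comms[a]
          gain <- modularity_q(W, lab2) - q0
          if (gain > best_gain + 1e-12) {
            best_gain <- gain; best_pair <- c(comms[a], comms[b])
          }
        }
      }
    }
    if (is.null(best_pair)) break
    labels[labels == best_pair[2]] <- best_pair[1]
  }
  # local refinement: move single nodes to neighbouring communities
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(m)) {
      q0 <- modularity_q(W, labels)
      for (target in unique(labels)) {
        if (target == labels[i]) next
        lab2 <- labels
        lab2[i] <- target
        if (modularity_q(W, lab2) > q0 + 1e-12) {
          labels <- lab2
          q0 <- modularity_q(W, labels)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(q = modularity_q(W, labels), labels = labels)
}

#' Partition ROIs into representational sub-networks
#'
#' Two clustering paths over the second-level ROI similarity matrix:
#' `"kmeans"` treats the rows of `S` as feature vectors, runs best-of-`n_init`
#' k-means for each `k`, and selects `k` by mean silhouette on the `1 - s`
#' distance; `"modularity"` builds a weighted graph with edge weights
#' `(s + 1) / 2` and maximizes Newman modularity (exhaustively for small ROI
#' sets, greedy agglomeration with local refinement otherwise). Outlier ROIs
#' are expected to be excluded before calling.
#'
#' @param S ROI similarity matrix from [roi_similarity_matrix()].
#' @param method `"kmeans"` (default) or `"modularity"`.
#' @param k_range Candidate cluster counts for the k-means path.
#' @param n_init Random k-means starts per `k`.
#' @param exact_max Largest ROI count for exhaustive modularity search.
#' @param seed Optional integer seed.
#' @return A list of class `network_partition` with `labels` (named integer),
#'   `silhouette_by_k`, `chosen_k`, `method` and `modularity_q`.
#' @export
cluster_rois <- function(S, method = c("kmeans", "modularity"),
                         k_range = 2:8, n_init = 50L, exact_max = 10L,
                         seed = NULL) {
  method <- match.arg(method)
  S <- as.matrix(S)
  m <- nrow(S)
  if (m < 4L) stop("need >= 4 ROIs to cluster")
  if (!is.null(seed)) set.seed(seed)
  roi_ids <- rownames(S)
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%02d", seq_len(m))

  if (method == "kmeans") {
    if (length(k_range) == 0L) stop("empty k_range")
    k_range <- k_range[k_range < m]
    d <- 1 - S
    diag(d) <- 0
    sil <- stats::setNames(numeric(length(k_range)), k_range)
    labs <- list()
    for (i in seq_along(k_range)) {
      km <- stats::kmeans(S, centers = k_range[i], nstart = n_init,
                          iter.max = 100L)
      sil[i] <- silhouette_mean(d, km$cluster)
      labs[[i]] <- km$cluster
    }
    best <- which.max(sil)
    labels <- stats::setNames(labs[[best]], roi_ids)
    W <- (S + 1) / 2
    diag(W) <- 0
    out <- list(labels = labels, silhouette_by_k = sil,
                chosen_k = k_range[best], method = "kmeans",
                modularity_q = modularity_q(W, labels))
  } else {
    W <- (S + 1) / 2
    diag(W) <- 0
    fit <- if (m <= exact_max) .modularity_exact(W) else .modularity_greedy(W)
    labels <- stats::setNames(as.integer(as.factor(fit$labels)), roi_ids)
    d <- 1 - S
    diag(d) <- 0
    k <- length(unique(labels))
    sil <- stats::setNames(
      if (k >= 2L) silhouette_mean(d, labels) else NA_real_, k)
    out <- list(labels = labels, silhouette_by_k = sil, chosen_k = k,
                method = "modularity", modularity_q = fit$q)
  }
  class(out) <- "network_partition"
  out
}
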