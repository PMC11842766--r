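test_that("ROI similarity matrix matches a pairwise Pearson oracle", {
  set.seed(51)
  rdms <- lapply(1:4, function(i) make_rdm(rnorm(8)))
  names(rdms) <- paste0("roi", 1:4)
  S <- roi_similarity_matrix(rdms)
  expect_equal(diag(S), rep(1, 4), ignore_attr = TRUE)
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    expect_equal(S[a, b],
                 pearson(upper_tri(rdms[[a]]), upper_tri(rdms[[b]])),
                 tolerance = 1e-12)
  }
  # identical RDMs across ROIs give an all-ones matrix
  same <- rep(rdms[1], 3); names(same) <- paste0("r", 1:3)
  expect_true(all(abs(roi_similarity_matrix(same) - 1) < 1e-12))
})

test_that("anti-correlated RDM vectors give similarity -1", {
  v1 <- c(0.1, 0.5, 0.9, 0.2, 0.7, 0.4)
  v2 <- 1 - v1
  rdms <- list(a = rdm_from_upper(v1), b = rdm_from_upper(v2),
               c = rdm_from_upper(v1 * 2))
  S <- roi_similarity_matrix(rdms)
  expect_equal(S["a", "b"], -1, tolerance = 1e-12)
  expect_equal(S["a", "c"], 1, tolerance = 1e-12)
})

test_that("outlier screen flags a planted orthogonal-geometry ROI", {
  set.seed(52)
  shared <- rnorm(10)
  vecs <- c(lapply(1:6, function(i) make_rdm(shared + rnorm(10, sd = 0.05))),
            list(make_rdm(rnorm(10) * 3)))
  names(vecs) <- paste0("roi", 1:7)
  rep <- detect_outlier_rois(vecs, z_threshold = 2)
  expect_identical(names(which(rep$excluded)), "roi7")
  expect_equal(which.max(rep$z[, "correlation"]), c(roi7 = 7L))
  # per-metric z-scores are standardized across ROIs
  expect_equal(colMeans(rep$z), c(correlation = 0, euclidean = 0,
                                  mahalanobis = 0), tolerance = 1e-12)
  expect_equal(apply(rep$z, 2, sd), c(correlation = 1, euclidean = 1,
                                      mahalanobis = 1), tolerance = 1e-12)
})

test_that("identical ROIs make the outlier screen degenerate", {
  vecs <- rep(list(make_rdm(c(0, 1, 3, 6))), 5)
  names(vecs) <- paste0("r", 1:5)
  expect_error(detect_outlier_rois(vecs), "identical|degenerate")
  expect_error(detect_outlier_rois(vecs[1:3]), ">= 4")
})

test_that("default synthetic cohort excludes exactly the planted outlier", {
  cfg <- synth_config(seed = 53)
  space <- gen_food_space(cfg)
  roi <- gen_roi_patterns(cfg, space)
  group <- lapply(roi$roi_ids, function(r)
    average_rdms(lapply(roi$patterns, function(s) compute_rdm(s[[r]]))))
  names(group) <- roi$roi_ids
  rep <- detect_outlier_rois(group)
  expect_identical(names(which(rep$excluded)),
                   names(which(roi$network == "outlier")))
})

test_that("both clustering paths recover planted blocks and k = 2", {
  m <- 8
  S <- matrix(0.1, m, m)
  S[1:4, 1:4] <- 0.9; S[5:8, 5:8] <- 0.9; diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("r", 1:m)
  truth <- rep(1:2, each = 4)
  for (method in c("kmeans", "modularity")) {
    part <- cluster_rois(S, method = method, seed = 54)
    expect_equal(part$chosen_k, 2L)
    expect_equal(length(unique(paste(part$labels, truth))), 2L)
  }
  km <- cluster_rois(S, method = "kmeans", seed = 54)
  expect_equal(unname(which.max(km$silhouette_by_k)), 1L)  # k = 2 wins
})

test_that("modularity of two disconnected equal cliques is 1/2", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  expect_equal(modularity_q(W, c(1, 1, 1, 2, 2, 2)), 0.5)
})

test_that("exhaustive modularity search equals a brute-force maximum", {
  set.seed(55)
  m <- 8
  S <- cov2cor(crossprod(matrix(rnorm(10 * m), 10, m)))
  W <- (S + 1) / 2; diag(W) <- 0
  all_parts <- partitions_oracle(m)
  q_best <- max(apply(all_parts, 1, function(lab) modularity_q(W, lab)))
  fit <- foodnet:::.modularity_exact(W)
  expect_equal(fit$q, q_best, tolerance = 1e-12)
  # greedy path reaches the same optimum on this instance
  expect_equal(foodnet:::.modularity_greedy(W)$q, q_best, tolerance = 1e-12)
})

test_that("modularity agrees with the igraph implementation", {
  skip_if_not_installed("igraph")
  set.seed(56)
  m <- 9
  S <- cov2cor(crossprod(matrix(rnorm(12 * m), 12, m)))
  W <- (S + 1) / 2; diag(W) <- 0
  W <- (W + t(W)) / 2   # exact symmetry for igraph
  labels <- sample(1:3, m, replace = TRUE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  expect_equal(modularity_q(W, labels),
               igraph::modularity(g, labels, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("mean silhouette matches a manual 5-point oracle", {
  # two duplicated clusters with positive separation
  d2 <- as.matrix(dist(c(0, 0, 5, 5)))
  expect_equal(silhouette_mean(d2, c(1, 1, 2, 2)), 1)
  # all points mutually equidistant
  deq <- matrix(1, 4, 4); diag(deq) <- 0
  expect_equal(silhouette_mean(deq, c(1, 1, 2, 2)), 0)
  # 5-point toy: hand-computed silhouette
  x <- c(0, 1, 5, 6, 10)
  lab <- c(1, 1, 2, 2, 3)
  d <- as.matrix(dist(x))
  manual <- sapply(1:5, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(5) != i])
    if (sum(lab == lab[i]) == 1) return(0)
    b <- min(sapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(d[i, lab == l])))
    (b - a) / max(a, b)
  })
  expect_equal(silhouette_mean(d, lab), mean(manual), tolerance = 1e-12)
  expect_error(silhouette_mean(d, rep(1, 5)), ">= 2")
})

test_that("partitions are invariant to ROI input order", {
  cfg <- synth_config(seed = 57, n_subjects = 6)
  space <- gen_food_space(cfg)
  roi <- gen_roi_patterns(cfg, space)
  group <- lapply(roi$roi_ids, function(r)
    average_rdms(lapply(roi$patterns, function(s) compute_rdm(s[[r]]))))
  names(group) <- roi$roi_ids
  keep <- setdiff(roi$roi_ids, names(which(roi$network == "outlier")))
  S <- roi_similarity_matrix(group[keep])
  p1 <- cluster_rois(S, seed = 58)
  perm <- sample(seq_along(keep))
  p2 <- cluster_rois(S[perm, perm], seed = 58)
  expect_equal(p1$chosen_k, p2$chosen_k)
  common <- names(p1$labels)
  agree <- table(p1$labels[common], p2$labels[common])
  expect_equal(sum(agree > 0), p1$chosen_k)  # label bijection
})
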