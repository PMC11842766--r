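test_that("single-triplet similarity proportions are exact", {
  tr <- data.frame(item_a = 1L, item_b = 2L, item_c = 3L, odd = 3L)
  S <- triplet_similarity_matrix(tr, 3L)
  expect_equal(S$values[1, 2], 1)
  expect_equal(S$values[1, 3], 0)
  expect_equal(S$values[2, 3], 0)
  expect_equal(diag(S$values), rep(1, 3))
  expect_equal(S$values, t(S$values))
})

test_that("full enumeration observes every pair exactly n - 2 times per rep", {
  cfg <- synth_config(seed = 21)
  space <- gen_food_space(cfg)
  tr <- gen_triplet_responses(space, reps = 1, seed = 22)
  S <- triplet_similarity_matrix(tr, 36L)
  off <- S$n_pairs[upper.tri(S$n_pairs)]
  expect_true(all(off == 34L))
  expect_false(anyNA(S$values))
})

test_that("similarity estimation errors on bad input", {
  expect_error(triplet_similarity_matrix(data.frame(), 3), "empty")
  tr <- data.frame(item_a = 1L, item_b = 2L, item_c = 9L, odd = 9L)
  expect_error(triplet_similarity_matrix(tr, 3L), "out of range")
  tr2 <- data.frame(item_a = 1L, item_b = 2L, item_c = 3L, odd = 4L)
  expect_error(triplet_similarity_matrix(tr2, 4L), "one of the triplet")
})

test_that("never-observed pairs are flagged as NA", {
  tr <- data.frame(item_a = 1L, item_b = 2L, item_c = 3L, odd = 2L)
  S <- triplet_similarity_matrix(tr, 4L)
  expect_true(is.na(S$values[1, 4]))
  expect_equal(S$n_pairs[1, 4], 0L)
  expect_error(pca_similarity(S), "flagged")
  expect_error(similarity_rdm(S), "flagged")
})

test_that("deterministic choices recover the 1-D distance ordering", {
  # enough items that the per-pair proportion granularity (1/(n-2)) does not
  # blur the distance ordering
  n <- 18
  space <- make_space(seq(0, 3, length.out = n))
  tr <- gen_triplet_responses(space, reps = 1, temperature = 1e-9, seed = 23)
  S <- triplet_similarity_matrix(tr, n)
  d <- as.matrix(dist(space$coords))
  rho <- cor(S$values[upper.tri(d)], -d[upper.tri(d)], method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("PCA of an exactly rank-2 matrix puts all variance in two components", {
  set.seed(24)
  a <- rnorm(8); b <- rnorm(8); p <- rnorm(8); q <- rnorm(8)
  M <- a %o% p + b %o% q          # rows live in a 2-D subspace
  res <- pca_similarity(M)
  expect_equal(sum(res$variance_fraction[1:2]), 1, tolerance = 1e-10)
  expect_true(all(diff(res$variance_fraction) <= 1e-12))
  # components are orthogonal
  G <- crossprod(res$loadings)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("exchangeable similarity matrix has a flat eigenvalue spectrum", {
  n <- 7
  M <- matrix(0.3, n, n); diag(M) <- 1
  res <- pca_similarity(M)
  nz <- res$variance_fraction[res$variance_fraction > 1e-12]
  expect_lt(max(nz) - min(nz), 1e-10)
})

test_that("adding a constant off the diagonal preserves score orderings", {
  cfg <- synth_config(seed = 25)
  space <- gen_food_space(cfg)
  tr <- gen_triplet_responses(space, reps = 2, seed = 26)
  S <- triplet_similarity_matrix(tr, 36L)$values
  S2 <- S + 0.2 * (1 - diag(36))
  sc1 <- pca_similarity(S)$scores[, 1]
  sc2 <- pca_similarity(S2)$scores[, 1]
  expect_equal(abs(cor(sc1, sc2, method = "spearman")), 1, tolerance = 1e-6)
})

test_that("silhouette-selected k-means recovers planted score clusters", {
  set.seed(27)
  centers <- rbind(c(0, 0), c(6, 0), c(3, 6))
  truth <- rep(1:3, each = 8)
  scores <- centers[truth, ] + matrix(rnorm(48, sd = 0.3), 24, 2)
  res <- select_k_kmeans(scores, k_range = 2:6, seed = 28)
  expect_equal(res$chosen_k, 3L)
  expect_equal(length(unique(paste(res$labels, truth))), 3L)  # bijection
})

test_that("duplicated points in separated clusters give silhouette 1", {
  scores <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  res <- select_k_kmeans(scores, k_range = 2, n_init = 5, seed = 29)
  expect_equal(unname(res$silhouette_by_k["2"]), 1)
})

test_that("k range outside [2, n-1] errors", {
  expect_error(select_k_kmeans(matrix(rnorm(10), 5, 2), k_range = 2:5), "k_range")
  expect_error(select_k_kmeans(matrix(rnorm(10), 5, 2), k_range = integer(0)),
               "empty")
})

test_that("principal-component RDMs are absolute score differences", {
  scores <- matrix(c(0, 1, 3), 3, 1)
  R <- pc_rdm(scores, 1L)
  expect_equal(upper_tri(R), c(1, 3, 2))
  expect_equal(diag(R), rep(0, 3), ignore_attr = TRUE)
  expect_equal(pc_rdm(-scores, 1L), R)     # sign invariance
  expect_error(pc_rdm(scores, 2L), "out of range")
})

test_that("similarity RDM is the 1 - S involution", {
  S <- matrix(0.25, 4, 4); diag(S) <- 1
  R <- similarity_rdm(S)
  expect_equal(R[1, 2], 0.75)
  expect_equal(diag(R), rep(0, 4))
  back <- 1 - R; diag(back) <- 1
  expect_equal(back, S)
  expect_equal(similarity_rdm(matrix(1, 3, 3)), matrix(0, 3, 3))
})

test_that("similarity estimator converges to closed-form choice proportions", {
  space <- make_space(c(0, 0.5, 1.2, 2.1, 3.0))
  n <- 5; temp <- 0.3
  S <- space$sim
  expected <- matrix(NA_real_, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ks <- setdiff(1:n, c(i, j))
    pk <- sapply(ks, function(k) {
      u <- c(S[j, k], S[i, k], S[i, j]) / temp
      p <- exp(u - max(u)); p[3] / sum(p)
    })
    expected[i, j] <- expected[j, i] <- mean(pk)
  }
  err <- sapply(c(20, 320), function(reps) {
    tr <- gen_triplet_responses(space, reps = reps, temperature = temp,
                                seed = 31)
    Sh <- triplet_similarity_matrix(tr, n)$values
    sqrt(mean((Sh - expected)[upper.tri(Sh)]^2))
  })
  expect_lt(err[2], err[1] / 2)   # ~1/sqrt(reps) shrinkage
  expect_lt(err[2], 0.04)
})
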