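# Behavioural food-similarity estimation from odd-one-out triplet responses,
# PCA of the similarity matrix, category discovery, and model RDMs for RSA.

#' Estimate a food-similarity matrix from triplet responses
#'
#' For each pair of items, similarity is the proportion of triplets containing
#' both in which neither was selected as the odd one out. The diagonal is
#' fixed at 1 (a self-pair can never be odd). Pairs never observed together
#' are `NA` and flagged in the `n_pairs` count matrix.
#'
#' @param triplets Data frame with columns `item_a`, `item_b`, `item_c`,
#'   `odd` (item ids in `1..n_items`, `odd` one of the three).
#' @param n_items Number of items.
#' @return A list of class `food_similarity` with `values` (n x n, diagonal
#'   1, off-diagonal in `[0, 1]` or `NA`) and `n_pairs` (co-occurrence
#'   counts).
#' @export
triplet_similarity_matrix <- function(triplets, n_items) {
  if (is.null(triplets) || nrow(triplets) == 0L)
    stop("empty triplet list")
  ids <- c(triplets$item_a, triplets$item_b, triplets$item_c, triplets$odd)
  if (any(ids < 1L | ids > n_items))
    stop("item id out of range 1..n_items")
  if (any(triplets$odd != triplets$item_a &
          triplets$odd != triplets$item_b &
          triplets$odd != triplets$item_c))
    stop("`odd` must be one of the triplet's items")

  n <- n_items
  count_lin <- function(i, j) {
    a <- pmin(i, j); b <- pmax(i, j)
    tabulate((a - 1L) * n + b, nbins = n * n)
  }
  tot <- count_lin(triplets$item_a, triplets$item_b) +
         count_lin(triplets$item_a, triplets$item_c) +
         count_lin(triplets$item_b, triplets$item_c)
  # the pair not containing the odd item
  keep_i <- ifelse(triplets$odd == triplets$item_a, triplets$item_b,
                   triplets$item_a)
  keep_j <- ifelse(triplets$odd == triplets$item_c, triplets$item_b,
                   triplets$item_c)
  kept <- count_lin(keep_i, keep_j)

  tot_m <- matrix(tot, n, n, byrow = TRUE)
  kept_m <- matrix(kept, n, n, byrow = TRUE)
  tot_m <- tot_m + t(tot_m)
  kept_m <- kept_m + t(kept_m)
  S <- kept_m / tot_m          # NaN where a pair was never observed
  S[tot_m == 0] <- NA_real_
  diag(S) <- 1
  diag(tot_m) <- 0L
  structure(list(values = S, n_pairs = tot_m), class = "food_similarity")
}

#' PCA of a food-similarity matrix
#'
#' Rows of the similarity matrix are treated as observations and columns are
#' centered (no scaling); components come from the eigendecomposition of the
#' resulting covariance. Scores are the centered rows projected on the
#' components; `variance_fraction` gives eigenvalue shares.
#'
#' @param S A `food_similarity` or a plain numeric square matrix.
#' @return A list of class `similarity_pca` with `scores`, `loadings` and
#'   `variance_fraction`.
#' @export
pca_similarity <- function(S) {
  M <- if (inherits(S, "food_similarity")) S$values else S
  if (anyNA(M)) stop("similarity matrix contains unobserved (flagged) pairs")
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  structure(list(
    scores = p$x,
    loadings = p$rotation,
    variance_fraction = p$sdev^2 / sum(p$sdev^2)
  ), class = "similarity_pca")
}

#' Silhouette-validated k-means on principal-component scores
#'
#' Runs k-means (best of `n_init` random starts, by within-cluster sum of
#' squares) for every `k` in `k_range` on the given score matrix, scores each
#' solution by mean silhouette on Euclidean distances, and returns the
#' partition at the silhouette-maximizing `k`.
#'
#' @param scores Numeric matrix, items x dimensions (typically the first two
#'   PC scores).
#' @param k_range Integer vector of candidate cluster counts.
#' @param n_init Random starts per `k`.
#' @param seed Optional integer seed.
#' @return A list with `labels`, `silhouette_by_k` (named numeric) and
#'   `chosen_k`.
#' @export
select_k_kmeans <- function(scores, k_range = 2:10, n_init = 50L,
                            seed = NULL) {
  scores <- as.matrix(scores)
  if (length(k_range) == 0L) stop("empty k_range")
  if (any(k_range < 2L) || any(k_range > nrow(scores) - 1L))
    stop("k_range must lie within [2, n_items - 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(stats::dist(scores))
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  labs <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- stats::kmeans(scores, centers = k, nstart = n_init, iter.max = 100L)
    sil[i] <- silhouette_mean(d, km$cluster)
    labs[[i]] <- km$cluster
  }
  best <- which.max(sil)
  list(labels = labs[[best]], silhouette_by_k = sil,
       chosen_k = k_range[best])
}

#' Euclidean RDM from one principal component
#'
#' `RDM(i, j) = |score_i - score_j|` on the named component: a simple
#' one-dimensional Euclidean distance matrix, invariant to the component's
#' sign.
#'
#' @param pca A `similarity_pca` (or a plain score matrix).
#' @param component Component index.
#' @return A symmetric zero-diagonal distance matrix.
#' @export
pc_rdm <- function(pca, component = 1L) {
  scores <- if (inherits(pca, "similarity_pca")) pca$scores else as.matrix(pca)
  if (component < 1L || component > ncol(scores))
    stop("`component` out of range")
  as.matrix(stats::dist(scores[, component]))
}

#' Dissimilarity RDM from a similarity matrix
#'
#' `RDM = 1 - S` off the diagonal, diagonal 0.
#'
#' @param S A `food_similarity` or plain square matrix with no flagged
#'   entries.
#' @return A symmetric zero-diagonal RDM.
#' @export
similarity_rdm <- function(S) {
  M <- if (inherits(S, "food_similarity")) S$values else S
  if (anyNA(M)) stop("similarity matrix contains unobserved (flagged) pairs")
  R <- 1 - M
  diag(R) <- 0
  R
}
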