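# Representational similarity analysis statistics: Spearman correlation of
# RDM upper triangles, permutation-null z-scoring, network-level group tests,
# and FDR control.

#' Spearman correlation between two RDMs' upper triangles
#'
#' Rank correlation (average ranks for ties) between the upper-triangle
#' vectors of two equally-labelled RDMs.
#'
#' @param r1,r2 RDM matrices with matching dimensions.
#' @return Spearman rho.
#' @export
spearman_upper <- function(r1, r2) {
  v1 <- upper_tri(r1)
  v2 <- upper_tri(r2)
  if (length(v1) != length(v2)) stop("RDM sizes differ")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant upper-triangle vector")
  stats::cor(rank(v1), rank(v2))
}

#' Permutation z-score for an RDM-model correlation
#'
#' The observed Spearman rho between the neural and model RDMs is z-scored
#' against a null distribution obtained by randomly relabelling the neural
#' RDM's conditions (the same permutation applied jointly to rows and
#' columns, which preserves the RDM's internal structure) and recomputing
#' rho. `z = (rho_obs - mean_null) / sd_null`. With `exhaustive = TRUE` and
#' few conditions, all `n!` relabelings are enumerated instead of sampled.
#'
#' @param neural,model Equally-sized RDM matrices (>= 4 conditions).
#' @param n_perm Number of sampled permutations.
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all `n!` relabelings (requires `n <= 7`).
#' @return A list with `rho`, `z`, `null_mean`, `null_sd`, `n_perm`.
#' @export
permutation_z <- function(neural, model, n_perm = 10000L, seed = NULL,
                          exhaustive = FALSE) {
  n <- nrow(neural)
  if (n < 4L) stop("need >= 4 conditions")
  v_model <- upper_tri(model)
  if (stats::sd(v_model) == 0 || stats::sd(upper_tri(neural)) == 0)
    stop("constant upper-triangle vector")
  rk_model <- rank(v_model)
  # precomputed (i, j) index pairs of the row-major upper triangle
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  rho_for <- function(perm) {
    v <- neural[cbind(perm[pairs[, 1]], perm[pairs[, 2]])]
    stats::cor(rank(v), rk_model)
  }
  rho_obs <- rho_for(seq_len(n))
  if (exhaustive) {
    if (n > 7L) stop("exhaustive mode supports at most 7 conditions")
    perms <- .all_permutations(n)
    null <- apply(perms, 1L, rho_for)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) rho_for(sample.int(n)),
                   numeric(1))
  }
  mu <- mean(null)
  sdev <- stats::sd(null)
  if (sdev == 0) stop("degenerate permutation null (sd = 0)")
  list(rho = rho_obs, z = (rho_obs - mu) / sdev,
       null_mean = mu, null_sd = sdev, n_perm = length(null))
}

# All n! permutations of 1..n as rows of a matrix.
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Run permutation RSA for every subject x ROI x model combination
#'
#' Convenience driver producing one row of statistics per subject-level
#' neural RDM and model RDM, with reproducible per-cell permutation seeds
#' derived from `seed`.
#'
#' @param subject_rdms Nested list: `subject_rdms[[subject]][[roi]]` is an
#'   RDM.
#' @param models Named list of model RDMs.
#' @param n_perm Permutations per cell.
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `roi`, `model`, `rho`, `z`,
#'   `n_perm`.
#' @export
rsa_all <- function(subject_rdms, models, n_perm = 1000L, seed = 1L) {
  rows <- list()
  cell <- 0L
  for (s in names(subject_rdms)) {
    for (r in names(subject_rdms[[s]])) {
      for (m in names(models)) {
        cell <- cell + 1L
        pz <- permutation_z(subject_rdms[[s]][[r]], models[[m]],
                            n_perm = n_perm,
                            seed = (seed * 7919L + cell) %% .Machine$integer.max)
        rows[[cell]] <- data.frame(subject = s, roi = r, model = m,
                                   rho = pz$rho, z = pz$z, n_perm = pz$n_perm)
      }
    }
  }
  do.call(rbind, rows)
}

#' Network-level group tests of RSA z-scores
#'
#' Two-stage summary-statistic procedure: stage 1 averages z-scores across
#' each network's ROIs within subject; stage 2 runs, per model, a two-sided
#' one-sample t-test of each network's subject means against zero and a
#' paired two-sided t-test between networks, with Benjamini-Hochberg FDR
#' across all tests of a model family.
#'
#' @param stats Data frame from [rsa_all()] (columns `subject`, `roi`,
#'   `model`, `z`).
#' @param partition Named vector or `network_partition` mapping ROI id to
#'   network label; ROIs absent from the partition (e.g. excluded outliers)
#'   are dropped.
#' @return Data frame with columns `model`, `contrast`, `estimate`, `t`,
#'   `df`, `p`, `q`.
#' @export
network_level_tests <- function(stats, partition) {
  labels <- if (inherits(partition, "network_partition")) partition$labels
            else partition
  stats <- stats[stats$roi %in% names(labels), ]
  if (nrow(stats) == 0L) stop("no ROI in `stats` is labelled by `partition`")
  stats$network <- labels[stats$roi]
  agg <- stats::aggregate(z ~ subject + network + model, stats, mean)
  nets <- sort(unique(agg$network))
  out <- list()
  for (m in unique(agg$model)) {
    sub <- agg[agg$model == m, ]
    for (net in nets) {
      x <- sub$z[sub$network == net]
      if (stats::sd(x) == 0) stop("zero variance across subjects")
      tt <- stats::t.test(x)
      out[[length(out) + 1L]] <- data.frame(
        model = m, contrast = paste0(net, "_vs_0"),
        estimate = mean(x), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value)
    }
    if (length(nets) == 2L) {
      wide <- merge(sub[sub$network == nets[1], c("subject", "z")],
                    sub[sub$network == nets[2], c("subject", "z")],
                    by = "subject")
      dz <- wide$z.x - wide$z.y
      tt <- if (stats::sd(dz) == 0 && mean(dz) == 0)
        list(statistic = 0, parameter = length(dz) - 1, p.value = 1)
      else stats::t.test(dz)
      out[[length(out) + 1L]] <- data.frame(
        model = m, contrast = paste0(nets[1], "_vs_", nets[2]),
        estimate = mean(dz), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value)
    }
  }
  res <- do.call(rbind, out)
  res$q <- fdr_bh(res$p)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone in p-value rank and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
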