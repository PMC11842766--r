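# Shared fixture builders. Everything is generated in code; no stored data.

# A food_space with hand-chosen coordinates (bypasses the generator's layout).
make_space <- function(coords, hedonic = NULL) {
  coords <- as.matrix(coords)
  structure(list(
    coords = coords,
    category_label = rep(1L, nrow(coords)),
    processing_score = coords[, 1],
    hedonic_score = if (is.null(hedonic)) rep(0, nrow(coords)) else hedonic,
    sim = exp(-as.matrix(stats::dist(coords)))
  ), class = "food_space")
}

# A valid RDM from arbitrary scores (Euclidean distances, labelled).
make_rdm <- function(scores, labels = NULL) {
  R <- as.matrix(stats::dist(scores))
  if (is.null(labels)) labels <- sprintf("c%02d", seq_len(nrow(R)))
  dimnames(R) <- list(labels, labels)
  R
}

# All permutations of 1..n, written independently of the package's
# generator (used as the exhaustive-null oracle).
perms_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- perms_oracle(n - 1L)
    cbind(first, matrix(setdiff(seq_len(n), first)[rest], nrow(rest)))
  }))
}

# All set partitions of 1..m as label vectors, via base-(m) strings filtered
# to canonical (restricted-growth) form; independent of the package's
# recursion.
partitions_oracle <- function(m) {
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(m)), m)))
  keep <- apply(grid, 1, function(lab) {
    seen <- 0L
    for (x in lab) {
      if (x > seen + 1L) return(FALSE)
      seen <- max(seen, x)
    }
    TRUE
  })
  grid[keep, , drop = FALSE]
}
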