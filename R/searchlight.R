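# Spherical searchlight RSA: map the Spearman correspondence between local
# correlation-distance RDMs and a model RDM across a volume, then combine
# subject maps with a voxelwise t-test and FDR thresholding.

#' Integer lattice offsets of a searchlight sphere
#'
#' All integer offsets `(dx, dy, dz)` with `dx^2 + dy^2 + dz^2 <= radius^2`,
#' in a deterministic (dz, dy, dx ascending) order; always includes the
#' center. A radius of 3 yields 123 offsets.
#'
#' @param radius Sphere radius in voxels (>= 0).
#' @return Integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ]
  g <- g[order(g$dz, g$dy, g$dx), ]
  as.matrix(g)
}

# Normalize condition volumes to a condition x voxel matrix plus shape.
.flatten_betas <- function(betas) {
  if (is.list(betas) && is.matrix(betas$data) && !is.null(betas$shape))
    return(betas)
  if (is.list(betas) && length(betas) > 0L && length(dim(betas[[1]])) == 3L) {
    shape <- dim(betas[[1]])
    for (b in betas) if (!identical(dim(b), shape))
      stop("condition volumes do not share a shape")
    B <- t(vapply(betas, as.vector, numeric(prod(shape))))
    rownames(B) <- names(betas)
    return(list(data = B, shape = shape))
  }
  stop("betas must be a named list of 3-D condition volumes or list(data=, shape=)")
}

#' Run a searchlight RSA over a volume
#'
#' At every in-mask center, collects the sphere's in-mask voxels (intersected
#' with the volume bounds); when at least `min_voxels` remain, builds the
#' local condition x voxel pattern, computes the correlation-distance RDM,
#' correlates it (Spearman) with `model`, and stores the Fisher z
#' (`atanh` of rho clipped to `|rho| <= 1 - 1e-7`). Centers with fewer
#' members, or with a zero-variance local pattern, are left undefined (`NA`)
#' and counted in the QC report.
#'
#' @param betas Named list of 3-D condition volumes (names matching the model
#'   RDM labels), or a condition x voxel matrix via `list(data=, shape=)`.
#' @param mask Logical 3-D array (or numeric, nonzero = in-mask).
#' @param model Model RDM whose labels match the condition set.
#' @param radius Sphere radius in voxels.
#' @param min_voxels Minimum sphere membership for a defined center.
#' @return A list of class `searchlight_map` with `z` (3-D array, `NA`
#'   outside defined centers), `rho`, `n_voxels`, `radius`, `min_voxels`
#'   and `qc` (counts of undefined centers by reason).
#' @export
run_searchlight <- function(betas, mask, model, radius = 3, min_voxels = 10L) {
  fb <- .flatten_betas(betas)
  B <- fb$data
  shape <- fb$shape
  if (!is.null(rownames(B)) && !is.null(rownames(model))) {
    if (!setequal(rownames(B), rownames(model)))
      stop("model labels do not match condition set")
    B <- B[rownames(model), , drop = FALSE]
  }
  mask <- array(as.logical(mask != 0), dim = shape)
  if (!any(mask)) stop("empty mask")
  rk_model <- rank(upper_tri(model))

  offs <- sphere_offsets(radius)
  centers <- which(mask)
  cidx <- arrayInd(centers, shape)
  zmap <- array(NA_real_, shape)
  rmap <- array(NA_real_, shape)
  nmap <- array(NA_integer_, shape)
  n_small <- 0L; n_degenerate <- 0L
  lin <- function(i, j, k) i + (j - 1L) * shape[1] + (k - 1L) * shape[1] * shape[2]
  for (c in seq_along(centers)) {
    vi <- cidx[c, 1] + offs[, 1]
    vj <- cidx[c, 2] + offs[, 2]
    vk <- cidx[c, 3] + offs[, 3]
    ok <- vi >= 1L & vi <= shape[1] & vj >= 1L & vj <= shape[2] &
          vk >= 1L & vk <= shape[3]
    vox <- lin(vi[ok], vj[ok], vk[ok])
    vox <- vox[mask[vox]]
    if (length(vox) < min_voxels) { n_small <- n_small + 1L; next }
    P <- B[, vox, drop = FALSE]
    sds <- apply(P, 1L, stats::sd)
    if (any(sds == 0)) { n_degenerate <- n_degenerate + 1L; next }
    v <- upper_tri(1 - stats::cor(t(P)))
    rho <- stats::cor(rank(v), rk_model)
    rho <- max(min(rho, 1 - 1e-7), -1 + 1e-7)
    zmap[centers[c]] <- atanh(rho)
    rmap[centers[c]] <- rho
    nmap[centers[c]] <- length(vox)
  }
  structure(list(z = zmap, rho = rmap, n_voxels = nmap, radius = radius,
                 min_voxels = min_voxels,
                 qc = c(too_small = n_small, degenerate = n_degenerate)),
            class = "searchlight_map")
}

#' Reference searchlight implementation (naive loops)
#'
#' A deliberately simple engine used as an independent check of
#' [run_searchlight()]: explicit triple loops over voxel coordinates,
#' per-pair Pearson correlations, and `stats::cor(..., method = "spearman")`
#' for the model comparison.
#'
#' @inheritParams run_searchlight
#' @return A 3-D array of Fisher-z values (`NA` at undefined centers).
#' @export
run_searchlight_reference <- function(betas, mask, model, radius = 3,
                                      min_voxels = 10L) {
  fb <- .flatten_betas(betas)
  B <- fb$data
  shape <- fb$shape
  if (!is.null(rownames(B)) && !is.null(rownames(model)))
    B <- B[rownames(model), , drop = FALSE]
  mask <- array(as.logical(mask != 0), dim = shape)
  n <- nrow(B)
  zmap <- array(NA_real_, shape)
  mv <- upper_tri(model)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      if (!mask[i, j, k]) next
      vox <- integer(0)
      for (di in -floor(radius):floor(radius))
        for (dj in -floor(radius):floor(radius))
          for (dk in -floor(radius):floor(radius)) {
            if (di^2 + dj^2 + dk^2 > radius^2) next
            ii <- i + di; jj <- j + dj; kk <- k + dk
            if (ii < 1 || ii > shape[1] || jj < 1 || jj > shape[2] ||
                kk < 1 || kk > shape[3]) next
            if (!mask[ii, jj, kk]) next
            vox <- c(vox, ii + (jj - 1) * shape[1] +
                            (kk - 1) * shape[1] * shape[2])
          }
      if (length(vox) < min_voxels) next
      P <- B[, vox, drop = FALSE]
      if (any(apply(P, 1, stats::sd) == 0)) next
      D <- matrix(0, n, n)
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        D[a, b] <- D[b, a] <- 1 - stats::cor(P[a, ], P[b, ])
      }
      rho <- stats::cor(upper_tri(D), mv, method = "spearman")
      rho <- max(min(rho, 1 - 1e-7), -1 + 1e-7)
      zmap[i, j, k] <- atanh(rho)
    }
  zmap
}

#' Group-level searchlight inference
#'
#' Voxelwise two-sided one-sample t-test of subject Fisher-z maps against
#' zero at centers defined in all maps, Benjamini-Hochberg FDR across the
#' defined centers, and a significance mask at the requested q level.
#'
#' @param maps List (>= 3) of `searchlight_map` objects or z arrays of equal
#'   shape.
#' @param q FDR level for the significance mask.
#' @return A list with `t`, `p`, `q_value` (3-D arrays, `NA` where
#'   undefined), `significant` (logical array), `n_subjects`.
#' @export
group_searchlight <- function(maps, q = 0.05) {
  zs <- lapply(maps, function(m) if (inherits(m, "searchlight_map")) m$z else m)
  if (length(zs) < 3L) stop("need >= 3 subjects")
  shape <- dim(zs[[1]])
  for (z in zs) if (!identical(dim(z), shape)) stop("maps are not aligned")
  Z <- vapply(zs, as.vector, numeric(prod(shape)))
  defined <- rowSums(is.na(Z)) == 0L
  if (!any(defined)) stop("no commonly defined centers")
  n <- ncol(Z)
  mu <- rowMeans(Z[defined, , drop = FALSE])
  sdv <- apply(Z[defined, , drop = FALSE], 1L, stats::sd)
  tval <- mu / (sdv / sqrt(n))
  pval <- 2 * stats::pt(-abs(tval), df = n - 1)
  qval <- fdr_bh(pval)
  tmap <- array(NA_real_, shape); tmap[defined] <- tval
  pmap <- array(NA_real_, shape); pmap[defined] <- pval
  qmap <- array(NA_real_, shape); qmap[defined] <- qval
  sig <- array(FALSE, shape); sig[defined] <- qval < q
  list(t = tmap, p = pmap, q_value = qmap, significant = sig, n_subjects = n)
}

#' Dice overlap between two binary volumes
#'
#' `2 |A & B| / (|A| + |B|)`; 1 when both are empty.
#'
#' @param a,b Logical arrays of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
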