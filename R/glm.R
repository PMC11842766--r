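# Amplitude-modulated GLM for rating tasks: gamma-variate HRF, design
# construction with mean-centered modulators and polynomial nuisance trends,
# ordinary least squares, and the network x condition repeated-measures
# analysis of modulated betas.

#' Gamma-variate hemodynamic response kernel
#'
#' `h(t) = (t / (p q))^p exp(p - t / q)` for `t >= 0`, sampled at `dt` and
#' normalized to peak 1. The analytic peak sits at `t = p q` (about 4.70 s at
#' the defaults, the standard gamma-variate used by common fMRI software).
#' The sampled support is truncated after the peak once values fall below
#' `1e-4` of the peak.
#'
#' @param dt Sample spacing in seconds.
#' @param p Shape parameter.
#' @param q Scale parameter in seconds.
#' @return A list of class `hrf_kernel` with `samples`, `times`, `dt`, `p`,
#'   `q`.
#' @export
gamma_hrf <- function(dt, p = 8.6, q = 0.547) {
  if (dt <= 0 || p <= 0 || q <= 0) stop("dt, p and q must be positive")
  peak_t <- p * q
  # generous upper bound on support; truncated below
  t <- seq(0, 8 * peak_t, by = dt)
  h <- (t / peak_t)^p * exp(p - t / q)
  h <- h / max(h)
  past_peak <- t > peak_t & h < 1e-4
  if (any(past_peak)) {
    cut <- which(past_peak)[1]
    t <- t[seq_len(cut)]
    h <- h[seq_len(cut)]
  }
  structure(list(samples = h, times = t, dt = dt, p = p, q = q),
            class = "hrf_kernel")
}

# Convolve a set of events (onset seconds, amplitudes) with the HRF and
# sample at the TR grid. Events are laid on a fine grid (dt) and the
# convolution is read out at volume acquisition times.
.convolve_events <- function(onsets, amplitudes, tr, n_vols, hrf) {
  dt <- hrf$dt
  run_len <- n_vols * tr
  grid <- seq(0, run_len, by = dt)
  stick <- numeric(length(grid))
  idx <- round(onsets / dt) + 1L
  if (any(idx < 1L | idx > length(grid))) stop("onsets outside the run")
  for (e in seq_along(idx)) stick[idx[e]] <- stick[idx[e]] + amplitudes[e]
  conv <- stats::convolve(stick, rev(hrf$samples), type = "open")
  conv <- conv[seq_along(grid)]
  vol_idx <- round((0:(n_vols - 1)) * tr / dt) + 1L
  conv[vol_idx]
}

# Legendre-style polynomial trend columns (orthogonal over the run) up to
# the requested degree, including the constant.
.poly_trends <- function(n_vols, polort) {
  x <- seq(-1, 1, length.out = n_vols)
  cols <- sapply(0:polort, function(d) {
    if (d == 0) rep(1, n_vols) else x^d
  })
  # orthogonalize successively (Gram-Schmidt) for numerical stability
  Q <- qr.Q(qr(cols))
  Q <- Q * sign(Q[n_vols, 1])  # keep the constant column positive
  colnames(Q) <- paste0("polort", 0:polort)
  Q
}

#' Build an amplitude-modulated design matrix
#'
#' One unit-amplitude onset regressor plus one modulated regressor whose
#' event amplitudes are the mean-centered modulator values (so the onset
#' column carries the mean response and the modulated column the
#' rating-driven deviation), both convolved with the gamma-variate HRF,
#' together with polynomial nuisance trends up to degree `polort` and any
#' extra nuisance columns. A modulated column that is identically zero after
#' centering (constant modulator) is dropped with a warning.
#'
#' @param onsets Event onset times in seconds.
#' @param modulators Behavioural covariate per event.
#' @param tr Repetition time in seconds.
#' @param n_vols Number of volumes.
#' @param polort Highest polynomial trend degree (default cubic).
#' @param hrf An [gamma_hrf()] kernel; defaults to `gamma_hrf(dt = 0.1)`.
#' @param nuisance Optional extra nuisance matrix (`n_vols` rows).
#' @return A list of class `modulated_design` with `design` (matrix with
#'   labelled columns), `dropped` (labels of dropped columns).
#' @export
build_modulated_design <- function(onsets, modulators, tr, n_vols,
                                   polort = 3L, hrf = NULL, nuisance = NULL) {
  if (length(onsets) != length(modulators))
    stop("modulators must align with onsets")
  if (any(onsets < 0 | onsets > n_vols * tr)) stop("onsets outside the run")
  if (is.null(hrf)) hrf <- gamma_hrf(dt = 0.1)
  onset_col <- .convolve_events(onsets, rep(1, length(onsets)), tr, n_vols, hrf)
  centered <- modulators - mean(modulators)
  mod_col <- .convolve_events(onsets, centered, tr, n_vols, hrf)
  X <- cbind(onset = onset_col, modulated = mod_col)
  dropped <- character(0)
  if (all(abs(mod_col) < 1e-12)) {
    warning("constant modulator: modulated column is zero and was dropped")
    X <- X[, "onset", drop = FALSE]
    dropped <- "modulated"
  }
  trends <- .poly_trends(n_vols, polort)
  X <- cbind(X, trends)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vols) stop("nuisance must have n_vols rows")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  structure(list(design = X, dropped = dropped, tr = tr, polort = polort),
            class = "modulated_design")
}

#' Ordinary least-squares fit of a modulated design
#'
#' @param y Time series of length `n_vols`.
#' @param X A `modulated_design` or plain design matrix (full column rank).
#' @return A list of class `glm_fit` with `beta` (named), `fitted`,
#'   `residuals`, `sigma2` (residual variance).
#' @export
fit_glm <- function(y, X) {
  M <- if (inherits(X, "modulated_design")) X$design else as.matrix(X)
  if (length(y) != nrow(M)) stop("length(y) must equal the design's rows")
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) stop("rank-deficient design matrix")
  beta <- qr.coef(qr_m, y)
  fitted <- drop(M %*% beta)
  res <- y - fitted
  structure(list(beta = beta, fitted = fitted, residuals = res,
                 sigma2 = sum(res^2) / (length(y) - ncol(M))),
            class = "glm_fit")
}

#' Network x condition analysis of modulated betas
#'
#' Two-stage repeated-measures procedure over the rating task's modulated
#' regression coefficients: stage 1 averages betas per subject x network x
#' condition; stage 2 runs a 2 x 2 repeated-measures ANOVA across subjects
#' (network, condition, and interaction F-tests via `aov` with a
#' within-subject error stratum) and post-hoc paired t-tests between
#' conditions within each network, FDR-adjusted.
#'
#' @param betas Data frame with columns `subject`, `roi`, `condition`,
#'   `beta`.
#' @param partition Named vector (ROI id -> network label) or
#'   `network_partition`; unlabelled ROIs are dropped.
#' @return A list with `anova` (data frame: effect, F, df1, df2, p) and
#'   `posthoc` (data frame: network, contrast, t, df, p, q).
#' @export
psc_network_anova <- function(betas, partition) {
  labels <- if (inherits(partition, "network_partition")) partition$labels
            else partition
  betas <- betas[betas$roi %in% names(labels), ]
  if (nrow(betas) == 0L) stop("no ROI in `betas` is labelled by `partition`")
  betas$network <- factor(labels[betas$roi])
  betas$condition <- factor(betas$condition)
  if (nlevels(betas$network) != 2L || nlevels(betas$condition) != 2L)
    stop("expected exactly 2 networks and 2 conditions")
  cells <- stats::aggregate(beta ~ subject + network + condition, betas, mean)
  n_cells <- table(cells$subject)
  if (any(n_cells != 4L)) stop("missing subject x network x condition cells")
  cells$subject <- factor(cells$subject)
  fit <- stats::aov(beta ~ network * condition +
                      Error(subject / (network * condition)), data = cells)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- rn == term
    data.frame(effect = term, F = tab[i, "F value"],
               df1 = tab[i, "Df"], df2 = tab[rn == "Residuals", "Df"],
               p = tab[i, "Pr(>F)"])
  }
  anova_tab <- rbind(
    pull("Error: subject:network", "network"),
    pull("Error: subject:condition", "condition"),
    pull("Error: subject:network:condition", "network:condition")
  )
  conds <- levels(cells$condition)
  posthoc <- do.call(rbind, lapply(levels(cells$network), function(net) {
    wide <- merge(
      cells[cells$network == net & cells$condition == conds[1],
            c("subject", "beta")],
      cells[cells$network == net & cells$condition == conds[2],
            c("subject", "beta")],
      by = "subject")
    tt <- stats::t.test(wide$beta.x, wide$beta.y, paired = TRUE)
    data.frame(network = net,
               contrast = paste(conds[1], "vs", conds[2]),
               estimate = mean(wide$beta.x - wide$beta.y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  posthoc$q <- fdr_bh(posthoc$p)
  list(anova = anova_tab, posthoc = posthoc)
}
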