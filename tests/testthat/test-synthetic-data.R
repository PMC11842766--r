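test_that("config validation rejects malformed parameters", {
  expect_error(synth_config(n_items = 2), "n_items")
  expect_error(synth_config(choice_temperature = 0), "temperature")
  expect_error(synth_config(pattern_noise_sd = -1), "non-negative")
  expect_error(synth_config(volume_shape = c(8, 8)), "triple")
})

test_that("single-category degenerate space collapses to identical items", {
  cfg <- synth_config(seed = 1, n_items = 6, n_categories = 1)
  space <- gen_food_space(cfg)
  expect_equal(max(dist(space$coords)), 0)
  expect_true(all(space$sim == 1))
})

test_that("default food space plants five separable categories", {
  cfg <- synth_config(seed = 7)
  space <- gen_food_space(cfg)
  expect_equal(nrow(space$coords), 36L)
  expect_setequal(unique(space$category_label), 1:5)
  sil <- silhouette_mean(as.matrix(dist(space$coords)), space$category_label)
  expect_gt(sil, 0.6)
})

test_that("triplet enumeration covers all C(n,3) triplets, reps times", {
  for (n in c(3, 5, 8, 12)) {
    cfg <- synth_config(seed = 2, n_items = n, n_categories = 2)
    space <- gen_food_space(cfg)
    tr <- gen_triplet_responses(space, reps = 2, seed = 3)
    expect_equal(nrow(tr), 2 * choose(n, 3))
    expect_equal(nrow(unique(tr[, 1:3])), choose(n, 3))
    expect_true(all(tr$odd == tr$item_a | tr$odd == tr$item_b |
                      tr$odd == tr$item_c))
  }
})

test_that("odd item is the far item in the zero-temperature limit", {
  space <- make_space(c(0, 0.1, 5))
  tr <- gen_triplet_responses(space, reps = 50, temperature = 1e-9, seed = 4)
  expect_true(all(tr$odd == 3L))
})

test_that("empirical odd-choice frequencies match softmax probabilities", {
  space <- make_space(c(0, 0.4, 1.1, 2.0))
  temp <- 0.15
  tr <- gen_triplet_responses(space, reps = 1000, temperature = temp, seed = 5)
  S <- space$sim
  for (t in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
    rows <- tr$item_a == t[1] & tr$item_b == t[2] & tr$item_c == t[3]
    # closed-form choice probabilities
    u <- c(S[t[2], t[3]], S[t[1], t[3]], S[t[1], t[2]]) / temp
    p <- exp(u - max(u)); p <- p / sum(p)
    for (j in 1:3) {
      phat <- mean(tr$odd[rows] == t[j])
      se <- sqrt(p[j] * (1 - p[j]) / 1000)
      expect_lt(abs(phat - p[j]), 3 * se + 1e-12)
    }
  }
})

test_that("noiseless ROI patterns reproduce their network target geometry", {
  # many voxels: finite-voxel sampling error of the empirical correlation
  # (~1/sqrt(V)) is the only deviation from the target once noise is 0
  cfg <- synth_config(seed = 11, n_subjects = 2, pattern_noise_sd = 0,
                      voxels_per_roi = 2000)
  space <- gen_food_space(cfg)
  roi <- gen_roi_patterns(cfg, space, subject_jitter = 0)
  for (r in roi$roi_ids) {
    target <- roi$target_rdms[[roi$network[r]]]
    rho <- spearman_upper(compute_rdm(roi$patterns[[1]][[r]]), target)
    expect_gte(rho, 0.95)
  }
  # two ROIs of the same network share the target: RDMs nearly identical
  r1 <- compute_rdm(roi$patterns[[1]][["roi01"]])
  r2 <- compute_rdm(roi$patterns[[1]][["roi02"]])
  expect_gt(cor(upper_tri(r1), upper_tri(r2)), 0.9)
})

test_that("default cohort has the planned dimensions", {
  cfg <- synth_config(seed = 12)
  space <- gen_food_space(cfg)
  roi <- gen_roi_patterns(cfg, space)
  expect_length(roi$patterns, 43L)
  expect_length(roi$roi_ids, 17L)
  expect_equal(unname(table(roi$network)[c("net1", "net2", "outlier")]),
               c(6L, 10L, 1L), ignore_attr = TRUE)
  expect_equal(dim(roi$patterns[[1]][[1]]), c(36L, 120L))
  # planted target RDMs satisfy RDM invariants
  for (tg in roi$target_rdms) {
    expect_equal(tg, t(tg))
    expect_true(all(diag(tg) == 0))
    expect_true(all(tg >= 0 & tg <= 2))
  }
})

test_that("searchlight dataset plants a cuboid of the configured fraction", {
  cfg <- synth_config(seed = 13)
  sl <- gen_searchlight_dataset(cfg, n_subjects = 3)
  expect_lt(abs(mean(sl$truth) - cfg$truth_frac), 0.06)
  expect_equal(dim(sl$truth), cfg$volume_shape)
  expect_equal(nrow(sl$betas[[1]]), 36L)
  # noiseless variant: searchlight rho ~ 1 well inside the cuboid
  sl0 <- gen_searchlight_dataset(cfg, n_subjects = 1, noise_sd = 0)
  map <- run_searchlight(list(data = sl0$betas[[1]], shape = sl0$shape),
                         sl0$mask, sl0$target_rdm, radius = 3)
  interior <- array(FALSE, sl0$shape)
  interior[7:10, 7:10, 5:6] <- TRUE   # > radius away from cuboid faces
  expect_gt(min(map$rho[interior]), 0.95)
})

test_that("rating task plants correlated ratings and the network pattern", {
  cfg <- synth_config(seed = 14, n_subjects = 8)
  space <- gen_food_space(cfg)
  # noise-free ratings: conditions perfectly correlated
  psc0 <- gen_psc_dataset(cfg, space, mode = "betas",
                          rating_subject_sd = 0, rating_cond_sd = 0)
  w <- reshape(psc0$ratings, idvar = c("subject", "item"),
               timevar = "condition", direction = "wide")
  expect_equal(cor(w$rating.pleasantness, w$rating.self_control), 1)
  # default noise: between-subject mean rating correlation >= 0.9
  psc <- gen_psc_dataset(cfg, space, mode = "betas")
  rmat <- sapply(split(psc$ratings, psc$ratings$subject), function(d)
    d$rating[order(d$condition, d$item)])
  cors <- cor(rmat)
  expect_gte(mean(cors[upper.tri(cors)]), 0.9)
  # planted beta signs follow the two-network opponent pattern
  tr <- psc$truth
  expect_true(all(tr$beta[tr$network == "net2"] > 0))
  expect_true(all(tr$beta[tr$network == "net1" &
                            tr$condition == "self_control"] > 0))
  expect_true(all(tr$beta[tr$network == "net1" &
                            tr$condition == "pleasantness"] < 0))
})

test_that("noise-free time series returns the planted modulated beta exactly", {
  cfg <- synth_config(seed = 15, n_subjects = 1, n_items = 12)
  space <- gen_food_space(cfg)
  psc <- gen_psc_dataset(cfg, space, mode = "timeseries", ts_noise_sd = 0)
  run <- psc$series[[1]][["self_control"]]
  X <- build_modulated_design(run$onsets, run$modulators, tr = cfg$tr_seconds,
                              n_vols = 206L)
  b <- fit_glm(run$y[, "roi01"], X)$beta[["modulated"]]
  expect_equal(b, 0.8, tolerance = 1e-6)
})

test_that("generators are seed-deterministic", {
  cfg <- synth_config(seed = 16, n_subjects = 2)
  s1 <- gen_food_space(cfg); s2 <- gen_food_space(cfg)
  expect_identical(s1, s2)
  t1 <- gen_triplet_responses(s1, reps = 1, seed = 9)
  t2 <- gen_triplet_responses(s1, reps = 1, seed = 9)
  t3 <- gen_triplet_responses(s1, reps = 1, seed = 10)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  r1 <- gen_roi_patterns(cfg, s1); r2 <- gen_roi_patterns(cfg, s1)
  expect_identical(r1, r2)
})
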