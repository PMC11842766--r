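#!/usr/bin/env Rscript
# Stage 2: behavioural food-similarity structure.
#
# Estimates the 36 x 36 similarity matrix from the triplet responses (pairwise
# proportion of triplets in which neither food was the odd one out), extracts
# principal components, discovers food categories by silhouette-validated
# k-means on the first two PC scores, and writes the model RDMs used by the
# RSA stages.

library(foodnet)

seed <- 42L
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

triplets <- read_triplets_tsv("results/data/triplets.tsv")
n_items <- max(triplets[, c("item_a", "item_b", "item_c")])
S <- triplet_similarity_matrix(triplets, n_items)
pca <- pca_similarity(S)
km <- select_k_kmeans(pca$scores[, 1:2], k_range = 2:10, seed = seed + 11L)

lab <- sprintf("food%02d", seq_len(n_items))
dimnames(S$values) <- list(lab, lab)
write_rdm_csv(S$values, file.path(out, "similarity.csv"))
write.csv(pca$scores, file.path(out, "pca_scores.csv"))
write.csv(data.frame(item = seq_len(n_items), category = km$labels),
          file.path(out, "categories.csv"), row.names = FALSE)

models <- list(similarity = similarity_rdm(S$values),
               pc1 = pc_rdm(pca, 1L), pc2 = pc_rdm(pca, 2L))
for (m in names(models)) {
  dimnames(models[[m]]) <- list(lab, lab)
  write_rdm_csv(models[[m]], file.path(out, sprintf("model_%s.csv", m)))
}

f12 <- 100 * sum(pca$variance_fraction[1:2])
cat(sprintf("first two components explain %.1f%% of similarity variance\n", f12))
cat(sprintf("silhouette-selected number of food categories: %d\n", km$chosen_k))
cat(sprintf("silhouette by k: %s\n",
            paste(sprintf("k=%s %.3f", names(km$silhouette_by_k),
                          km$silhouette_by_k), collapse = ", ")))
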