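#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the latent food-property space (36 foods, 5 planted categories),
# the full odd-one-out triplet response set (7140 triplets x 5 repetitions),
# and per-subject rating tables for the pleasantness/self-control task, and
# writes the tabular inputs under results/data/. Voxel-level patterns are
# regenerated by later stages from the same seed (they are large and cheap
# to redraw).

library(foodnet)

seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
space <- gen_food_space(cfg)
triplets <- gen_triplet_responses(space, reps = cfg$triplet_reps,
                                  temperature = cfg$choice_temperature,
                                  seed = seed + 10L)
write_triplets_tsv(triplets, file.path(out, "triplets.tsv"))

psc <- gen_psc_dataset(cfg, space, mode = "betas")
write.table(psc$ratings, file.path(out, "ratings.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(psc$betas, file.path(out, "psc_betas.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

truth <- list(seed = seed,
              category_label = space$category_label,
              processing_score = space$processing_score,
              hedonic_score = space$hedonic_score,
              psc_truth = psc$truth)
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d subjects, %d foods, %d triplet responses\n",
            cfg$n_subjects, cfg$n_items, nrow(triplets)))
cat(sprintf("wrote triplets.tsv, ratings.tsv, psc_betas.tsv, truth.json to %s\n",
            out))
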