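#!/usr/bin/env Rscript

# Step 3 — nonrotated behavioral PLS.
#
# Relates the stacked disconnectome maps to (female, age, MoCA) with
# identity contrasts: one latent variable per behavioral variable, whose
# salience map is the vector of voxel-wise correlations with that
# variable. Latent-variable significance by 1000 permutations; voxel
# reliability by 1000 bootstrap resamples, expressed as pseudo-z
# (bootstrap ratio) maps. Outputs under results/pls/.

suppressMessages(library(disconnectr))

SEED <- 1

cohort <- read_cohort("results/cohort")
map_files <- sort(list.files("results/maps", full.names = TRUE))
ids <- sub("_disconnectome\\.nii$", "", basename(map_files))
maps <- lapply(seq_along(map_files), function(i) {
  vol <- read_volume(map_files[i])
  structure(list(volume = vol, subject_id = ids[i],
                 n_controls = length(cohort$controls)),
            class = "disconnectome_map")
})
stopifnot(identical(ids, cohort$cohort$subject_id))

pls <- pls_brain_behavior(maps, cohort$cohort,
                          columns = c("female", "age", "moca"),
                          n_perm = 1000, n_boot = 1000,
                          seed = derive_seed(SEED, "pls"))

dir.create("results/pls", showWarnings = FALSE, recursive = TRUE)
for (k in seq_along(pls$columns)) {
  write_volume(salience_to_volume(pls$bsr[, k], pls$mask_index, pls$grid),
               sprintf("results/pls/bsr_%s.nii", pls$columns[k]), "float")
  write_volume(salience_to_volume(pls$salience[, k], pls$mask_index,
                                  pls$grid),
               sprintf("results/pls/salience_%s.nii", pls$columns[k]),
               "float")
}
scores <- data.frame(subject_id = ids[pls$subjects_used],
                     pls$brain_scores)
names(scores)[-1] <- paste0("score_", pls$columns)
write.table(scores, "results/pls/brain_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(columns = pls$columns, strength = pls$strength,
       perm_p = pls$perm_p, n = pls$n, n_perm = pls$n_perm,
       n_boot = pls$n_boot, mask_size = length(pls$mask_index),
       seed = pls$seed),
  "results/pls/pls_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("PLS over %d subjects x %d voxels (results/pls/)\n",
            pls$n, length(pls$mask_index)))
for (k in seq_along(pls$columns))
  cat(sprintf("  LV %-7s strength %6.2f  perm p = %.4f\n",
              pls$columns[k], pls$strength[k], pls$perm_p[k]))
cat("Only the MoCA latent variable is expected to pass permutation",
    "testing:\nthe generator couples disconnection to cognition, not to",
    "age or sex.\n")
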