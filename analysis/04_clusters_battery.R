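#!/usr/bin/env Rscript

# Step 4 — cluster extraction and battery correlations.
#
# Thresholds the MoCA pseudo-z map at |z| > 3 (strictly), labels connected
# components under 26-connectivity, summarises them in a cluster table
# (size, peak pseudo-z, peak voxel and mm coordinates), and correlates the
# per-subject mean disconnection within each cluster with the cognitive
# battery, MoCA and the PLS brain scores. Outputs under results/clusters/.

suppressMessages(library(disconnectr))

cohort <- read_cohort("results/cohort")
bsr <- read_volume("results/pls/bsr_moca.nii")
map_files <- sort(list.files("results/maps", full.names = TRUE))
maps <- lapply(map_files, function(f)
  structure(list(volume = read_volume(f),
                 subject_id = sub("_disconnectome\\.nii$", "", basename(f)),
                 n_controls = length(cohort$controls)),
            class = "disconnectome_map"))

dir.create("results/clusters", showWarnings = FALSE, recursive = TRUE)
neg <- extract_clusters(bsr, threshold = 3, connectivity = 26,
                        tail = "negative")
pos <- extract_clusters(bsr, threshold = 3, connectivity = 26,
                        tail = "positive")
write.table(neg$table, "results/clusters/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pos$table, "results/clusters/clusters_other_tail.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_volume(neg$labels, "results/clusters/cluster_labels.nii", "float")

cat("Clusters with pseudo-z < -3 (disconnection linked to lower MoCA):\n")
print(neg$table[, c("cluster_id", "size_vox", "size_mm3", "max_bsr",
                    "peak_i", "peak_j", "peak_k")], row.names = FALSE)
cat(sprintf("Opposite tail: %d cluster(s).\n", nrow(pos$table)))

if (nrow(neg$table)) {
  cv <- cluster_disconnectivity(maps, neg$labels)
  write.table(data.frame(subject_id = cohort$cohort$subject_id, cv),
              "results/clusters/cluster_values.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  scores <- read.table("results/pls/brain_scores.tsv", sep = "\t",
                       header = TRUE)
  battery <- cohort$cohort[, c("fluency_phonetic", "fluency_semantic",
                               "attention_span", "working_memory",
                               "psychomotor_speed", "spatial_memory")]
  extra <- data.frame(
    moca = cohort$cohort$moca,
    brain_score = scores$score_moca[match(cohort$cohort$subject_id,
                                          scores$subject_id)])
  cw <- correlate_with_battery(cv, battery, extra)
  long <- expand.grid(predictor = rownames(cw$r), measure = colnames(cw$r),
                      stringsAsFactors = FALSE)
  long$r <- as.vector(cw$r); long$n <- as.vector(cw$n)
  long$reason <- as.vector(cw$reason)
  write.table(long, "results/clusters/battery_correlations.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)

  cl_rows <- grepl("^cluster_", rownames(cw$r))
  cat(sprintf("\nBattery correlations (n per cell %d-%d):\n",
              min(cw$n[cl_rows, ]), max(cw$n[cl_rows, ])))
  print(round(cw$r, 2))
  cat(sprintf("cluster x battery correlations negative: %d of %d\n",
              sum(cw$r[cl_rows, ] < 0, na.rm = TRUE),
              sum(!is.na(cw$r[cl_rows, ]))))
}
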