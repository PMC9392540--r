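#!/usr/bin/env Rscript

# Step 1 — generate the synthetic cohort.
#
# Builds the study-shaped phantom world: 20 normative control tractograms
# (two tube bundles on a 32^3 x 2 mm grid), 102 subjects with 1-3 spherical
# lesions of widely varying size (35% of subjects lesioned on the target
# bundle), and a behavioral table in which the cognitive score declines
# with true disconnection of the target bundle. Writes everything, plus
# the generator's ground truth, under results/cohort/.

suppressMessages(library(disconnectr))

SEED <- 1  # master seed for the whole analysis; steps derive sub-seeds

sim <- simulate_cohort(seed = SEED)
write_cohort("results/cohort", sim)

cohort <- sim$cohort
cat("Simulated cohort written to results/cohort/\n")
cat(sprintf("  subjects: %d (%d on target), controls: %d\n",
            nrow(cohort), sum(sim$truth$on_target), length(sim$controls)))
cat(sprintf("  lesion size: %d-%d voxels (median %d)\n",
            min(cohort$lesion_voxels), max(cohort$lesion_voxels),
            round(median(cohort$lesion_voxels))))
cat(sprintf("  MoCA: median %d, impairment rate (MoCA < 26): %.0f%%\n",
            round(median(cohort$moca)),
            100 * impairment_rate(cohort)$rate))
cat(sprintf("  planted coupling: r(MoCA, true target disconnection) = %.2f\n",
            cor(cohort$moca, sim$truth$d)))
cat(sprintf("  battery subsample: %d of %d subjects\n",
            sum(!is.na(cohort$fluency_phonetic)), nrow(cohort)))
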