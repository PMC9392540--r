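#!/usr/bin/env Rscript

# Step 2 — estimate per-subject disconnectome maps.
#
# For each subject, streamlines of every normative control that pass
# through the lesion are selected, binarized into visitation maps, and
# averaged over controls: each voxel's value is the fraction of controls
# in whom that voxel's fibers are disrupted by the lesion. Maps are written
# as 32-bit float NIfTI under results/maps/.

suppressMessages(library(disconnectr))

cohort <- read_cohort("results/cohort")
stopifnot(check_cohort("results/cohort")$ok)

batch <- suppressWarnings(
  disconnectome_batch(cohort$lesions, cohort$controls, cohort$grid))
if (length(batch$errors))
  stop("disconnectome failed for: ", paste(names(batch$errors),
                                           collapse = ", "))

dir.create("results/maps", showWarnings = FALSE, recursive = TRUE)
for (m in batch$maps)
  write_volume(m$volume,
               file.path("results/maps",
                         paste0(m$subject_id, "_disconnectome.nii")),
               datatype = "float")

nz <- vapply(batch$maps, function(m) sum(m$volume$data > 0), numeric(1))
mx <- vapply(batch$maps, function(m) max(m$volume$data), numeric(1))
cat(sprintf("Wrote %d disconnectome maps to results/maps/\n",
            length(batch$maps)))
cat(sprintf("  nonzero voxels per subject: %d-%d (median %d)\n",
            min(nz), max(nz), round(median(nz))))
cat(sprintf("  %d subjects reach full agreement (probability 1) somewhere\n",
            sum(mx == 1)))
cat(sprintf("  all values are exact multiples of 1/%d: %s\n",
            batch$maps[[1]]$n_controls,
            all(vapply(batch$maps, function(m)
              all(m$volume$data * m$n_controls ==
                    round(m$volume$data * m$n_controls)), logical(1)))))
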