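#!/usr/bin/env Rscript
# Generate the synthetic study data: a small imaging cohort with a
# planted connectivity gradient (two of the subjects carry a localized
# artifact), plus a larger tabular cohort whose gradient shape is
# coupled to a biomarker, genotype and memory with known effect sizes.
#
# Outputs under results/data/: per-subject ROI and target BOLD volumes
# (NIfTI), planted-truth sidecars (TSV), and the cohort table.

suppressPackageStartupMessages(library(connectograd))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_clean <- 10
n_artifact <- 2

message("Simulating ", n_clean, " clean and ", n_artifact,
        " artifact subjects (ROI 8x8x8, T = 300, noise_sd = 0.5)...")
manifest <- data.frame(subject = character(), artifact = logical(),
                       stringsAsFactors = FALSE)
for (i in seq_len(n_clean + n_artifact)) {
  id <- sprintf("sub-%02d", i)
  artifact <- i > n_clean
  sc <- gradient_scenario(seed = 100 + i)
  sim <- if (artifact) simulate_artifact_subject(sc, n_outliers = 3,
                                                 seed = 100 + i)
         else simulate_gradient_bold(sc)
  write_volume(sim$roi, file.path(out, paste0(id, "_roi_bold.nii.gz")))
  write_volume(sim$target, file.path(out, paste0(id, "_target_bold.nii.gz")))
  write_volume(sim$roi$mask * 1, file.path(out, paste0(id, "_roi_mask.nii.gz")),
               grid = sim$roi$grid)
  write_volume(sim$target$mask * 1,
               file.path(out, paste0(id, "_target_mask.nii.gz")),
               grid = sim$target$grid)
  write_cohort(sim$truth, file.path(out, paste0(id, "_truth.tsv")))
  manifest <- rbind(manifest, data.frame(subject = id, artifact = artifact))
}
write_cohort(manifest, file.path(out, "manifest.tsv"))

message("Simulating the tabular cohort (n = 100, biomarker coupling r = 0.5)...")
co <- cohort_scenario(n_subjects = 100, effect_biomarker = 0.5,
                      effect_group = 0.8, effect_memory = 0.3, seed = 42)
cohort <- simulate_cohort(co)
write_cohort(cohort$table, file.path(out, "cohort.tsv"))
write_cohort(cohort$truth, file.path(out, "cohort_truth.tsv"))

message("Wrote imaging cohort (", nrow(manifest), " subjects) and cohort table (",
        nrow(cohort$table), " subjects) under ", out)
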