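#!/usr/bin/env Rscript

# Build the full phantom battery — six two-level spheres, the ~11 mL
# spheroid under four uptake patterns, the irregular lesion under all five —
# simulate one PET image per phantom, and record the ground-truth geometry.
# Volumes (NIfTI) and printable page samples go to results/phantoms/.

suppressPackageStartupMessages(library(ssphantom))

out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- paper_experiment_config(noise_seeds = 1L)
rows <- list()
for (entry in cfg$lesions) {
  case <- simulate_lesion_case(entry, cfg, noise_seed = 1L)
  write_nifti_volume(case$template,
                     file.path(out, paste0(entry$id, "_template.nii.gz")))
  write_nifti_volume(case$image,
                     file.path(out, paste0(entry$id, "_pet.nii.gz")))
  write_nifti_volume(case$truth,
                     file.path(out, paste0(entry$id, "_truth.nii.gz")))
  rows[[entry$id]] <- data.frame(
    lesion = entry$id,
    shape = entry$spec$shape_kind,
    pattern = entry$spec$pattern,
    template_volume_ml = mask_volume_ml(case$template$lesion_mask),
    pet_truth_volume_ml = mask_volume_ml(case$truth),
    core_volume_ml = if (is.null(case$core)) NA else mask_volume_ml(case$core),
    pet_max_intensity = max(case$image$values))
  message(sprintf("%-28s truth %.2f mL on the PET grid", entry$id,
                  mask_volume_ml(case$truth)))
}
summary <- do.call(rbind, rows)
write.csv(summary, file.path(out, "phantom_summary.csv"), row.names = FALSE)

# printable pages for one phantom, as in the physical workflow
tpl <- simulate_lesion_case(cfg$lesions[[6]], cfg, 1L)$template  # S6
pages <- export_printout_pages(tpl)
write_pages_png(pages[seq(1, length(pages), by = 8)],
                file.path(out, "pages_S6"))
message(sprintf("%d phantoms, %d printable pages for S6; summary in %s",
                nrow(summary), length(pages),
                file.path(out, "phantom_summary.csv")))
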