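#!/usr/bin/env Rscript
# Phantom demonstration: builds one phantom per uptake profile, writes the
# SUV/label NIfTI pairs, and tabulates volume-threshold curves against the
# analytic continuum values where a closed form exists.

suppressPackageStartupMessages(library(hfpet))

out_dir <- "results/phantoms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

profiles <- list(
  uniform       = list(),
  radial_linear = list(),
  radial_power  = list(gamma = 2),
  necrotic_core = list(core_fraction = 0.4),
  multifocal    = list(k_seeds = 4))

rows <- list()
for (prof in names(profiles)) {
  sp <- phantom_spec(grid_shape = c(81, 81, 81), tumor_radius_mm = 30,
                     profile = prof, profile_params = profiles[[prof]],
                     suv_max_target = 10, noise_sd = 0.15, seed = 11)
  ph <- generate_phantom(sp)
  write_phantom_nifti(ph, file.path(out_dir, paste0(prof, ".nii.gz")),
                      file.path(out_dir, paste0(prof, "_labels.nii.gz")))
  res <- hf_for_patient(ph$volume, ph$lesions)
  curve <- attr(res, "curve")
  analytic <- if (prof == "multifocal") rep(NA_real_, nrow(curve)) else
    analytic_volume_threshold(prof, 30, curve$threshold_pct,
                              profiles[[prof]])$volume_cm3
  rows[[prof]] <- data.frame(profile = prof, curve,
                             analytic_cm3 = analytic,
                             hf = res$hf, r2 = res$r2)
  cat(sprintf("%-14s HF = %6.3f cm^3/%%  (r2 = %.3f)\n", prof, res$hf, res$r2))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "volume_threshold_curves.csv"),
          row.names = FALSE)
cat("\nThe uniform sphere is the flat-curve degenerate case (HF ~ 0);\n",
    "the necrotic-core and power profiles lose volume faster across the\n",
    "40-80% thresholds and score the highest heterogeneity.\n", sep = "")
cat("wrote", file.path(out_dir, "volume_threshold_curves.csv"), "\n")
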