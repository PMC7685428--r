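#!/usr/bin/env Rscript
# Preprocess: 8 mm Gaussian smoothing, the 0.2 mean-GM analysis mask over
# all subjects of both sites, and per-site regression of age and sex.
source("analysis/00_config.R")

cohort <- read_cohort(COHORT_DIR)
parts <- cohort$participants
message("Smoothing ", nrow(parts), " volumes at ", FWHM_MM, " mm FWHM ...")
smoothed <- lapply(cohort$volumes, smooth_volume, fwhm_mm = FWHM_MM)

mask <- build_mask(smoothed, threshold = MASK_THRESHOLD)
message("Analysis mask: ", mask$voxel_count, " voxels above ",
        MASK_THRESHOLD, " mean GM density.")

features <- assemble_features(smoothed, mask, subject_ids = parts$subject_id)
features$provenance$smoothed <- FWHM_MM
features <- residualize(features, parts, parts$site, use = c("age", "sex"))
print(features)

dir.create(PREP_DIR, recursive = TRUE, showWarnings = FALSE)
write_volume(volume_grid(array(as.numeric(mask$mask), dim(mask$mask)),
                         mask$affine),
             file.path(PREP_DIR, "mask.nii.gz"), datatype = "uint8")
save_features(features, file.path(PREP_DIR, "features"))
message("Mask and residualized feature matrix written to ", PREP_DIR, ".")
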