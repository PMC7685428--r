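#!/usr/bin/env Rscript
# Clinical statistics: demographic contrasts of the simulated cohort
# (summary-statistic t and chi-square forms), ROI mean GM in the
# significant clusters, Spearman correlations with clinical scores
# (patients of the model's own site), and ROI-ROI correlations.
source("analysis/00_config.R")

features <- load_features(file.path(PREP_DIR, "features"))
parts <- read.delim(file.path(COHORT_DIR, "participants.tsv"))
dir.create(CLIN_DIR, recursive = TRUE, showWarnings = FALSE)

## Demographic contrasts from the generated cohort's own summary rows
demo_rows <- list()
for (s in site_names) {
  pat <- subset(parts, site == s & diagnosis == "patient")
  con <- subset(parts, site == s & diagnosis == "control")
  tt <- t_from_summary(mean(pat$age), sd(pat$age), nrow(pat),
                       mean(con$age), sd(con$age), nrow(con))
  cs <- chi2_2x2(sum(pat$sex == "M"), sum(pat$sex == "F"),
                 sum(con$sex == "M"), sum(con$sex == "F"))
  message(sprintf("%s: age t(%d) = %.2f (p = %.2g), sex chi2 = %.3f (p = %.2f)",
                  s, tt$df, tt$t, tt$p, cs$chi2, cs$p))
  demo_rows[[s]] <- data.frame(site = s, age_t = tt$t, age_df = tt$df,
                               age_p = tt$p, sex_chi2 = cs$chi2,
                               sex_p = cs$p)
}
patA <- subset(parts, site == site_names[1] & diagnosis == "patient")
patB <- subset(parts, site == site_names[2] & diagnosis == "patient")
dur <- t_from_summary(mean(patA$duration), sd(patA$duration), nrow(patA),
                      mean(patB$duration), sd(patB$duration), nrow(patB))
message(sprintf("Between-site illness duration: t(%d) = %.2f, p = %.2g",
                dur$df, dur$t, dur$p))
write.table(do.call(rbind, demo_rows),
            file.path(CLIN_DIR, "demographics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ROI-level correlations per model
for (s in site_names) {
  lab <- read_volume(file.path(MAP_DIR, paste0(s, "_clusters.nii.gz")))
  lab_arr <- array(as.integer(round(lab$values)), dim(lab$values))
  if (!any(lab_arr > 0)) {
    message(s, ": no significant clusters; skipping ROI correlations.")
    next
  }
  roi <- roi_mean_gm(features, lab_arr)
  keep <- parts$site == s
  tab <- correlate_rois_clinical(roi[parts$subject_id[keep], , drop = FALSE],
                                 parts[keep, ], q = FDR_Q)
  n_unc <- sum(tab$sig_uncorrected); n_fdr <- sum(tab$sig_fdr)
  message(sprintf("%s model: %d ROI x variable cells, %d uncorrected p < 0.05, %d after FDR",
                  s, nrow(tab), n_unc, n_fdr))
  print(subset(as.data.frame(tab), sig_uncorrected,
               select = c(ROI, variable, rho, p, n)))
  write.table(tab, file.path(CLIN_DIR, paste0(s, "_roi_clinical.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pat_ids <- parts$subject_id[keep & parts$diagnosis == "patient"]
  if (ncol(roi) >= 2) {
    rr <- roi_roi_correlation(roi[pat_ids, , drop = FALSE])
    write.table(round(rr, 3),
                file.path(CLIN_DIR, paste0(s, "_roi_roi.tsv")),
                sep = "\t", quote = FALSE)
  }
}
message("Clinical tables written to ", CLIN_DIR, ".")
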