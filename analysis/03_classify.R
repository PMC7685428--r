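#!/usr/bin/env Rscript
# Classification: for each direction, select C by stratified ten-fold CV
# on the training site, report CV performance, test on the other site,
# and attach permutation p-values to the test accuracy and AUC.
source("analysis/00_config.R")

features <- load_features(file.path(PREP_DIR, "features"))
parts <- read.delim(file.path(COHORT_DIR, "participants.tsv"))
stopifnot(identical(parts$subject_id, features$subject_ids))
y <- ifelse(parts$diagnosis == "patient", -1, 1)

dir.create(CLS_DIR, recursive = TRUE, showWarnings = FALSE)
seeds <- gmsvm:::local_rng(MASTER_SEED)$draw_seeds(4)

perf_rows <- list()
for (i in seq_along(site_names)) {
  train_site <- site_names[i]
  test_site <- site_names[-i]
  tr <- parts$site == train_site
  stopifnot(length(intersect(parts$subject_id[tr], parts$subject_id[!tr])) == 0)
  message("== Model trained on ", train_site, ", tested on ", test_site, " ==")

  sel <- select_C(features$X[tr, ], y[tr], grid = C_GRID, k = FOLDS,
                  seed = seeds[i])
  message("CV-selected C = ", sel$C_best)
  cv <- cv_performance(features$X[tr, ], y[tr], C = sel$C_best, k = FOLDS,
                       seed = seeds[i])
  message("Ten-fold CV on ", train_site, ":"); print(cv)

  model <- train_linear_svm(features$X[tr, ], y[tr], C = sel$C_best)
  save_model(model, file.path(CLS_DIR, paste0("model_", train_site)))

  test <- evaluate(model, features$X[!tr, ], y[!tr])
  message("Cross-site test on ", test_site, ":"); print(test)

  perm <- permutation_test_performance(
    features$X[tr, ], y[tr], features$X[!tr, ], y[!tr],
    C = sel$C_best, B = B_PERFORMANCE, seed = seeds[2 + i])
  message(sprintf("Permutation p: accuracy %.4g, AUC %.4g (B = %d)",
                  perm$p_accuracy, perm$p_auc, B_PERFORMANCE))

  for (set in c("cv", "test")) {
    r <- if (set == "cv") cv else test
    perf_rows[[length(perf_rows) + 1]] <- data.frame(
      model = train_site, dataset = if (set == "cv") train_site else test_site,
      type = set, C = sel$C_best,
      accuracy = r$accuracy, sensitivity = r$sensitivity,
      specificity = r$specificity, ppv = r$ppv, npv = r$npv, auc = r$auc,
      p_accuracy = if (set == "test") perm$p_accuracy else NA,
      p_auc = if (set == "test") perm$p_auc else NA)
  }
}
perf <- do.call(rbind, perf_rows)
write.table(perf, file.path(CLS_DIR, "performance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Performance table written to ",
        file.path(CLS_DIR, "performance.tsv"))
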