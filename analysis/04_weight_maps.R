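#!/usr/bin/env Rscript
# Weight-map inference: permutation null of the SVM voxel weights,
# Benjamini-Hochberg FDR at q < 0.05, cluster-extent thresholding
# (> MIN_CLUSTER voxels, 26-connectivity), cluster tables with centers of
# gravity and mean weights, and the overlap of the two models' maps.
source("analysis/00_config.R")

features <- load_features(file.path(PREP_DIR, "features"))
parts <- read.delim(file.path(COHORT_DIR, "participants.tsv"))
truth <- read_volume(file.path(COHORT_DIR, "truth_mask.nii.gz"))
y <- ifelse(parts$diagnosis == "patient", -1, 1)
dir.create(MAP_DIR, recursive = TRUE, showWarnings = FALSE)
seeds <- gmsvm:::local_rng(MASTER_SEED + 1L)$draw_seeds(2)

sig_maps <- list()
for (i in seq_along(site_names)) {
  train_site <- site_names[i]
  tr <- parts$site == train_site
  model <- load_model(file.path(CLS_DIR, paste0("model_", train_site)))
  message("== Weight significance map, ", train_site, " model (B = ",
          B_WEIGHTS, ") ==")

  wn <- weight_null(features$X[tr, ], y[tr], C = model$C, B = B_WEIGHTS,
                    seed = seeds[i])
  sig <- voxel_pvalues(wn, q = FDR_Q)
  print(sig)

  sig_vol <- significance_volume(sig, features)
  clusters <- extract_clusters(sig_vol, affine = features$affine,
                               connectivity = CONNECTIVITY,
                               min_size = MIN_CLUSTER)
  w_vol <- weight_volume(model, features)
  tab <- cluster_table(clusters, w_vol)
  message(length(clusters), " clusters of > ", MIN_CLUSTER, " voxels:")
  print(tab)

  labels <- cluster_label_map(clusters, features$dim)
  message(sprintf("Dice overlap with the generator truth mask: %.3f",
                  dice(labels > 0, truth$values > 0)))

  p_vol <- array(1, features$dim)
  p_vol[features$voxel_map$voxel] <- sig$p
  write_volume(volume_grid(p_vol, features$affine),
               file.path(MAP_DIR, paste0(train_site, "_p.nii.gz")))
  write_volume(volume_grid(array(as.numeric(labels), features$dim),
                           features$affine),
               file.path(MAP_DIR, paste0(train_site, "_clusters.nii.gz")),
               datatype = "int16")
  write.table(tab, file.path(MAP_DIR, paste0(train_site, "_clusters.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig_maps[[train_site]] <- labels
}

ov <- overlap_map(sig_maps[[1]] > 0, sig_maps[[2]] > 0)
write_volume(volume_grid(array(as.numeric(ov), features$dim),
                         features$affine),
             file.path(MAP_DIR, "overlap.nii.gz"), datatype = "uint8")
message(sum(ov), " voxels significant in both models (overlap map written).")
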