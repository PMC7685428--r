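#' Configuration for a full two-site experiment
#'
#' Defaults are the analysis constants of the target study design: GM mask
#' threshold 0.2, 8 mm FWHM smoothing, age + sex nuisance regression per
#' site, ten-fold CV over a log2 C grid, 5000 permutations for both the
#' performance and the weight-map tests, FDR q < 0.05 with clusters of
#' more than 100 voxels under 26-connectivity.
#'
#' @param spec a [cohort_spec()] describing the synthetic cohort, or NULL
#'   when `dataset_dir` points to an on-disk cohort.
#' @param dataset_dir optional directory written by [write_cohort()].
#' @param mask_threshold GM density threshold for the analysis mask.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param covariates nuisance covariates regressed per site.
#' @param C_grid candidate regularization parameters.
#' @param folds CV folds for C selection.
#' @param B_performance permutations for test-set performance p-values
#'   (0 skips the test).
#' @param B_weights permutations for the voxel-weight significance map.
#' @param q FDR level.
#' @param min_cluster_size cluster-extent threshold (strictly greater).
#' @param connectivity 6, 18 or 26.
#' @param sidedness weight-map sidedness (see [voxel_pvalues()]).
#' @param strict_split if TRUE, the mask and the nuisance regression are
#'   fitted on the training site only and applied to the test site,
#'   instead of pooling both sites (the study's pooled construction is a
#'   mild information leak kept as the default for fidelity).
#' @param seed master seed; per-stage seeds are derived from it and
#'   recorded in the manifest.
#' @return a `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), dataset_dir = NULL,
                       mask_threshold = 0.2, fwhm_mm = 8,
                       covariates = c("age", "sex"),
                       C_grid = 2^(-10:10), folds = 10,
                       B_performance = 5000, B_weights = 5000,
                       q = 0.05, min_cluster_size = 100, connectivity = 26,
                       sidedness = "two-sided-magnitude",
                       strict_split = FALSE, seed = 1L) {
  structure(list(
    spec = spec, dataset_dir = dataset_dir, mask_threshold = mask_threshold,
    fwhm_mm = fwhm_mm, covariates = covariates, C_grid = C_grid,
    folds = folds, B_performance = B_performance, B_weights = B_weights,
    q = q, min_cluster_size = min_cluster_size, connectivity = connectivity,
    sidedness = sidedness, strict_split = strict_split,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full cross-site experiment
#'
#' Simulate (or load) the two-site cohort, smooth, mask, residualize, then
#' for each direction (site A model tested on site B, and vice versa):
#' select C by stratified ten-fold CV, report CV and cross-site
#' performance (with permutation p-values when `B_performance > 0`), build
#' the voxel-weight significance map, extract FDR + extent-thresholded
#' clusters, and correlate cluster GM with the training site's patient
#' clinical scores. Also computes the voxelwise overlap of the two models'
#' significant clusters.
#'
#' @param config a [run_config()].
#' @param run_dir output directory; NULL runs in memory only.
#' @return a `run_result` list: per-direction results, overlap map,
#'   cohort, config, manifest (when `run_dir` is set).
#' @export
run_experiment <- function(config = run_config(), run_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- local_rng(config$seed)$draw_seeds(8)
  seed_chain <- list(simulate = seeds[1], folds = seeds[2:3],
                     performance = seeds[4:5], weights = seeds[6:7])

  if (!is.null(config$dataset_dir)) {
    raw <- read_cohort(config$dataset_dir)
    cohort <- list(participants = raw$participants, volumes = raw$volumes,
                   truth = raw$truth, spec = config$spec)
  } else {
    spec <- config$spec
    spec$seed <- seed_chain$simulate
    cohort <- generate_cohort(spec)
  }
  # canonical subject order: results must not depend on input row order
  ord <- order(cohort$participants$subject_id)
  cohort$participants <- cohort$participants[ord, , drop = FALSE]
  cohort$volumes <- cohort$volumes[cohort$participants$subject_id]
  part <- cohort$participants
  sites <- sort(unique(part$site))
  if (length(sites) != 2) stop("the experiment needs exactly two sites")

  smoothed <- lapply(cohort$volumes, smooth_volume, fwhm_mm = config$fwhm_mm)
  y_all <- ifelse(part$diagnosis == "patient", -1, 1)

  prep_pooled <- if (!config$strict_split) {
    mask <- build_mask(smoothed, threshold = config$mask_threshold)
    feats <- assemble_features(smoothed, mask, subject_ids = part$subject_id)
    feats$provenance$smoothed <- config$fwhm_mm
    residualize(feats, part, part$site, use = config$covariates)
  }

  directions <- list()
  for (dir_i in 1:2) {
    train_site <- sites[dir_i]; test_site <- sites[3 - dir_i]
    tr <- part$site == train_site; te <- part$site == test_site
    stopifnot(length(intersect(part$subject_id[tr], part$subject_id[te])) == 0)

    if (config$strict_split) {
      mask <- build_mask(smoothed[part$subject_id[tr]],
                         threshold = config$mask_threshold)
      feats <- assemble_features(smoothed, mask, subject_ids = part$subject_id)
      feats$provenance$smoothed <- config$fwhm_mm
      feats <- residualize_train_apply(feats, part, tr, te, config$covariates)
    } else feats <- prep_pooled

    X_tr <- feats$X[tr, , drop = FALSE]; y_tr <- y_all[tr]
    X_te <- feats$X[te, , drop = FALSE]; y_te <- y_all[te]

    sel <- select_C(X_tr, y_tr, grid = config$C_grid, k = config$folds,
                    seed = seed_chain$folds[dir_i])
    cv_rep <- cv_performance(X_tr, y_tr, C = sel$C_best, k = config$folds,
                             seed = seed_chain$folds[dir_i])
    model <- train_linear_svm(X_tr, y_tr, C = sel$C_best)
    test_rep <- evaluate(model, X_te, y_te)
    perf_perm <- if (config$B_performance > 0)
      permutation_test_performance(X_tr, y_tr, X_te, y_te, C = sel$C_best,
                                   B = config$B_performance,
                                   seed = seed_chain$performance[dir_i])

    wnull <- weight_null(X_tr, y_tr, C = sel$C_best, B = config$B_weights,
                         seed = seed_chain$weights[dir_i])
    sig_map <- voxel_pvalues(wnull, sidedness = config$sidedness, q = config$q)
    sig_vol <- significance_volume(sig_map, feats)
    clusters <- extract_clusters(sig_vol, affine = feats$affine,
                                 connectivity = config$connectivity,
                                 min_size = config$min_cluster_size)
    w_vol <- weight_volume(model, feats)
    clu_tab <- cluster_table(clusters, w_vol)

    clinical <- NULL
    if (length(clusters)) {
      roi <- roi_mean_gm(feats, clusters)
      clinical <- correlate_rois_clinical(
        roi[part$subject_id[tr], , drop = FALSE],
        part[tr, , drop = FALSE], q = config$q)
      roi_pat <- roi[part$subject_id[tr & part$diagnosis == "patient"], ,
                     drop = FALSE]
      roi_roi <- if (ncol(roi) >= 2) roi_roi_correlation(roi_pat)
    } else roi_roi <- NULL

    directions[[paste0(train_site, "_to_", test_site)]] <- list(
      train_site = train_site, test_site = test_site,
      C = sel$C_best, cv_accuracy_per_C = sel$cv_accuracy,
      cv = cv_rep, test = test_rep, performance_permutation = perf_perm,
      significance = sig_map, clusters = clusters,
      cluster_table = clu_tab, cluster_labels =
        cluster_label_map(clusters, feats$dim),
      clinical = clinical, roi_roi = roi_roi,
      p_volume = {
        pv <- array(1, feats$dim)
        pv[feats$voxel_map$voxel] <- sig_map$p
        pv
      },
      model = model, features_provenance = feats$provenance)
  }

  overlap <- overlap_map(directions[[1]]$cluster_labels > 0,
                         directions[[2]]$cluster_labels > 0)
  result <- structure(list(
    directions = directions, overlap = overlap, cohort = cohort,
    config = config, seed_chain = seed_chain
  ), class = "run_result")
  if (!is.null(run_dir)) result$manifest <- write_run(result, run_dir)
  result
}

# Strict-split nuisance regression: betas fitted on the training site,
# applied to both sites with the training intercept retained.
residualize_train_apply <- function(feats, part, tr, te, use) {
  Z <- covariate_matrix(part, use)
  ctr <- colMeans(Z[tr, , drop = FALSE])
  Zc <- sweep(Z, 2, ctr)
  D_tr <- cbind(1, Zc[tr, , drop = FALSE])
  qr_d <- qr(D_tr)
  if (qr_d$rank < ncol(D_tr)) stop("rank-deficient training covariate design")
  beta <- qr.coef(qr_d, feats$X[tr, , drop = FALSE])
  D_all <- cbind(1, Zc)
  fitted <- D_all %*% beta
  feats$X <- feats$X - fitted + rep(beta[1, ], each = nrow(feats$X))
  feats$provenance$residualized <- union(feats$provenance$residualized, use)
  feats
}

#' @export
print.run_result <- function(x, ...) {
  cat("Two-site SVM experiment (seed", x$config$seed, ")\n")
  for (nm in names(x$directions)) {
    d <- x$directions[[nm]]
    cat(sprintf("  %s: C = %g, CV acc %.1f%%, test acc %.1f%%, AUC %.4f, %d clusters\n",
                nm, d$C, 100 * d$cv$accuracy, 100 * d$test$accuracy,
                d$test$auc, length(d$clusters)))
  }
  cat(sprintf("  overlap: %d voxels significant in both models\n",
              sum(x$overlap)))
  invisible(x)
}

# Persist a run: models/, maps/, tables/, logs/ plus manifest.json with
# md5 hashes and the seed chain (no timestamps, so identical configs give
# byte-identical manifests).
write_run <- function(result, run_dir) {
  for (sub in c("models", "maps", "tables", "logs"))
    dir.create(file.path(run_dir, sub), recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  affine <- result$cohort$volumes[[1]]$affine
  dims <- dim(result$cohort$volumes[[1]]$values)
  files <- character(0)
  emit <- function(rel) files <<- c(files, rel)

  write.table(result$cohort$participants,
              file.path(run_dir, "tables", "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emit("tables/participants.tsv")

  for (nm in names(result$directions)) {
    d <- result$directions[[nm]]
    wpath <- file.path(run_dir, "models", paste0(nm, "_w.bin"))
    con <- file(wpath, "wb"); writeBin(d$model$w, con, size = 8); close(con)
    emit(file.path("models", paste0(nm, "_w.bin")))
    jsonlite::write_json(list(
      direction = nm, C = d$C, b = d$model$b,
      n_weights = length(d$model$w),
      cv_accuracy = d$cv$accuracy, test_accuracy = d$test$accuracy,
      test_auc = d$test$auc,
      p_accuracy = d$performance_permutation$p_accuracy,
      p_auc = d$performance_permutation$p_auc,
      B_performance = cfg$B_performance, B_weights = cfg$B_weights,
      q = cfg$q, connectivity = cfg$connectivity,
      sidedness = cfg$sidedness, seed = cfg$seed),
      file.path(run_dir, "models", paste0(nm, "_model.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
    emit(file.path("models", paste0(nm, "_model.json")))

    write_volume(volume_grid(d$p_volume, affine),
                 file.path(run_dir, "maps", paste0(nm, "_p.nii.gz")))
    write_volume(volume_grid(array(as.numeric(d$cluster_labels > 0), dims),
                             affine),
                 file.path(run_dir, "maps", paste0(nm, "_sig.nii.gz")),
                 datatype = "uint8")
    write_volume(volume_grid(array(as.numeric(d$cluster_labels), dims),
                             affine),
                 file.path(run_dir, "maps", paste0(nm, "_clusters.nii.gz")),
                 datatype = "int16")
    emit(file.path("maps", paste0(nm, "_p.nii.gz")))
    emit(file.path("maps", paste0(nm, "_sig.nii.gz")))
    emit(file.path("maps", paste0(nm, "_clusters.nii.gz")))

    write.table(d$cluster_table,
                file.path(run_dir, "tables", paste0(nm, "_clusters.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path("tables", paste0(nm, "_clusters.tsv")))
    if (!is.null(d$clinical)) {
      write.table(d$clinical,
                  file.path(run_dir, "tables", paste0(nm, "_clinical.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      emit(file.path("tables", paste0(nm, "_clinical.tsv")))
    }
  }
  write_volume(volume_grid(array(as.numeric(result$overlap), dims), affine),
               file.path(run_dir, "maps", "overlap.nii.gz"),
               datatype = "uint8")
  emit("maps/overlap.nii.gz")

  hashes <- as.list(tools::md5sum(file.path(run_dir, files)))
  names(hashes) <- files
  manifest <- list(
    config = serializable_config(cfg),
    seed_chain = result$seed_chain,
    artifacts = hashes)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(sprintf("[%s] run complete: %d artifacts",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), length(files)),
             file.path(run_dir, "logs", "run.log"))
  manifest
}

serializable_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$spec)) {
    sp <- unclass(out$spec)
    sp$sites <- lapply(sp$sites, unclass)
    sp$effect_regions <- lapply(sp$effect_regions, function(r) unclass(r))
    out$spec <- sp
  }
  out
}
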