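#' Null distribution of SVM voxel weights under label permutation
#'
#' Retrains the SVM `B` times with permuted class labels at the observed
#' fit's `C` and tallies, per voxel, how often the null weight reaches the
#' observed one (both in magnitude and signed). Tallies are accumulated in
#' streaming fashion so memory stays O(voxels) unless `keep_weights` is
#' set; the identity permutation reproduces the observed weights exactly.
#'
#' @param X training features (matrix or `feature_matrix`).
#' @param y labels in `{-1, +1}`.
#' @param C regularization parameter (fixed across permutations by
#'   default; set `reselect_C` to a grid to re-run CV selection per
#'   permutation).
#' @param B number of permutations.
#' @param seed RNG seed.
#' @param keep_weights if TRUE, also return the B x voxels null weight
#'   matrix (for small problems / cross-checks).
#' @param reselect_C optional C grid for per-permutation re-selection.
#' @return a `weight_null` list: `w_obs`, `count_ge_abs`, `count_ge_signed`,
#'   `B`, `C`, `seed`, and optionally `null_weights`.
#' @export
weight_null <- function(X, y, C = 1, B = 5000, seed = 1,
                        keep_weights = FALSE, reselect_C = NULL) {
  if (B < 1) stop("B must be at least 1")
  Xm <- as_feature_rows(X)
  K <- tcrossprod(Xm)
  obs <- train_linear_svm(Xm, y, C = C, K = K)
  w_obs <- obs$w
  p <- length(w_obs)
  count_abs <- numeric(p)
  count_signed <- numeric(p)
  null_w <- if (keep_weights) matrix(NA_real_, B, p)
  rng <- local_rng(seed)
  for (b in seq_len(B)) {
    yp <- y[rng$sample_perm(length(y))]
    Cb <- if (is.null(reselect_C)) C else
      select_C(Xm, yp, grid = reselect_C, seed = seed + b)$C_best
    fit <- tryCatch(train_linear_svm(Xm, yp, C = Cb, K = K),
                    error = function(e)
                      stop("permutation ", b, " failed: ", conditionMessage(e)))
    wb <- fit$w
    count_abs <- count_abs + (abs(wb) >= abs(w_obs))
    count_signed <- count_signed + (wb >= w_obs)
    if (keep_weights) null_w[b, ] <- wb
  }
  structure(list(w_obs = w_obs, count_ge_abs = count_abs,
                 count_ge_signed = count_signed, B = B, C = C, seed = seed,
                 null_weights = null_w),
            class = "weight_null")
}

#' Per-voxel permutation p-values for SVM weights
#'
#' Default sidedness is two-sided on the weight magnitude:
#' `p_v = max(#\{b : |w_null| >= |w_obs|\}, 1) / B`. The literal one-sided
#' rule (`>=` on signed weights) is selectable; it leaves strongly negative
#' weights non-significant.
#'
#' @param null a `weight_null`.
#' @param sidedness `"two-sided-magnitude"` (default) or
#'   `"one-sided-signed"`.
#' @param q FDR level recorded with the map.
#' @return a `significance_map`: `p` per voxel, `significant` (BH at level
#'   `q`), `B`, `sidedness`, `q`, `w_obs`.
#' @export
voxel_pvalues <- function(null, sidedness = c("two-sided-magnitude",
                                              "one-sided-signed"),
                          q = 0.05) {
  sidedness <- match.arg(sidedness)
  counts <- switch(sidedness,
                   `two-sided-magnitude` = null$count_ge_abs,
                   `one-sided-signed` = null$count_ge_signed)
  p <- pmax(counts, 1) / null$B
  structure(list(p = p, significant = fdr_bh(p, q = q), q = q,
                 B = null$B, sidedness = sidedness, w_obs = null$w_obs),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("significance_map: %d voxels, B = %d, %s; %d significant at FDR q < %g\n",
              length(x$p), x$B, x$sidedness, sum(x$significant), x$q))
  invisible(x)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up rule over one family (all masked voxels / all table cells).
#'
#' @param p p-value vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical vector, TRUE where the hypothesis is rejected.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q & !is.na(p)
}

#' Extract significant clusters by connected components
#'
#' Connected components of the significant voxels under 6-, 18- or
#' 26-connectivity; components with `voxel count <= min_size` are dropped
#' ("more than `min_size` voxels"). Records are sorted by voxel count,
#' ascending.
#'
#' @param sig logical 3D array (or `significance_map` voxel decisions
#'   scattered into the lattice — see [significance_volume()]).
#' @param affine 4x4 voxel-to-world matrix for center-of-gravity output.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_size cluster-extent threshold (default 100; strictly
#'   greater-than).
#' @return list of `cluster_record`s: `index`, `n_voxels`, `cog_mm`,
#'   `voxels` (linear indices), `coords` (n x 3 lattice indices).
#' @export
extract_clusters <- function(sig, affine = diag(4), connectivity = 26,
                             min_size = 100) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  sig <- array(as.logical(sig), dim(sig))
  d <- dim(sig)
  labels <- label_components(sig, connectivity)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  clusters <- list()
  for (id in ids) {
    vox <- which(labels == id)
    if (length(vox) <= min_size) next
    coords <- arrayInd(vox, d)
    cog <- colMeans(voxel_to_world(coords, affine))
    clusters[[length(clusters) + 1]] <- structure(
      list(index = NA_integer_, n_voxels = length(vox),
           cog_mm = cog, voxels = vox, coords = coords),
      class = "cluster_record")
  }
  ord <- order(vapply(clusters, `[[`, 0L, "n_voxels"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$index <- i
  clusters
}

# Connected-component labeling by breadth-first flood over the true voxels.
label_components <- function(sig, connectivity) {
  d <- dim(sig)
  offs <- neighbor_offsets(connectivity)
  labels <- array(0L, d)
  todo <- which(sig)
  nextlab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      for (t in seq_len(nrow(offs))) {
        nb <- cc + offs[t, , drop = FALSE]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (sig[lin] && labels[lin] == 0L) {
          labels[lin] <- nextlab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  colnames(g) <- NULL
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Scatter significance decisions into the lattice
#'
#' @param map a `significance_map`.
#' @param features the `feature_matrix` whose voxel map produced it.
#' @return logical 3D array over the full lattice.
#' @export
significance_volume <- function(map, features) {
  sig <- array(FALSE, features$dim)
  sig[features$voxel_map$voxel] <- map$significant
  sig
}

#' Cluster report table
#'
#' One row per cluster: index, voxel count, center of gravity in world mm
#' (unweighted centroid of member voxel centers through the affine), and
#' the arithmetic mean observed SVM weight over member voxels.
#'
#' @param clusters list of `cluster_record`s from [extract_clusters()].
#' @param w_vol 3D array of observed weights on the lattice (zeros outside
#'   the mask), e.g. from [weight_volume()].
#' @return data.frame with columns `cluster`, `n_voxels`, `cog_x_mm`,
#'   `cog_y_mm`, `cog_z_mm`, `mean_weight`.
#' @export
cluster_table <- function(clusters, w_vol) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), n_voxels = integer(0),
                      cog_x_mm = numeric(0), cog_y_mm = numeric(0),
                      cog_z_mm = numeric(0), mean_weight = numeric(0)))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster = cl$index, n_voxels = cl$n_voxels,
    cog_x_mm = cl$cog_mm[1], cog_y_mm = cl$cog_mm[2], cog_z_mm = cl$cog_mm[3],
    mean_weight = mean(w_vol[cl$voxels]), row.names = NULL)))
}

#' Observed weights on the lattice
#'
#' @param model an `svm_model`.
#' @param features the `feature_matrix` it was trained on.
#' @return 3D array with the voxel weights (0 outside the mask).
#' @export
weight_volume <- function(model, features) {
  w <- array(0, features$dim)
  w[features$voxel_map$voxel] <- model$w
  w
}

#' Cluster label map
#'
#' @param clusters list of `cluster_record`s.
#' @param dim lattice dimensions.
#' @return integer 3D array: cluster index per voxel, 0 elsewhere.
#' @export
cluster_label_map <- function(clusters, dim) {
  lab <- array(0L, dim)
  for (cl in clusters) lab[cl$voxels] <- cl$index
  lab
}

#' Voxelwise overlap of two significance maps
#'
#' @param a,b logical 3D arrays (e.g. two models' significant-cluster maps).
#' @return logical AND array.
#' @export
overlap_map <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a & b
}

#' Dice coefficient between two binary volumes
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return `2|A and B| / (|A| + |B|)`; `NA` when both are empty.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
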