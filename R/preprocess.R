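#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with per-axis sigma
#' `fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size_axis`, so anisotropic voxels
#' are honored through the affine. The boundary is mass-conserving: the
#' kernel is renormalized where it is truncated by the lattice edge
#' (division by the smoothed all-ones volume), which preserves constant
#' volumes exactly. `fwhm_mm = 0` is the identity.
#'
#' @param v a `volume_grid` (or 3D array, taken as unit voxels).
#' @param fwhm_mm full width at half maximum of the kernel, in mm.
#' @return a `volume_grid` with the same affine.
#' @export
smooth_volume <- function(v, fwhm_mm = 8) {
  if (!inherits(v, "volume_grid")) v <- volume_grid(v)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(v)
  ks <- smoothing_kernels(v$affine, fwhm_mm)
  out <- smooth_array(v$values, ks)
  volume_grid(out, affine = v$affine)
}

# Per-axis 1D Gaussian kernels for a given affine and FWHM.
smoothing_kernels <- function(affine, fwhm_mm) {
  vs <- voxel_sizes(affine)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  lapply(sigma_vox, function(s) {
    if (s < 1e-8) return(1)
    h <- max(1L, ceiling(4 * s))
    x <- seq(-h, h)
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  })
}

# Separable zero-padded convolution with edge renormalization.
smooth_array <- function(a, kernels) {
  num <- conv_separable(a, kernels)
  den <- conv_separable(array(1, dim(a)), kernels)
  num / den
}

conv_separable <- function(a, kernels) {
  for (axis in 1:3) a <- conv_axis(a, kernels[[axis]], axis)
  a
}

# Convolve along one axis with zero padding, vectorized over kernel taps.
conv_axis <- function(a, k, axis) {
  if (length(k) == 1) return(a * k)
  d <- dim(a)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  n <- dp[1]
  h <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(k)) {
    off <- t - 1L - h            # source row = dest row + off
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    out[keep, ] <- out[keep, ] + k[t] * m[src[keep], , drop = FALSE]
  }
  res <- array(out, dp)
  aperm(res, order(perm))
}

# Interior SD shrink factor of the smoothing: white noise with unit SD has
# post-smoothing SD equal to prod(sqrt(sum(k^2))) over axes.
smoothing_sd_factor <- function(affine, fwhm_mm) {
  if (fwhm_mm <= 0) return(1)
  prod(vapply(smoothing_kernels(affine, fwhm_mm),
              function(k) sqrt(sum(k^2)), numeric(1)))
}

#' Build the gray-matter analysis mask
#'
#' A voxel enters the mask iff the mean GM density across ALL provided
#' subjects (both sites pooled) is strictly greater than `threshold`.
#'
#' @param volumes list of `volume_grid`s on one common lattice.
#' @param threshold GM density threshold (default 0.2).
#' @return a `mask_volume`: logical lattice + affine + `voxel_count`.
#' @export
build_mask <- function(volumes, threshold = 0.2) {
  if (length(volumes) < 1) stop("at least one volume is required")
  stopifnot_same_grid(volumes)
  mean_vol <- Reduce(`+`, lapply(volumes, `[[`, "values")) / length(volumes)
  keep <- mean_vol > threshold
  structure(list(mask = keep, affine = volumes[[1]]$affine,
                 voxel_count = sum(keep), threshold = threshold),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume %s: %d voxels above %g\n",
              paste(dim(x$mask), collapse = "x"), x$voxel_count, x$threshold))
  invisible(x)
}

#' Assemble the subjects x masked-voxels feature matrix
#'
#' Row i holds subject i's masked voxel values flattened in lattice order
#' with the first (x) index fastest; the voxel map records, per column, the
#' linear voxel index and its (i, j, k) lattice coordinates, making the
#' flattening invertible (see [scatter_row()]).
#'
#' @param volumes named list of `volume_grid`s (names = subject ids).
#' @param mask a `mask_volume`.
#' @param subject_ids row order; defaults to `names(volumes)`.
#' @return a `feature_matrix`: `X`, `subject_ids`, `voxel_map`
#'   (data.frame voxel/i/j/k), `affine`, `dim`, `provenance`.
#' @export
assemble_features <- function(volumes, mask, subject_ids = names(volumes)) {
  if (is.null(subject_ids)) stop("subject ids are required (name the volumes)")
  missing <- setdiff(subject_ids, names(volumes))
  if (length(missing))
    stop("missing volumes for subjects: ", paste(missing, collapse = ", "))
  stopifnot_same_grid(volumes[subject_ids])
  if (!identical(dim(volumes[[subject_ids[1]]]$values), dim(mask$mask)))
    stop("mask shape does not match the volumes")
  idx <- which(mask$mask)                       # column-major: x fastest
  coord <- arrayInd(idx, dim(mask$mask))
  vals <- vapply(subject_ids, function(id) volumes[[id]]$values[idx],
                 numeric(length(idx)))
  X <- if (is.null(dim(vals))) matrix(vals, ncol = 1) else t(vals)
  dimnames(X) <- list(subject_ids, NULL)
  structure(list(
    X = X, subject_ids = subject_ids,
    voxel_map = data.frame(voxel = idx, i = coord[, 1], j = coord[, 2],
                           k = coord[, 3]),
    affine = mask$affine, dim = dim(mask$mask),
    provenance = list(smoothed = NA, residualized = character(0))
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d voxels (lattice %s)\n",
              nrow(x$X), ncol(x$X), paste(x$dim, collapse = "x")))
  if (length(x$provenance$residualized))
    cat("  residualized covariates:",
        paste(x$provenance$residualized, collapse = ", "), "\n")
  invisible(x)
}

#' Scatter one feature row back into a masked volume
#'
#' Inverse of the flattening done by [assemble_features()].
#'
#' @param features a `feature_matrix`.
#' @param row row index or subject id.
#' @param fill value for voxels outside the mask.
#' @return a `volume_grid`.
#' @export
scatter_row <- function(features, row, fill = 0) {
  vals <- array(fill, features$dim)
  vals[features$voxel_map$voxel] <- features$X[row, ]
  volume_grid(vals, affine = features$affine)
}

#' Remove nuisance covariates per site
#'
#' Within each site, every voxel column is regressed by ordinary least
#' squares on an intercept plus the given covariates (centered per site),
#' and replaced by residual + intercept estimate, so the site's mean GM
#' level is retained and densities stay on the [0, 1] GM scale. Sex is
#' encoded 0 = female, 1 = male.
#'
#' @param features a `feature_matrix`.
#' @param covariates data.frame aligned with the feature rows (e.g. the
#'   participants table); must contain every name in `use`.
#' @param groups site label per subject; residualization is fit
#'   independently within each level.
#' @param use covariate names (default `c("age", "sex")`; add `"ICV"` for
#'   the intracranial-volume sensitivity variant).
#' @return a `feature_matrix` with residualized `X`.
#' @export
residualize <- function(features, covariates, groups,
                        use = c("age", "sex")) {
  X <- features$X
  if (nrow(covariates) != nrow(X))
    stop("covariate rows must align with feature rows")
  groups <- as.character(groups)
  Z <- covariate_matrix(covariates, use)
  out <- X
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) <= ncol(Z) + 1)
      stop("site ", g, " has too few subjects (", length(rows),
           ") for ", ncol(Z), " covariates")
    Zg <- scale(Z[rows, , drop = FALSE], center = TRUE, scale = FALSE)
    D <- cbind(intercept = 1, Zg)
    qr_d <- qr(D)
    if (qr_d$rank < ncol(D))
      stop("rank-deficient covariate design in site ", g,
           " (constant or collinear covariate among: ",
           paste(use, collapse = ", "), ")")
    beta <- qr.coef(qr_d, X[rows, , drop = FALSE])
    resid <- X[rows, , drop = FALSE] - D %*% beta
    # covariates are centered, so the intercept is the site voxel mean
    out[rows, ] <- sweep(resid, 2, beta[1, ], `+`)
  }
  features$X <- out
  features$provenance$residualized <-
    union(features$provenance$residualized, use)
  features
}

covariate_matrix <- function(covariates, use) {
  cols <- lapply(use, function(v) {
    if (!v %in% names(covariates)) stop("covariate not found: ", v)
    x <- covariates[[v]]
    if (v == "sex") x <- as.numeric(x %in% c("M", "male", "Male", 1))
    x <- as.numeric(x)
    if (anyNA(x)) stop("covariate ", v, " contains missing values")
    x
  })
  Z <- do.call(cbind, cols)
  colnames(Z) <- use
  Z
}

#' Persist a feature matrix as flat binary plus JSON sidecar
#'
#' The matrix is written row-major as float64 to `<path>.bin`; subject ids,
#' voxel map, lattice dimensions, affine and provenance go to
#' `<path>.json`.
#'
#' @param features a `feature_matrix`.
#' @param path output path stem (no extension).
#' @return the stem, invisibly.
#' @export
save_features <- function(features, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(t(features$X)), con, size = 8)
  close(con)
  jsonlite::write_json(list(
    n_subjects = nrow(features$X), n_voxels = ncol(features$X),
    subject_ids = features$subject_ids,
    voxel_map = features$voxel_map,
    dim = features$dim, affine = features$affine,
    provenance = features$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a feature matrix written by [save_features()]
#'
#' @param path the path stem used when saving.
#' @return a `feature_matrix`.
#' @export
load_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "numeric", n = meta$n_subjects * meta$n_voxels,
                  size = 8)
  close(con)
  structure(list(
    X = matrix(vals, nrow = meta$n_subjects, byrow = TRUE,
               dimnames = list(meta$subject_ids, NULL)),
    subject_ids = meta$subject_ids,
    voxel_map = as.data.frame(meta$voxel_map),
    affine = matrix(unlist(meta$affine), 4, 4),
    dim = as.integer(meta$dim),
    provenance = list(
      smoothed = meta$provenance$smoothed,
      residualized = as.character(meta$provenance$residualized %||%
                                    character(0)))
  ), class = "feature_matrix")
}
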