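#' ROI mean gray matter per subject
#'
#' Entry (i, r) is the arithmetic mean of subject i's (preprocessed) GM
#' over ROI r's voxels.
#'
#' @param volumes named list of `volume_grid`s, or a `feature_matrix`
#'   (ROI means are then taken over the masked voxels it contains).
#' @param clusters list of `cluster_record`s defining the ROIs (or an
#'   integer cluster label map).
#' @return subjects x ROI matrix with ROI indices as column names.
#' @export
roi_mean_gm <- function(volumes, clusters) {
  if (inherits(clusters, "cluster_record")) clusters <- list(clusters)
  if (is.array(clusters)) {
    labs <- setdiff(sort(unique(as.vector(clusters))), 0)
    clusters <- lapply(labs, function(l)
      list(index = l, voxels = which(clusters == l)))
  }
  if (!length(clusters)) stop("no ROIs supplied")
  for (cl in clusters)
    if (!length(cl$voxels)) stop("ROI ", cl$index, " is empty")
  if (inherits(volumes, "feature_matrix")) {
    fm <- volumes
    lut <- integer(prod(fm$dim))
    lut[fm$voxel_map$voxel] <- seq_len(ncol(fm$X))
    out <- vapply(clusters, function(cl) {
      cols <- lut[cl$voxels]
      if (any(cols == 0)) stop("ROI ", cl$index, " leaves the analysis mask")
      rowMeans(fm$X[, cols, drop = FALSE])
    }, numeric(nrow(fm$X)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(fm$X))
    rownames(out) <- fm$subject_ids
  } else {
    stopifnot_same_grid(volumes)
    out <- vapply(clusters, function(cl)
      vapply(volumes, function(v) mean(v$values[cl$voxels]), numeric(1)),
      numeric(length(volumes)))
    if (is.null(dim(out))) out <- matrix(out, nrow = length(volumes))
    rownames(out) <- names(volumes)
  }
  colnames(out) <- vapply(clusters, function(cl) as.character(cl$index), "")
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average (mid-)ranks for ties; pairs with a missing value in either
#' vector are dropped (pairwise deletion). The two-sided p-value uses
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired observations.
#' @return list with `rho`, `p`, `n` (pairs used).
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero variance in a ranked vector; Spearman correlation undefined")
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate ROI gray matter with clinical variables (patients only)
#'
#' All ROI x variable Spearman correlations for one model's ROIs, with
#' pairwise deletion of missing clinical values, uncorrected p flagged at
#' 0.05, and a BH q computed across the full ROI x variable family.
#'
#' @param roi_matrix subjects x ROI matrix from [roi_mean_gm()]; rows must
#'   be the patients to correlate (subset before calling, or pass
#'   `records` with a `diagnosis` column and patients are selected by
#'   subject id).
#' @param records data.frame of subject records containing the clinical
#'   variables (and `subject_id`/`diagnosis` when subsetting is needed).
#' @param variables clinical variable names (default: JART, PANSS
#'   total/positive/negative, onset age, illness duration, CPZ dose).
#' @param q FDR level for the family-wise BH correction.
#' @return data.frame (`correlation_table`): ROI, variable, rho, p, q_bh,
#'   n, sig_uncorrected, sig_fdr. Rows with fewer than 3 usable pairs
#'   carry NA correlations.
#' @export
correlate_rois_clinical <- function(roi_matrix, records,
                                    variables = c("JART", "PANSS_total",
                                                  "PANSS_positive",
                                                  "PANSS_negative",
                                                  "onset_age", "duration",
                                                  "CPZ_mg"),
                                    q = 0.05) {
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars))
    stop("variables absent from records: ", paste(missing_vars, collapse = ", "))
  if ("diagnosis" %in% names(records) && "subject_id" %in% names(records)) {
    pat <- records[records$diagnosis == "patient", , drop = FALSE]
    keep <- intersect(rownames(roi_matrix), pat$subject_id)
    roi_matrix <- roi_matrix[keep, , drop = FALSE]
    records <- pat[match(keep, pat$subject_id), , drop = FALSE]
  }
  if (nrow(roi_matrix) != nrow(records))
    stop("records do not align with the ROI matrix rows")
  rows <- list()
  for (roi in colnames(roi_matrix)) {
    for (v in variables) {
      g <- roi_matrix[, roi]
      cv <- as.numeric(records[[v]])
      n_ok <- sum(is.finite(g) & is.finite(cv))
      res <- if (n_ok >= 3) spearman(g, cv)
             else list(rho = NA_real_, p = NA_real_, n = n_ok)
      rows[[length(rows) + 1]] <- data.frame(
        ROI = roi, variable = v, rho = res$rho, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q_bh <- NA_real_
  ok <- !is.na(tab$p)
  if (any(ok)) tab$q_bh[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  tab$sig_uncorrected <- !is.na(tab$p) & tab$p < 0.05
  tab$sig_fdr <- !is.na(tab$q_bh) & tab$q_bh <= q
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

#' ROI-to-ROI Spearman correlation matrix
#'
#' @param roi_matrix subjects x ROI matrix (>= 2 ROIs).
#' @return symmetric matrix of pairwise Spearman rho with unit diagonal.
#' @export
roi_roi_correlation <- function(roi_matrix) {
  if (ncol(roi_matrix) < 2) stop("at least two ROIs are required")
  k <- ncol(roi_matrix)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(roi_matrix), colnames(roi_matrix))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <- spearman(roi_matrix[, i], roi_matrix[, j])$rho
  }
  out
}

#' Pooled two-sample t test from summary statistics
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df = n1 + n2 - 2`, two-sided `p`.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 observations")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t is infinite")
  }
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df = df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param a,b,c,d cell counts, rows = group, columns = category.
#' @return list with `chi2` and two-sided `p`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all table margins must be positive")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
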