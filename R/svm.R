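#' Train a soft-margin linear SVM
#'
#' Solves the standard L1-loss soft-margin dual by sequential minimal
#' optimization (maximal-violating-pair working set, compiled) to a KKT-gap
#' tolerance of `tol`. Labels follow the convention patient = -1,
#' control = +1; the decision value is `d(x) = w . x + b` and the predicted
#' class is `sign(d)` with ties (`d == 0`) assigned to the patient class.
#'
#' @param X numeric matrix, subjects x features (or a `feature_matrix`).
#' @param y numeric labels in `{-1, +1}`, one per row of `X`.
#' @param C positive soft-margin regularization parameter.
#' @param tol KKT-gap convergence tolerance for the dual solver.
#' @param K optional precomputed Gram matrix `X %*% t(X)`; supplying it lets
#'   permutation refits skip the kernel evaluation.
#' @return An object of class `svm_model` with elements `w` (one weight per
#'   feature), `b`, `C`, `alpha`, `sv_index` (indices with `alpha > 0`),
#'   `objective` (dual objective at the solution) and the label convention.
#' @export
train_linear_svm <- function(X, y, C = 1, tol = 1e-6, K = NULL) {
  X <- as_feature_rows(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 (patient) or +1 (control)")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (!all(is.finite(X))) stop("features must be finite")
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stop("C must be a positive scalar")
  if (is.null(K)) K <- tcrossprod(X)
  fit <- .smo_solve(K, y, C, tol = tol)
  alpha <- fit$alpha
  w <- drop(crossprod(X, alpha * y))
  structure(list(
    w = w, b = fit$b, C = C,
    alpha = alpha, sv_index = which(alpha > 1e-10),
    objective = fit$objective, kkt_gap = fit$kkt_gap,
    converged = fit$converged, n = nrow(X),
    labels = c(patient = -1, control = 1)
  ), class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("Linear SVM: %d features, %d/%d support vectors, C = %g, b = %.4g\n",
              length(x$w), length(x$sv_index), x$n, x$C, x$b))
  invisible(x)
}

#' Decision values of a linear SVM
#'
#' @param model an `svm_model`.
#' @param X test feature matrix with the same columns as the training data.
#' @return numeric vector `X %*% w + b`.
#' @export
decision_values <- function(model, X) {
  X <- as_feature_rows(X)
  if (ncol(X) != length(model$w))
    stop("test features do not match the model's voxel map (",
         ncol(X), " vs ", length(model$w), " columns)")
  drop(X %*% model$w) + model$b
}

#' Predicted class labels
#'
#' Ties (`decision == 0`) go to the patient class (-1).
#' @inheritParams decision_values
#' @return vector of -1/+1 labels.
#' @export
predict_labels <- function(model, X) {
  d <- decision_values(model, X)
  ifelse(d > 0, 1, -1)
}

#' Stratified cross-validation folds
#'
#' Assigns each subject to one of `k` folds so that per-fold class
#' proportions differ from the global proportions by at most one subject.
#'
#' @param y labels in `{-1, +1}`.
#' @param k number of folds.
#' @param seed RNG seed for the within-class shuffle.
#' @return integer fold id per subject.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  if (k > min(table(y))) stop("k exceeds the size of the smallest class; use a smaller k")
  fold <- integer(length(y))
  rng <- local_rng(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[rng$sample_perm(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the SVM regularization parameter by stratified k-fold CV
#'
#' Accuracy is pooled over held-out folds for each candidate `C`; the best
#' `C` is the accuracy argmax with ties broken toward the smallest value
#' (strongest regularization).
#'
#' @param X feature matrix.
#' @param y labels in `{-1, +1}`.
#' @param grid candidate `C` values; default `2^(-10:10)`.
#' @param k folds (default 10).
#' @param seed seed for fold assignment.
#' @return list with `C_best`, `cv_accuracy` (named per grid value), `folds`.
#' @export
select_C <- function(X, y, grid = 2^(-10:10), k = 10, seed = 1) {
  X <- as_feature_rows(X)
  if (length(grid) == 0) stop("C grid must be non-empty")
  grid <- sort(as.numeric(grid))
  fold <- stratified_folds(y, k = k, seed = seed)
  K <- tcrossprod(X)
  acc <- vapply(grid, function(C) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      model <- train_linear_svm(X[tr, , drop = FALSE], y[tr], C = C,
                                K = K[tr, tr, drop = FALSE])
      pred <- predict_labels(model, X[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  names(acc) <- format(grid, trim = TRUE)
  list(C_best = grid[which.max(acc)], cv_accuracy = acc, folds = fold)
}

#' Cross-validated performance at a fixed C
#'
#' Pools held-out decision values and predictions over stratified folds and
#' scores them as one test set (the conventional non-nested CV report).
#'
#' @inheritParams select_C
#' @param C regularization parameter to use in every fold.
#' @return a `performance_report` (see [evaluate()]).
#' @export
cv_performance <- function(X, y, C, k = 10, seed = 1) {
  X <- as_feature_rows(X)
  fold <- stratified_folds(y, k = k, seed = seed)
  K <- tcrossprod(X)
  d <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_linear_svm(X[tr, , drop = FALSE], y[tr], C = C,
                              K = K[tr, tr, drop = FALSE])
    d[!tr] <- decision_values(model, X[!tr, , drop = FALSE])
  }
  performance_from_decisions(d, y)
}

#' Performance metrics from decision values
#'
#' The patient class (-1) is the positive class: sensitivity is the patient
#' recall, specificity the control recall. The AUC treats `-decision` as the
#' risk score (higher risk means patient) and counts concordant pairs with
#' half-credit for ties. Undefined ratios (zero denominators) are `NA`.
#'
#' @param d decision values `w . x + b`.
#' @param y true labels in `{-1, +1}`.
#' @return a `performance_report` list: confusion counts, accuracy,
#'   sensitivity, specificity, ppv, npv, auc, n per group.
#' @export
performance_from_decisions <- function(d, y) {
  pred <- ifelse(d > 0, 1, -1)
  rep <- confusion_metrics(
    tp = sum(pred == -1 & y == -1), fn = sum(pred == 1 & y == -1),
    tn = sum(pred == 1 & y == 1),  fp = sum(pred == -1 & y == 1))
  rep$auc <- auc_rank(-d, y == -1)
  rep$decision_values <- d
  rep
}

#' Metrics from a confusion matrix
#'
#' @param tp,fn,tn,fp confusion counts with patient as the positive class.
#' @return a `performance_report` list (without AUC).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    n_patients = tp + fn, n_controls = tn + fp,
    accuracy = rate(tp + tn, tp + fn + tn + fp),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    auc = NA_real_
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf(
    "n = %d patients / %d controls\naccuracy %s  sensitivity %s  specificity %s\nPPV %s  NPV %s  AUC %s\n",
    x$n_patients, x$n_controls, pct(x$accuracy), pct(x$sensitivity),
    pct(x$specificity), pct(x$ppv), pct(x$npv),
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Rank-based AUC
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half (midrank formula).
#'
#' @param score risk scores, higher = more positive-like.
#' @param positive logical, TRUE for the positive class.
#' @return AUC in `[0, 1]`, `NA` if either class is empty.
#' @export
auc_rank <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Reconstruct confusion counts from printed rates
#'
#' Inverts a published (sensitivity, specificity, group size) summary into
#' integer confusion counts by rounding `sensitivity * n_patients` and
#' `specificity * n_controls` to the nearest integer, so that accuracy, PPV
#' and NPV can be recomputed from a performance table alone.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_patients,n_controls group sizes.
#' @return a `performance_report` from [confusion_metrics()].
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_patients, n_controls) {
  tp <- round(sensitivity * n_patients)
  tn <- round(specificity * n_controls)
  confusion_metrics(tp = tp, fn = n_patients - tp, tn = tn, fp = n_controls - tn)
}

#' Evaluate a trained SVM on a test set
#'
#' @param model an `svm_model`.
#' @param X_test,y_test test features and true labels.
#' @return a `performance_report` including AUC from decision values.
#' @export
evaluate <- function(model, X_test, y_test) {
  performance_from_decisions(decision_values(model, X_test), y_test)
}

#' Permutation p-values for test-set performance
#'
#' For each of `B` iterations the *training* labels are permuted, the SVM is
#' retrained at the observed fit's `C`, and the permuted model is scored on
#' the unpermuted test set. The p-value for each statistic is
#' `max(#\{null >= observed\}, 1) / B`, floored at `1/B` (so with B = 5000
#' the smallest reportable p is 2e-4).
#'
#' @param X_train,y_train training data.
#' @param X_test,y_test test data (never permuted).
#' @param C regularization parameter (fixed across permutations).
#' @param B number of permutations.
#' @param seed RNG seed.
#' @param permute_test if TRUE, permute test labels of a single fit instead
#'   of retraining on permuted training labels.
#' @return list with `p_accuracy`, `p_auc`, `observed` (a
#'   `performance_report`), and the null statistic vectors.
#' @export
permutation_test_performance <- function(X_train, y_train, X_test, y_test,
                                         C = 1, B = 5000, seed = 1,
                                         permute_test = FALSE) {
  if (B < 1) stop("B must be at least 1")
  X_train <- as_feature_rows(X_train)
  X_test <- as_feature_rows(X_test)
  model <- train_linear_svm(X_train, y_train, C = C)
  obs <- evaluate(model, X_test, y_test)
  rng <- local_rng(seed)
  null_acc <- numeric(B); null_auc <- numeric(B)
  K <- if (!permute_test) tcrossprod(X_train)
  for (b in seq_len(B)) {
    if (permute_test) {
      yp <- y_test[rng$sample_perm(length(y_test))]
      rep_b <- performance_from_decisions(obs$decision_values, yp)
    } else {
      yp <- y_train[rng$sample_perm(length(y_train))]
      mb <- train_linear_svm(X_train, yp, C = C, K = K)
      rep_b <- evaluate(mb, X_test, y_test)
    }
    null_acc[b] <- rep_b$accuracy
    null_auc[b] <- rep_b$auc
  }
  list(
    p_accuracy = permutation_p(obs$accuracy, null_acc),
    p_auc = permutation_p(obs$auc, null_auc),
    observed = obs, null_accuracy = null_acc, null_auc = null_auc,
    B = B, scheme = if (permute_test) "test-labels" else "train-labels")
}

#' Count-based permutation p-value with a 1/B floor
#'
#' @param observed observed statistic.
#' @param null vector of null statistics (length B).
#' @return `max(#\{null >= observed\}, 1) / B`.
#' @export
permutation_p <- function(observed, null) {
  B <- length(null)
  max(sum(null >= observed, na.rm = TRUE), 1) / B
}

# Accept plain matrices or feature_matrix objects everywhere features flow.
as_feature_rows <- function(X) {
  if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
}

#' Persist a trained SVM as flat binary weights plus JSON sidecar
#'
#' @param model an `svm_model`.
#' @param path output path stem (no extension).
#' @return the stem, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(model$w), con, size = 8)
  close(con)
  jsonlite::write_json(list(
    n_weights = length(model$w), b = model$b, C = model$C,
    n_train = model$n, objective = model$objective,
    labels = as.list(model$labels)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SVM written by [save_model()]
#'
#' Only the decision rule (w, b, C) is restored; dual coefficients are not
#' persisted.
#'
#' @param path the path stem used when saving.
#' @return an `svm_model` usable with [decision_values()] and [evaluate()].
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  w <- readBin(con, "numeric", n = meta$n_weights, size = 8)
  close(con)
  structure(list(w = w, b = meta$b, C = meta$C, alpha = NULL,
                 sv_index = integer(0), objective = meta$objective,
                 kkt_gap = NA_real_, converged = NA, n = meta$n_train,
                 labels = c(patient = -1, control = 1)),
            class = "svm_model")
}
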