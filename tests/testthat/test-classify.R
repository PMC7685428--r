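test_that("maximal-margin geometry and sign symmetry hold exactly", {
  X <- matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE)
  y <- c(-1, 1)
  fit <- train_linear_svm(X, y, C = 1e6, tol = 1e-10)
  expect_equal(fit$w, c(1, 0), tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_equal(decision_values(fit, X), c(-1, 1), tolerance = 1e-8)

  set.seed(10)
  Xr <- matrix(rnorm(30), 10, 3)
  yr <- rep(c(-1, 1), 5)
  f1 <- train_linear_svm(Xr, yr, C = 2)
  f2 <- train_linear_svm(Xr, -yr, C = 2)
  expect_equal(f1$w, -f2$w, tolerance = 1e-6)
  expect_equal(f1$b, -f2$b, tolerance = 1e-6)
})

test_that("the SMO solution satisfies the dual constraints and KKT gap", {
  set.seed(11)
  for (C in c(0.1, 1, 10)) {
    X <- matrix(rnorm(60), 20, 3)
    y <- rep(c(-1, 1), 10)
    X[y == 1, 1] <- X[y == 1, 1] + 1
    fit <- train_linear_svm(X, y, C = C)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= C + 1e-12))
    expect_lt(abs(sum(fit$alpha * y)), 1e-8)
    expect_lt(fit$kkt_gap, 1e-6)
    # dual-primal consistency: w = sum_i alpha_i y_i x_i
    expect_lt(max(abs(fit$w - drop(crossprod(X, fit$alpha * y)))), 1e-6)
  }
})

test_that("the solver agrees with independent QP and SVM implementations", {
  skip_if_not_installed("kernlab")
  skip_if_not_installed("e1071")
  set.seed(12)
  for (C in c(0.1, 1, 5)) {
    n <- 12
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rep(c(-1, 1), each = n / 2)
    X[y == 1, 1] <- X[y == 1, 1] + 1.5
    fit <- train_linear_svm(X, y, C = C, tol = 1e-8)

    # brute-force quadratic program on the dual
    K <- tcrossprod(X)
    Q <- (y %o% y) * K
    qp <- kernlab::ipop(c = rep(-1, n), H = Q + diag(1e-10, n),
                        A = matrix(y, 1), b = 0, r = 0,
                        l = rep(0, n), u = rep(C, n), sigf = 12)
    a <- kernlab::primal(qp)
    obj_qp <- sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
    expect_lt(abs(fit$objective - obj_qp), 1e-5)

    # reference SVM decision values
    ref <- e1071::svm(X, factor(y, levels = c(-1, 1)), scale = FALSE,
                      kernel = "linear", cost = C, tolerance = 1e-8)
    d_ref <- drop(attr(predict(ref, X, decision.values = TRUE),
                       "decision.values"))
    d_fit <- decision_values(fit, X)
    if (cor(d_ref, d_fit) < 0) d_ref <- -d_ref
    expect_lt(max(abs(d_fit - d_ref)), 1e-4)
  }
})

test_that("C selection uses properly stratified folds and sane tie-breaks", {
  set.seed(13)
  n <- 40
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2)
  X[y == 1, ] <- X[y == 1, ] + 4   # well separated

  sel1 <- select_C(X, y, grid = 0.5, k = 5, seed = 1)
  expect_equal(sel1$C_best, 0.5)

  sel <- select_C(X, y, grid = 2^(0:6), k = 5, seed = 1)
  expect_true(all(sel$cv_accuracy == 1))
  expect_equal(sel$C_best, 1)      # ties -> smallest C

  # exhaustive stratification audit
  folds <- stratified_folds(y, k = 5, seed = 2)
  for (f in 1:5) for (cls in c(-1, 1)) {
    expect_lt(abs(sum(y[folds == f] == cls) - (n / 2) / 5), 1.01)
  }
  expect_error(stratified_folds(c(-1, -1, 1), k = 2), "smaller k")
  expect_error(select_C(X, y, grid = numeric(0)), "non-empty")
})

test_that("performance metrics reproduce a published confusion layout", {
  # counts reconstructed from sensitivity 64.0% / specificity 82.3% at
  # n = 50/51 give the full printed metric column
  rep <- confusion_metrics(tp = 32, fn = 18, tn = 42, fp = 9)
  expect_equal(round(100 * rep$accuracy, 1), 73.3)
  expect_equal(round(100 * rep$sensitivity, 1), 64.0)
  expect_equal(round(100 * rep$specificity, 1), 82.4)
  expect_equal(round(100 * rep$ppv, 1), 78.0)
  expect_equal(round(100 * rep$npv, 1), 70.0)
})

test_that("metric identities hold for random confusion tables", {
  set.seed(14)
  for (i in 1:25) {
    cnt <- rpois(4, 20)
    rep <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(rep$tp + rep$fn, rep$n_patients)
    expect_equal(rep$tn + rep$fp, rep$n_controls)
    tot <- sum(cnt)
    if (tot > 0)
      expect_equal(rep$accuracy, (cnt[1] + cnt[3]) / tot)
    for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      v <- rep[[m]]
      expect_true(is.na(v) || (v >= 0 && v <= 1))
    }
  }
  # zero denominators are reported as missing, not zero
  rep0 <- confusion_metrics(tp = 0, fn = 0, tn = 5, fp = 3)
  expect_true(is.na(rep0$sensitivity))
})

test_that("AUC equals exhaustive pair counting, with half-credit ties", {
  d <- c(0.3, -0.2, 0.1, 0.1, -0.5, 0.4)       # decision values
  y <- c(-1, -1, -1, 1, 1, 1)
  risk <- -d
  pos <- y == -1
  # brute-force pair count
  conc <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  }
  expect_equal(auc_rank(risk, pos), conc / (sum(pos) * sum(!pos)))

  rep <- performance_from_decisions(d, y)
  expect_equal(rep$auc, conc / 9)

  perfect <- performance_from_decisions(c(-2, -1, 1, 2), c(-1, -1, 1, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  # ties at the decision boundary go to the patient class
  expect_equal(ifelse(0 > 0, 1, -1), -1)
  tie <- performance_from_decisions(c(0, 1), c(-1, 1))
  expect_equal(tie$tp, 1)
})

test_that("permutation p-values follow the floored counting rule", {
  expect_equal(permutation_p(0.9, rep(0.5, 20)), 1 / 20)
  expect_equal(permutation_p(0.1, rep(0.5, 20)), 1)
  expect_equal(permutation_p(0.5, rep(0.5, 20)), 1)     # >= is inclusive
  # with B = 5000 the smallest reportable p is 2e-4
  expect_equal(permutation_p(1, rep(0, 5000)), 2e-4)
})

test_that("performance permutation nulls live on the exhaustively enumerable support", {
  X_tr <- matrix(c(-1, -0.9, 1, 0.9, -1.1, 0.8, 1.2, -0.8), 4, 2)
  y_tr <- c(-1, -1, 1, 1)
  X_te <- matrix(c(-1, 1, -0.5, 0.6, 0.9, -1, 0.4, -0.6), 4, 2)
  y_te <- c(-1, 1, -1, 1)

  # oracle: accuracy under every one of the 4! training-label permutations
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  support <- sort(unique(apply(perms, 1, function(pr) {
    yp <- y_tr[pr]
    if (length(unique(yp)) < 2) return(NA_real_)
    m <- train_linear_svm(X_tr, yp, C = 10)
    evaluate(m, X_te, y_te)$accuracy
  })))

  res <- permutation_test_performance(X_tr, y_tr, X_te, y_te, C = 10,
                                      B = 24, seed = 3)
  expect_true(all(res$null_accuracy %in% support))
  # counting rule against a manual count on the same sampled null
  expect_equal(res$p_accuracy,
               max(sum(res$null_accuracy >= res$observed$accuracy), 1) / 24)
  expect_gte(res$p_accuracy, 1 / 24)
})

test_that("degenerate label and argument combinations are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_linear_svm(X, rep(1, 10)), "both classes")
  expect_error(train_linear_svm(X, rep(c(-1, 1), 5), C = -1), "positive")
  expect_error(train_linear_svm(X, rep(c(0, 1), 5)), "-1")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(train_linear_svm(Xb, rep(c(-1, 1), 5)), "finite")
  expect_error(permutation_test_performance(X, rep(c(-1, 1), 5), X,
                                            rep(c(-1, 1), 5), B = 0),
               "at least 1")
})
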