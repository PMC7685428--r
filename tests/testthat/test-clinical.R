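test_that("ROI means equal naive per-voxel averages", {
  vols <- list(s1 = const_volume(0.37), s2 = const_volume(0.62))
  cl <- list(list(index = 1, voxels = 1:10), list(index = 2, voxels = 50:60))
  m <- roi_mean_gm(vols, cl)
  expect_true(all(abs(m["s1", ] - 0.37) < 1e-12))
  expect_true(all(abs(m["s2", ] - 0.62) < 1e-12))

  v <- const_volume(0)
  v$values[1] <- 0.4; v$values[2] <- 0.6
  expect_equal(unname(roi_mean_gm(list(a = v),
                                  list(list(index = 1, voxels = 1:2)))[1, 1]),
               0.5)

  set.seed(30)
  vr <- volume_grid(array(runif(8^3), c(8, 8, 8)))
  vox <- sample(8^3, 30)
  got <- roi_mean_gm(list(a = vr), list(list(index = 1, voxels = vox)))[1, 1]
  acc <- 0
  for (x in vox) acc <- acc + vr$values[x]
  expect_lt(abs(got - acc / 30), 1e-12)

  expect_error(roi_mean_gm(list(a = vr),
                           list(list(index = 1, voxels = integer(0)))),
               "empty")
})

test_that("Spearman correlation handles monotonicity, ties and missing pairs", {
  x <- 1:10
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, exp(-x))$rho, -1)

  # n = 6 with one tie: manual midrank oracle
  xs <- c(1, 2, 3, 4, 5, 6)
  ys <- c(2.0, 1.0, 3.0, 3.0, 5.0, 6.0)
  rx <- c(1, 2, 3, 4, 5, 6)
  ry <- c(2, 1, 3.5, 3.5, 5, 6)
  rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman(xs, ys)
  expect_equal(res$rho, rho_manual)
  t_manual <- rho_manual * sqrt((6 - 2) / (1 - rho_manual^2))
  expect_equal(res$p, 2 * pt(-abs(t_manual), 4))
  expect_equal(res$rho,
               unname(cor.test(xs, ys, method = "spearman",
                               exact = FALSE)$estimate))

  # pairwise deletion
  res_na <- spearman(c(xs, NA, 7), c(ys, 1, NA))
  expect_equal(res_na$n, 6)
  expect_equal(res_na$rho, res$rho)

  expect_error(spearman(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(spearman(1:2, 2:1)$rho))   # n < 3 -> NA
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(31)
  maps <- list(function(z) z, function(z) exp(z), function(z) z^3,
               function(z) atan(z), function(z) -1 / (1 + exp(-z)))
  for (i in 1:5) {
    x <- rnorm(25); y <- 0.5 * x + rnorm(25)
    base <- spearman(x, y)$rho
    f <- maps[[sample(5, 1)]]; g <- maps[[sample(5, 1)]]
    expect_equal(spearman(f(x), g(y))$rho, sign(f(2) - f(1)) *
                   sign(g(2) - g(1)) * base, tolerance = 1e-12)
  }
})

test_that("ROI-clinical tables use patients only, flag and correct coherently", {
  coh <- tiny_cohort()
  parts <- coh$participants
  # truth-region ROIs on the raw volumes
  tpl <- gmsvm:::template_parts(coh$spec)
  rois <- lapply(seq_along(coh$spec$effect_regions), function(r) {
    prof <- gmsvm:::region_profile(coh$spec$effect_regions[[r]], tpl$axes)
    list(index = r, voxels = which(prof > 0))
  })
  roi <- roi_mean_gm(coh$volumes, rois)
  tab <- correlate_rois_clinical(roi, parts)

  expect_s3_class(tab, "correlation_table")
  expect_equal(nrow(tab), 2 * 7)
  expect_true(all(tab$n <= sum(parts$diagnosis == "patient")))
  expect_true(all(abs(tab$rho) <= 1, na.rm = TRUE))
  expect_true(all(tab$q_bh >= tab$p - 1e-12, na.rm = TRUE))
  # BH never flags more cells than the uncorrected 0.05 rule
  expect_lte(sum(tab$sig_fdr), sum(tab$sig_uncorrected))

  # all-missing variable gives NA rows, not an error
  parts2 <- parts
  parts2$JART <- NA_real_
  tab2 <- correlate_rois_clinical(roi, parts2)
  expect_true(all(is.na(tab2$rho[tab2$variable == "JART"])))

  expect_error(correlate_rois_clinical(roi, parts, variables = "EDU_YRS"),
               "absent")
})

test_that("null clinical scores produce ~5% uncorrected flags", {
  set.seed(32)
  n_pat <- 40; n_roi <- 8; n_var <- 7
  roi <- matrix(rnorm(n_pat * n_roi), n_pat, n_roi,
                dimnames = list(sprintf("P%02d", 1:n_pat), 1:n_roi))
  rec <- data.frame(matrix(rnorm(n_pat * n_var), n_pat, n_var))
  names(rec) <- c("JART", "PANSS_total", "PANSS_positive", "PANSS_negative",
                  "onset_age", "duration", "CPZ_mg")
  tab <- correlate_rois_clinical(roi, rec)
  frac <- mean(tab$sig_uncorrected)
  expect_lt(frac, 0.05 + 2.5 * sqrt(0.05 * 0.95 / nrow(tab)))
})

test_that("ROI-ROI correlation matrices are symmetric with unit diagonal", {
  set.seed(33)
  roi <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("1", "2", "3")))
  m <- roi_roi_correlation(roi)
  expect_equal(diag(m), c(`1` = 1, `2` = 1, `3` = 1))
  expect_equal(m, t(m))
  # all-pairs brute force
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(m[i, j], spearman(roi[, i], roi[, j])$rho)

  dup <- cbind(roi[, 1], roi[, 1])
  colnames(dup) <- c("a", "b")
  expect_equal(roi_roi_correlation(dup)["a", "b"], 1)
  expect_error(roi_roi_correlation(roi[, 1, drop = FALSE]), "at least two")
})

test_that("summary-statistic t tests reproduce printed demographics", {
  # within-site age contrast at n = 49/48: |t| = 1.39 on 95 df
  res <- t_from_summary(28.1, 5.0, 49, 26.9, 3.3, 48)
  expect_equal(res$df, 95)
  expect_equal(round(abs(res$t), 2), 1.39)
  expect_equal(round(res$p, 2), 0.17)

  # between-site illness duration contrast: |t| = 6.87
  res2 <- t_from_summary(14.7, 8.2, 50, 5.4, 4.8, 49)
  expect_equal(round(abs(res2$t), 2), 6.87)
  expect_lt(res2$p, 1e-8)

  res0 <- t_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(t_from_summary(1, 0, 5, 2, 0, 5), "infinite")
})

test_that("summary t equals the raw-data pooled t on exact sample moments", {
  set.seed(34)
  for (i in 1:5) {
    a <- rnorm(12, 1, 2); b <- rnorm(17, 0, 2)
    ref <- t.test(a, b, var.equal = TRUE)
    got <- t_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 17)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("2x2 chi-square matches the definition and printed sex contrast", {
  # sex counts 23/26 vs 23/25: chi-square ~ 0.009
  res <- chi2_2x2(23, 26, 23, 25)
  expect_equal(round(res$chi2, 3), 0.009)
  expect_equal(round(res$p, 2), 0.92)

  expect_equal(chi2_2x2(10, 10, 10, 10)$chi2, 0)

  set.seed(35)
  for (i in 1:5) {
    cnt <- rpois(4, 15) + 1
    got <- chi2_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    # sum((O - E)^2 / E) computed cell by cell
    tab <- matrix(cnt, 2, byrow = TRUE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$chi2, sum((tab - E)^2 / E), tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
  }
  expect_error(chi2_2x2(0, 0, 3, 4), "margins")
  expect_error(chi2_2x2(1.5, 2, 3, 4), "integers")
})
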