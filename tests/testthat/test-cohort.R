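test_that("template is deterministic, brain-like, and mask-compatible", {
  spec <- tiny_spec(seed = 3)
  t1 <- generate_template(spec)
  t2 <- generate_template(spec)
  expect_identical(t1$values, t2$values)
  t3 <- generate_template(tiny_spec(seed = 4))
  expect_false(identical(t1$values, t3$values))

  v <- t1$values
  d <- dim(v)
  faces <- c(v[1, , ], v[d[1], , ], v[, 1, ], v[, d[2], ], v[, , 1],
             v[, , d[3]])
  expect_lt(max(faces), 0.2)

  # direct scan of the lattice: above-threshold voxels sit in [0.3, 0.8]
  interior <- v[v > 0.2]
  expect_gt(length(interior), 100)
  expect_gt(mean(interior), 0.3)
  expect_lt(mean(interior), 0.8)

  expect_error(cohort_spec(grid_shape = c(6, 16, 16)), "at least 8")
})

test_that("cohort generation is deterministic and mirrors the two-site design", {
  spec <- tiny_spec(n_pat = 4, n_con = 5, seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$volumes[[3]]$values, c2$volumes[[3]]$values)

  # default design: 50/51 and 49/48 -> 101 and 97 participants
  def <- cohort_spec()
  ns <- vapply(def$sites, function(s) s$n_patients + s$n_controls, 0)
  expect_equal(unname(ns), c(101, 97))
  counts <- table(tiny_cohort()$participants$site)
  expect_equal(unname(as.vector(counts)), c(24, 24))
})

test_that("disease effect size at region cores matches the requested Cohen's d", {
  # full-size site (n = 50/51) so the sampling error of d is small when
  # averaged over seeds; brute-force d from the generated sample
  ds <- vapply(1:4, function(s) {
    coh <- generate_cohort(tiny_spec(n_pat = 50, n_con = 51,
                                     effect_d = 1.2, seed = 100 + s))
    core_cohens_d(coh, "siteA", region = 1)
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1.2), 0.25)
})

test_that("null cohorts have no group difference at region cores", {
  for (s in 1:3) {
    coh <- generate_cohort(tiny_spec(n_pat = 20, n_con = 20,
                                     effect_d = 0, seed = 200 + s))
    parts <- coh$participants
    tpl <- gmsvm:::template_parts(coh$spec)
    prof <- gmsvm:::region_profile(coh$spec$effect_regions[[1]], tpl$axes)
    core <- which(prof >= 0.999)
    pat <- parts$subject_id[parts$diagnosis == "patient" & parts$site == "siteA"]
    con <- parts$subject_id[parts$diagnosis == "control" & parts$site == "siteA"]
    gp <- vapply(coh$volumes[pat], function(v) mean(v$values[core]), 0)
    gc <- vapply(coh$volumes[con], function(v) mean(v$values[core]), 0)
    expect_gt(t.test(gp, gc)$p.value, 0.005)
  }
})

test_that("expected core group difference increases strictly with effect_d", {
  d_values <- c(0.3, 0.8, 1.3)
  mean_diff <- sapply(d_values, function(d) {
    mean(vapply(1:20, function(s) {
      coh <- generate_cohort(tiny_spec(n_pat = 8, n_con = 8, effect_d = d,
                                       seed = 300 + s))
      parts <- coh$participants
      tpl <- gmsvm:::template_parts(coh$spec)
      prof <- gmsvm:::region_profile(coh$spec$effect_regions[[1]], tpl$axes)
      core <- which(prof >= 0.999)
      pat <- parts$subject_id[parts$diagnosis == "patient"]
      con <- parts$subject_id[parts$diagnosis == "control"]
      mean(vapply(coh$volumes[con], function(v) mean(v$values[core]), 0)) -
        mean(vapply(coh$volumes[pat], function(v) mean(v$values[core]), 0))
    }, numeric(1)))
  })
  expect_true(all(diff(mean_diff) > 0))
})

test_that("site intensity offset is recovered in the voxel-mean difference", {
  shift <- 0.02
  spec <- cohort_spec(
    grid_shape = rep(16, 3),
    sites = list(site_spec("siteA", 10, 10, 35, 5, 35, 5),
                 site_spec("siteB", 10, 10, 35, 5, 35, 5,
                           site_intensity_shift = shift)),
    age_slope = 0, sex_effect = 0, effect_d = 0,
    effect_regions = list(effect_region(c(0, 0, 0), 8, 0)),
    seed = 42)
  coh <- generate_cohort(spec)
  parts <- coh$participants
  m <- vapply(coh$volumes, function(v) mean(v$values), 0)
  a <- m[parts$site == "siteA"]; b <- m[parts$site == "siteB"]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(b) - mean(a)) - shift), 3 * se)
})

test_that("clipping is rare under default-style parameters", {
  expect_lt(tiny_cohort()$clipped_fraction, 0.01)
  coh24 <- generate_cohort(cohort_spec(grid_shape = rep(24, 3), seed = 5))
  expect_lt(coh24$clipped_fraction, 0.01)
})

test_that("clinical records honor the patient-only and consistency invariants", {
  parts <- tiny_cohort()$participants
  pat <- parts[parts$diagnosis == "patient", ]
  con <- parts[parts$diagnosis == "control", ]

  expect_true(all(is.na(con$PANSS_total)))
  expect_true(all(is.na(con$CPZ_mg)))
  expect_true(all(is.na(con$onset_age)))
  expect_true(all(!is.na(con$JART)))    # premorbid IQ measured in controls

  expect_true(all(pat$PANSS_total >= pat$PANSS_positive))
  expect_true(all(pat$PANSS_total >= pat$PANSS_negative))
  expect_true(all(abs(pat$duration - (pat$age - pat$onset_age)) < 0.051))
  expect_true(all(pat$onset_age < pat$age))
})

test_that("unattainable or malformed clinical links are rejected", {
  expect_error(effect_region(c(0, 0, 0), 8, 1,
                             clinical_link = list(variable = "CPZ_mg",
                                                  rho = 0.995)),
               "unattainable")
  expect_error(effect_region(c(0, 0, 0), 8, 1,
                             clinical_link = list(variable = "handedness",
                                                  rho = 0.3)),
               "must be one of")
  spec <- tiny_spec()
  spec$effect_regions[[1]]$clinical_link <-
    list(variable = "CPZ_mg", rho = -0.3)   # CPZ already linked to region 2
  expect_error(generate_cohort(spec), "linked to more than one region")
})

test_that("a cohort round-trips through the on-disk layout", {
  coh <- generate_cohort(tiny_spec(n_pat = 3, n_con = 2, seed = 9, grid = 8))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "cohort_spec.json")))
  back <- read_cohort(dir)
  expect_equal(back$participants$subject_id, coh$participants$subject_id)
  id <- coh$participants$subject_id[1]
  expect_lt(max(abs(back$volumes[[id]]$values - coh$volumes[[id]]$values)),
            1e-6)
  expect_equal(back$truth$values > 0, coh$truth$values > 0)
  unlink(dir, recursive = TRUE)
})
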