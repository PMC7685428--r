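#' Deterministic baseline gray-matter template
#'
#' A smooth synthetic "brain": an ellipsoidal support at 80% of the field
#' of view holding a base density of 0.55 plus low-frequency random bumps
#' (seed-dependent, amplitude 0.06), apodized by the generator's intrinsic
#' smoothing. Interior values land in roughly \[0.3, 0.8\] and the
#' background stays near 0, so a 0.2 density threshold separates brain
#' from background.
#'
#' @param spec a [cohort_spec()].
#' @return a `volume_grid`.
#' @export
generate_template <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- template_parts(spec)
  tpl$template
}

# Template + support envelope + world coordinate grid, shared between
# generate_template() and generate_cohort().
template_parts <- function(spec) {
  d <- spec$grid_shape
  affine <- centered_affine(d, spec$voxel_size_mm)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1 - (d[a] - 1) / 2) *
                 spec$voxel_size_mm[a])
  semi <- 0.8 * (d - 1) / 2 * spec$voxel_size_mm
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, `+`),
              (ax[[3]] / semi[3])^2, `+`)
  support <- (r2 <= 1) * 1
  fwhm <- max(spec$smoothness_mm, 1e-8)
  kern <- smoothing_kernels(affine, fwhm)
  envelope <- smooth_array(support, kern)

  # low-frequency bumps: seed-dependent coarse field, heavily smoothed
  bumps <- with_seed(spec$seed, {
    raw <- array(rnorm(prod(d)), d)
    sm <- smooth_array(raw, smoothing_kernels(affine, 2 * fwhm))
    sm / max(sd(sm), 1e-12) * 0.06
  })
  vals <- pmin(pmax((0.55 + bumps) * envelope, 0), 1)
  list(template = volume_grid(vals, affine = affine),
       envelope = envelope, axes = ax, affine = affine)
}

# Ellipsoid profile of one effect region: 1 on the inner half-radius
# ("core"), smooth quadratic falloff to 0 at the boundary.
region_profile <- function(region, axes) {
  r2 <- outer(outer(((axes[[1]] - region$center_mm[1]) / region$radii_mm[1])^2,
                    ((axes[[2]] - region$center_mm[2]) / region$radii_mm[2])^2,
                    `+`),
              ((axes[[3]] - region$center_mm[3]) / region$radii_mm[3])^2, `+`)
  pmin(pmax((1 - r2) / 0.75, 0), 1)   # == 1 for r <= radius/2
}

# Analytic within-group voxel SD at a region core for one site: smoothed
# noise plus age-slope and sex-effect variance components.
site_within_sd <- function(spec, site, affine) {
  noise_pre <- sqrt(spec$subject_noise_sd^2 + site$site_noise_sd^2)
  noise_post <- noise_pre * smoothing_sd_factor(affine, spec$smoothness_mm)
  age_sd <- sqrt((site$age_sd_patients^2 + site$age_sd_controls^2) / 2)
  sqrt(noise_post^2 + (spec$age_slope * age_sd)^2 + spec$sex_effect^2 / 4)
}

#' Generate a synthetic two-site cohort
#'
#' Each subject's volume is
#' `template + site shift + age slope * (age - reference age) + sex effect
#'  + patient region reduction + smoothed noise`, with the age, sex and
#' noise terms apodized by the brain envelope and the result clipped to
#' \[0, 1\]. The patient reduction at a region core is
#' `effect_d * sd_within(site)` with `sd_within` the analytic within-group
#' voxel SD of that site, so the core Cohen's d matches `effect_d`.
#' Regions with a `clinical_link` couple the linked score to the region's
#' mean GM via a latent Gaussian with Pearson correlation
#' `2 sin(pi rho / 6)`, the bivariate-normal value that yields the target
#' Spearman rho.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort` list: `participants` (data.frame), `volumes` (named
#'   list of `volume_grid`), `truth` (0/1 `volume_grid` over all effect
#'   regions), `template`, `spec`, `clipped_fraction`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- template_parts(spec)
  affine <- tpl$affine
  d <- spec$grid_shape
  noise_kern <- smoothing_kernels(affine, max(spec$smoothness_mm, 0))

  profiles <- lapply(spec$effect_regions, region_profile, axes = tpl$axes)
  truth <- array(0, d)
  for (p in profiles) truth[p > 0] <- 1

  rng <- local_rng(spec$seed)
  stage_seeds <- rng$draw_seeds(3)

  participants <- with_seed(stage_seeds[1], draw_demographics(spec))
  age_ref <- mean(participants$age)

  n <- nrow(participants)
  volumes <- vector("list", n)
  names(volumes) <- participants$subject_id
  clipped <- 0
  noise_rng <- local_rng(stage_seeds[2])
  region_gm <- matrix(NA_real_, n, length(profiles))
  for (i in seq_len(n)) {
    site <- spec$sites[[participants$site[i]]]
    sd_pre <- sqrt(spec$subject_noise_sd^2 + site$site_noise_sd^2)
    noise <- array(noise_rng$rnorm(prod(d), sd = sd_pre), d)
    if (spec$smoothness_mm > 0) noise <- smooth_array(noise, noise_kern)
    vals <- tpl$template$values + site$site_intensity_shift +
      (spec$age_slope * (participants$age[i] - age_ref) +
         spec$sex_effect * (participants$sex[i] == "M")) * tpl$envelope +
      noise * tpl$envelope
    if (participants$diagnosis[i] == "patient") {
      sd_w <- site_within_sd(spec, site, affine)
      for (r in seq_along(profiles))
        vals <- vals - spec$effect_regions[[r]]$effect_d * sd_w * profiles[[r]]
    }
    clip <- pmin(pmax(vals, 0), 1)
    clipped <- clipped + sum(clip != vals)
    volumes[[i]] <- volume_grid(clip, affine = affine)
    for (r in seq_along(profiles)) {
      memb <- profiles[[r]] > 0
      region_gm[i, r] <- mean(clip[memb])
    }
  }

  participants <- with_seed(stage_seeds[3],
                            draw_clinical(spec, participants, region_gm))

  structure(list(
    participants = participants, volumes = volumes,
    truth = volume_grid(truth, affine = affine),
    template = tpl$template, spec = spec,
    clipped_fraction = clipped / (n * prod(d))
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$participants$site, x$participants$diagnosis)
  cat(sprintf("synthetic cohort: %d subjects, grid %s, seed %d\n",
              nrow(x$participants), paste(dim(x$truth$values), collapse = "x"),
              x$spec$seed))
  print(tab)
  invisible(x)
}

draw_demographics <- function(spec) {
  rows <- list()
  for (s in spec$sites) {
    for (grp in c("patient", "control")) {
      ng <- if (grp == "patient") s$n_patients else s$n_controls
      if (ng == 0) next
      mu <- if (grp == "patient") s$age_mean_patients else s$age_mean_controls
      sg <- if (grp == "patient") s$age_sd_patients else s$age_sd_controls
      age <- round(pmax(rnorm(ng, mu, sg), 18), 1)
      sex <- ifelse(runif(ng) < 0.5, "M", "F")
      icv <- round(rnorm(ng, ifelse(sex == "M", 1550, 1400), 110), 1)
      pre <- if (grp == "patient") "P" else "C"
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("%s-%s%03d", s$name, pre, seq_len(ng)),
        site = s$name, diagnosis = grp, age = age, sex = sex, ICV = icv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  for (k in seq_len(50)) {
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  pmin(pmax(x, lower), upper)
}

# Clinical scores. Patients get PANSS / onset / duration / CPZ; controls
# carry NA for those but do receive a JART estimate (it is measured in
# controls too). Linked variables are generated from the region GM.
draw_clinical <- function(spec, participants, region_gm) {
  n <- nrow(participants)
  vars <- c("PANSS_total", "PANSS_positive", "PANSS_negative",
            "onset_age", "duration", "CPZ_mg", "JART")
  for (v in vars) participants[[v]] <- NA_real_

  links <- list()
  for (r in seq_along(spec$effect_regions)) {
    cl <- spec$effect_regions[[r]]$clinical_link
    if (!is.null(cl)) {
      if (!is.null(links[[cl$variable]]))
        stop("variable ", cl$variable, " is linked to more than one region")
      links[[cl$variable]] <- list(region = r, rho = cl$rho)
    }
  }

  draw_var <- function(idx, site, variable) {
    mu_sd <- switch(variable,
      CPZ_mg = c(site$cpz_mean, site$cpz_sd, 0, Inf),
      JART = c(site$jart_mean_patients, site$jart_sd_patients, 60, 140),
      onset_age = c(site$onset_mean, site$onset_sd, 10, Inf),
      PANSS_positive = c(site$panss_pos_mean, site$panss_pos_sd, 7, 49),
      PANSS_negative = c(site$panss_neg_mean, site$panss_neg_sd, 7, 49),
      PANSS_general = c(site$panss_gen_mean, site$panss_gen_sd, 16, 112),
      stop("no distribution for ", variable))
    link <- links[[variable]]
    if (is.null(link))
      return(rtrunc_norm(length(idx), mu_sd[1], mu_sd[2], mu_sd[3], mu_sd[4]))
    # latent Pearson r giving the target Spearman rho for a bivariate normal
    r_lat <- 2 * sin(pi * link$rho / 6)
    g <- region_gm[idx, link$region]
    z <- (g - mean(g)) / max(sd(g), 1e-12)
    latent <- r_lat * z + sqrt(1 - r_lat^2) * rnorm(length(idx))
    pmin(pmax(mu_sd[1] + mu_sd[2] * latent, mu_sd[3]), mu_sd[4])
  }

  for (sname in names(spec$sites)) {
    site <- spec$sites[[sname]]
    pat <- which(participants$site == sname & participants$diagnosis == "patient")
    con <- which(participants$site == sname & participants$diagnosis == "control")
    if (length(pat)) {
      onset <- draw_var(pat, site, "onset_age")
      onset <- pmin(onset, participants$age[pat] - 1)
      participants$onset_age[pat] <- round(onset, 1)
      participants$duration[pat] <-
        round(participants$age[pat] - participants$onset_age[pat], 1)
      participants$CPZ_mg[pat] <- round(draw_var(pat, site, "CPZ_mg"), 1)
      participants$JART[pat] <- round(draw_var(pat, site, "JART"), 1)
      pos <- round(draw_var(pat, site, "PANSS_positive"))
      neg <- round(draw_var(pat, site, "PANSS_negative"))
      gen <- round(draw_var(pat, site, "PANSS_general"))
      participants$PANSS_positive[pat] <- pos
      participants$PANSS_negative[pat] <- neg
      participants$PANSS_total[pat] <- pos + neg + gen
    }
    if (length(con)) {
      participants$JART[con] <- round(rtrunc_norm(
        length(con), site$jart_mean_controls, site$jart_sd_controls, 60, 140), 1)
    }
  }
  participants
}

#' Write a cohort to disk
#'
#' One NIfTI volume per subject named `<site>_<subject_id>.nii.gz`, a
#' `participants.tsv`, the ground-truth effect mask as NIfTI, and the spec
#' echoed to a JSON sidecar.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$participants
  for (i in seq_len(nrow(p))) {
    fn <- file.path(dir, sprintf("%s_%s.nii.gz", p$site[i], p$subject_id[i]))
    write_volume(cohort$volumes[[p$subject_id[i]]], fn)
  }
  write.table(p, file.path(dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_volume(cohort$truth, file.path(dir, "truth_mask.nii.gz"),
               datatype = "uint8")
  spec_json <- cohort$spec
  spec_json$sites <- lapply(spec_json$sites, unclass)
  spec_json$effect_regions <- lapply(spec_json$effect_regions, unclass)
  jsonlite::write_json(unclass(spec_json), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `participants`, `volumes`, `truth`.
#' @export
read_cohort <- function(dir) {
  p <- read.delim(file.path(dir, "participants.tsv"),
                  stringsAsFactors = FALSE)
  vols <- lapply(seq_len(nrow(p)), function(i)
    read_volume(file.path(dir, sprintf("%s_%s.nii.gz", p$site[i],
                                       p$subject_id[i]))))
  names(vols) <- p$subject_id
  truth_path <- file.path(dir, "truth_mask.nii.gz")
  truth <- if (file.exists(truth_path)) read_volume(truth_path)
  list(participants = p, volumes = vols, truth = truth)
}
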