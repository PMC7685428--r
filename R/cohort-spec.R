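#' Define a disease effect region for the cohort generator
#'
#' An ellipsoidal region in world (mm) coordinates where patients have
#' reduced gray matter density. `effect_d >= 0` means patients have LOWER
#' GM at the region core (the sign convention is fixed: larger `effect_d`
#' means more atrophy). The spatial profile is 1 on the inner half of the
#' ellipsoid (the "core") and falls smoothly to 0 at the boundary.
#'
#' @param center_mm length-3 world coordinates of the region center.
#' @param radii_mm length-1 or length-3 ellipsoid semi-axes (mm), > 0.
#' @param effect_d Cohen's d of the patient-vs-control reduction at the
#'   region core, relative to the within-group voxel SD.
#' @param clinical_link optional `list(variable = <name>, rho = <target>)`
#'   coupling the region's mean GM (patients) to a clinical score with the
#'   given population Spearman correlation, `|rho| < 0.99`.
#' @return an `effect_region`.
#' @export
effect_region <- function(center_mm, radii_mm, effect_d,
                          clinical_link = NULL) {
  radii_mm <- rep_len(as.numeric(radii_mm), 3)
  if (any(radii_mm <= 0)) stop("radii_mm must be positive")
  if (!is.numeric(effect_d) || effect_d < 0)
    stop("effect_d must be >= 0 (patients-lower sign convention)")
  if (!is.null(clinical_link)) {
    if (!is.list(clinical_link) || is.null(clinical_link$variable) ||
        is.null(clinical_link$rho))
      stop("clinical_link must be list(variable=, rho=)")
    if (abs(clinical_link$rho) >= 0.99)
      stop("clinical_link target |rho| >= 0.99 is unattainable given score noise and discretization")
    linkable <- c("CPZ_mg", "JART", "onset_age", "PANSS_total",
                  "PANSS_positive", "PANSS_negative")
    if (!clinical_link$variable %in% linkable)
      stop("clinical_link variable must be one of: ",
           paste(linkable, collapse = ", "))
  }
  structure(list(center_mm = as.numeric(center_mm)[1:3], radii_mm = radii_mm,
                 effect_d = effect_d, clinical_link = clinical_link),
            class = "effect_region")
}

#' Define one imaging site of a synthetic cohort
#'
#' @param name site label used in subject ids and the participants table.
#' @param n_patients,n_controls group sizes (>= 0).
#' @param age_mean_patients,age_sd_patients,age_mean_controls,age_sd_controls
#'   age distributions (years).
#' @param site_intensity_shift additive GM-density offset for every volume
#'   from this site (scanner effect).
#' @param site_noise_sd extra per-voxel noise SD (pre-smoothing)
#'   contributed by this site's scanner, added in quadrature to the
#'   subject-level noise.
#' @param onset_mean,onset_sd illness onset age distribution (patients).
#' @param cpz_mean,cpz_sd chlorpromazine-equivalent dose (mg, patients).
#' @param jart_mean_patients,jart_sd_patients,jart_mean_controls,jart_sd_controls
#'   estimated-IQ (JART) distributions.
#' @param panss_pos_mean,panss_pos_sd,panss_neg_mean,panss_neg_sd,panss_gen_mean,panss_gen_sd
#'   PANSS positive / negative / general subscale distributions; the total
#'   is their sum.
#' @return a `site_spec`.
#' @export
site_spec <- function(name, n_patients, n_controls,
                      age_mean_patients, age_sd_patients,
                      age_mean_controls, age_sd_controls,
                      site_intensity_shift = 0, site_noise_sd = 0,
                      onset_mean = 23, onset_sd = 6,
                      cpz_mean = 500, cpz_sd = 400,
                      jart_mean_patients = 100, jart_sd_patients = 10,
                      jart_mean_controls = 109, jart_sd_controls = 6,
                      panss_pos_mean = 15, panss_pos_sd = 6,
                      panss_neg_mean = 17, panss_neg_sd = 7,
                      panss_gen_mean = 34, panss_gen_sd = 12) {
  if (n_patients < 0 || n_controls < 0) stop("group sizes must be >= 0")
  structure(as.list(environment()), class = "site_spec")
}

#' Full parameterization of a synthetic two-site cohort
#'
#' The defaults mirror the study design the pipeline targets: two sites of
#' 50/51 and 49/48 patients/controls with distinct age distributions
#' (site A ~ 38.8/36.5 years, site B ~ 28.1/26.9 years), clinical score
#' distributions taken from the corresponding demographic table, a mild
#' scanner intensity offset between sites, smooth age- and sex-related GM
#' variation, and two ellipsoidal disease-effect regions, one coupled to
#' antipsychotic dose.
#'
#' @param grid_shape lattice dimensions, each >= 8 (default 32^3).
#' @param voxel_size_mm voxel edge length in mm (> 0), length 1 or 3.
#' @param sites list of two or more [site_spec()] blocks.
#' @param age_slope GM density change per year of age (negative = atrophy).
#' @param sex_effect additive GM offset for male subjects.
#' @param subject_noise_sd per-voxel Gaussian noise SD before smoothing.
#' @param effect_regions list of [effect_region()] objects.
#' @param smoothness_mm FWHM (mm) of the generator's intrinsic smoothing,
#'   applied to the noise field so images have realistic spatial
#'   autocorrelation.
#' @param effect_d optional convenience override: if supplied, replaces
#'   `effect_d` in every effect region (0 gives a global-null cohort).
#' @param seed RNG seed recorded in all outputs.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(32L, 32L, 32L),
                        voxel_size_mm = 4,
                        sites = default_sites(),
                        age_slope = -0.0015,
                        sex_effect = 0.01,
                        subject_noise_sd = 0.4,
                        effect_regions = default_effect_regions(),
                        smoothness_mm = 8,
                        effect_d = NULL,
                        seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3))
  if (any(grid_shape < 8)) stop("grid_shape must be at least 8 voxels per axis")
  if (any(rep_len(voxel_size_mm, 3) <= 0)) stop("voxel_size_mm must be positive")
  if (subject_noise_sd < 0) stop("subject_noise_sd must be >= 0")
  if (smoothness_mm < 0) stop("smoothness_mm must be >= 0")
  stopifnot(length(sites) >= 2, all(vapply(sites, inherits, TRUE, "site_spec")))
  if (!is.null(effect_d))
    effect_regions <- lapply(effect_regions, function(r) { r$effect_d <- effect_d; r })
  stopifnot(all(vapply(effect_regions, inherits, TRUE, "effect_region")))
  names(sites) <- vapply(sites, `[[`, "", "name")
  structure(list(
    grid_shape = grid_shape, voxel_size_mm = rep_len(voxel_size_mm, 3),
    sites = sites, age_slope = age_slope, sex_effect = sex_effect,
    subject_noise_sd = subject_noise_sd, effect_regions = effect_regions,
    smoothness_mm = smoothness_mm, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default two-site design
#'
#' Site A: 50 patients / 51 controls, ages ~ 38.8 (6.9) / 36.5 (7.1);
#' site B: 49 patients / 48 controls, ages ~ 28.1 (5.0) / 26.9 (3.3),
#' with a +0.01 GM intensity offset and slightly noisier scanner at site B.
#'
#' @return list of two [site_spec()] objects named "siteA" and "siteB".
#' @export
default_sites <- function() {
  list(
    site_spec("siteA", 50, 51, 38.8, 6.9, 36.5, 7.1,
              site_intensity_shift = 0, site_noise_sd = 0,
              onset_mean = 24.1, onset_sd = 6.4,
              cpz_mean = 584.4, cpz_sd = 406.6,
              jart_mean_patients = 98.9, jart_sd_patients = 10.2,
              jart_mean_controls = 108.0, jart_sd_controls = 6.4,
              panss_pos_mean = 16.0, panss_pos_sd = 6.3,
              panss_neg_mean = 16.9, panss_neg_sd = 6.8,
              panss_gen_mean = 34.4, panss_gen_sd = 12),
    site_spec("siteB", 49, 48, 28.1, 5.0, 26.9, 3.3,
              site_intensity_shift = 0.005, site_noise_sd = 0.1,
              onset_mean = 22.5, onset_sd = 5.1,
              cpz_mean = 441.9, cpz_sd = 416.7,
              jart_mean_patients = 101.6, jart_sd_patients = 10.2,
              jart_mean_controls = 111.0, jart_sd_controls = 5.9,
              panss_pos_mean = 13.4, panss_pos_sd = 5.8,
              panss_neg_mean = 18.2, panss_neg_sd = 7.9,
              panss_gen_mean = 33.0, panss_gen_sd = 12))
}

#' Default disease-effect regions
#'
#' Two ellipsoids inside the synthetic brain: a frontal-midline-like region
#' (effect d = 1.2) and a deeper lateral region (d = 1.2) whose mean GM is
#' negatively coupled to antipsychotic dose (Spearman rho = -0.35).
#'
#' @param effect_d Cohen's d used for both regions.
#' @return list of [effect_region()] objects.
#' @export
default_effect_regions <- function(effect_d = 1.2) {
  list(
    effect_region(center_mm = c(0, 22, 10), radii_mm = c(16, 14, 14),
                  effect_d = effect_d),
    effect_region(center_mm = c(-18, -14, -6), radii_mm = c(13, 13, 13),
                  effect_d = effect_d,
                  clinical_link = list(variable = "CPZ_mg", rho = -0.35)))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: grid %s @ %s mm, seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"), x$seed))
  for (s in x$sites)
    cat(sprintf("  %s: %d patients / %d controls, shift %+.3g, noise sd %.3g\n",
                s$name, s$n_patients, s$n_controls,
                s$site_intensity_shift, s$site_noise_sd))
  cat(sprintf("  %d effect region(s), age slope %g/yr, sex effect %g, noise sd %g, FWHM %g mm\n",
              length(x$effect_regions), x$age_slope, x$sex_effect,
              x$subject_noise_sd, x$smoothness_mm))
  invisible(x)
}
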