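# Shared fixtures, all generated in code at test time.

# A small cohort spec whose effect regions fit inside the 16^3 brain
# support (semi-axes 0.8 * 30 mm = 24 mm).
tiny_spec <- function(n_pat = 12, n_con = 12, effect_d = 1.2, seed = 1,
                      grid = 16, rho_link = -0.5, ...) {
  cohort_spec(
    grid_shape = rep(grid, 3), voxel_size_mm = 4,
    sites = list(
      site_spec("siteA", n_pat, n_con, 38.8, 6.9, 36.5, 7.1),
      site_spec("siteB", n_pat, n_con, 28.1, 5.0, 26.9, 3.3,
                site_intensity_shift = 0.005, site_noise_sd = 0.1)),
    effect_regions = list(
      effect_region(c(0, 7, 5), radii_mm = 9, effect_d = effect_d),
      effect_region(c(-8, -7, -4), radii_mm = 8, effect_d = effect_d,
                    clinical_link = list(variable = "CPZ_mg",
                                         rho = rho_link))),
    seed = seed, ...)
}

# Memoized tiny cohort reused across test files.
.fixture_env <- new.env()
tiny_cohort <- function() {
  if (is.null(.fixture_env$coh))
    .fixture_env$coh <- generate_cohort(tiny_spec(seed = 7))
  .fixture_env$coh
}

# Uniform-valued volume helper.
const_volume <- function(value, d = c(8, 8, 8), voxel = 1) {
  volume_grid(array(value, d), voxel_size_mm = voxel)
}

# Hand-rolled step-up FDR oracle (independent of fdr_bh).
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= q * i / m) k <- i
  sig <- rep(FALSE, m)
  if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  sig
}

# Recursive flood-fill component labeling oracle.
floodfill_oracle <- function(sig, connectivity) {
  d <- dim(sig)
  offs <- expand.grid(-1:1, -1:1, -1:1)
  nz <- rowSums(abs(offs))
  offs <- as.matrix(offs[switch(as.character(connectivity),
                                "6" = nz == 1,
                                "18" = nz >= 1 & nz <= 2,
                                "26" = nz >= 1), ])
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(sig)) {
    if (lab[v]) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      s <- stack[1]; stack <- stack[-1]
      if (lab[s]) next
      lab[s] <- cur
      cc <- arrayInd(s, d)
      for (t in seq_len(nrow(offs))) {
        nb <- cc + offs[t, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (sig[lin] && !lab[lin]) stack <- c(stack, lin)
      }
    }
  }
  lab
}

# Per-voxel Cohen's d at region-core voxels, computed directly from the
# generated sample (brute-force group mean / pooled SD).
core_cohens_d <- function(coh, site, region = 1) {
  spec <- coh$spec
  parts <- coh$participants
  tpl <- gmsvm:::template_parts(spec)
  prof <- gmsvm:::region_profile(spec$effect_regions[[region]], tpl$axes)
  core <- which(prof >= 0.999)
  pat <- parts$subject_id[parts$site == site & parts$diagnosis == "patient"]
  con <- parts$subject_id[parts$site == site & parts$diagnosis == "control"]
  Gp <- t(vapply(coh$volumes[pat], function(v) v$values[core],
                 numeric(length(core))))
  Gc <- t(vapply(coh$volumes[con], function(v) v$values[core],
                 numeric(length(core))))
  mean(vapply(seq_along(core), function(j) {
    sp <- sqrt(((nrow(Gp) - 1) * var(Gp[, j]) +
                  (nrow(Gc) - 1) * var(Gc[, j])) /
                 (nrow(Gp) + nrow(Gc) - 2))
    (mean(Gc[, j]) - mean(Gp[, j])) / sp
  }, numeric(1)))
}
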