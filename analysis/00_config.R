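# Shared settings for the analysis scripts. The cohort emulates the
# two-site study design (sites of 50/51 and 49/48 patients/controls with
# distinct age distributions and a mild scanner offset) on a desk-scale
# 32^3 lattice of 4 mm voxels. Permutation depths are set so the
# Benjamini-Hochberg step over the ~9000-voxel mask can resolve
# discoveries (the p floor 1/B must be able to clear q * k / m).
library(gmsvm)

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
PREP_DIR <- file.path(RESULTS, "preprocess")
CLS_DIR <- file.path(RESULTS, "classify")
MAP_DIR <- file.path(RESULTS, "maps")
CLIN_DIR <- file.path(RESULTS, "clinical")

MASTER_SEED <- 20260926L
SPEC <- cohort_spec(grid_shape = c(32L, 32L, 32L), seed = MASTER_SEED)
FWHM_MM <- 8
MASK_THRESHOLD <- 0.2
C_GRID <- 2^(-10:10)
FOLDS <- 10
B_PERFORMANCE <- 1000
B_WEIGHTS <- 2000
FDR_Q <- 0.05
# Cluster-extent threshold. The reference scale for "more than 100 voxels"
# is a ~1.5 mm VBM lattice (~340 mm^3); at this 4 mm desk lattice the same
# volume is ~5 voxels, so 20 voxels (1280 mm^3) is already conservative.
MIN_CLUSTER <- 20
CONNECTIVITY <- 26

site_names <- names(SPEC$sites)
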