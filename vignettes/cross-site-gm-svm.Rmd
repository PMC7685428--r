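---
title: "Cross-site SVM classification of gray matter maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-site SVM classification of gray matter maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmsvm)
```

# The analysis

`gmsvm` implements a multivariate pattern analysis of structural MRI for a
two-site case-control design. The inputs are per-subject 3D gray-matter
(GM) density volumes, already segmented and normalized to a common space,
plus a participants table with site, diagnosis, age, sex and clinical
scores. The pipeline is:

1. **Smoothing.** Each volume is convolved with an isotropic Gaussian of
   8 mm full width at half maximum (FWHM), with per-axis
   $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ in voxel units taken from
   the affine, so anisotropic voxels are handled correctly.
2. **Masking.** A voxel enters the analysis mask iff the mean smoothed GM
   density across *all* subjects of *both* sites is strictly greater than
   0.2. Masking limits the feature dimension to brain tissue.
3. **Nuisance regression.** Within each site separately, every voxel is
   regressed on age and sex (ordinary least squares) and replaced by
   residual + fitted intercept. Covariates are centered per site, so the
   retained intercept is the site's voxel mean and densities stay on the
   interpretable [0, 1] GM scale. Arbitrary extra covariates (e.g.
   intracranial volume) can be added.
4. **Classification.** A soft-margin linear SVM with labels $-1$ (patient)
   and $+1$ (control) is trained on one site and tested on the other, in
   both directions. The regularization parameter $C$ is chosen by
   stratified ten-fold cross-validation over a log$_2$ grid
   ($2^{-10} \dots 2^{10}$ by default), with accuracy ties broken toward
   the smaller (more regularized) $C$. Performance is reported as
   accuracy, sensitivity, specificity, PPV, NPV (patient = positive
   class) and a rank-based AUC of the decision values, with permutation
   p-values obtained by retraining on label-permuted training data.
5. **Weight-map inference.** The linear SVM's weight vector assigns each
   voxel a contribution to the decision. Retraining the SVM $B$ times on
   permuted labels (fixed $C$) yields a per-voxel null distribution of
   weights; the voxel p-value is the fraction of null weights at least as
   extreme as the observed one, floored at $1/B$. Voxels surviving
   Benjamini–Hochberg FDR at $q < 0.05$ are grouped into connected
   components (26-connectivity), components above a cluster-extent
   threshold are reported with voxel count, center of gravity in mm and
   mean weight, and the two models' maps are intersected into an overlap
   map.
6. **Clinical correlation.** For each surviving cluster, the mean
   preprocessed GM per subject is correlated (Spearman, mid-ranks for
   ties, t-approximation p-values) with the patients' clinical scores
   (premorbid IQ, PANSS total/positive/negative, onset age, illness
   duration, antipsychotic dose), per model/site, with pairwise deletion
   of missing values, uncorrected flags at 0.05 and a BH-corrected q over
   the full ROI-by-variable family. ROI–ROI Spearman matrices and
   summary-statistic demographic tests (pooled two-sample t from means
   and SDs; 2x2 Pearson chi-square without continuity correction) round
   out the reporting.

## The SVM solver

The dual problem
$$\min_\alpha \tfrac12 \alpha^\top Q \alpha - e^\top \alpha,
  \quad 0 \le \alpha_i \le C,\; y^\top \alpha = 0,
  \quad Q_{ij} = y_i y_j x_i^\top x_j$$
is solved by sequential minimal optimization with maximal-violating-pair
working-set selection, implemented in compiled code. Convergence is
declared when the KKT gap $m(\alpha) - M(\alpha)$ falls below $10^{-6}$
(configurable). The bias is the KKT-stationarity average over free
support vectors, falling back to the midpoint of the feasible interval
when every coefficient is at a bound. Because only the $n \times n$ Gram
matrix enters the solver, the permutation loops reuse one kernel
evaluation; a label permutation costs well under a millisecond at
$n \approx 100$. The test suite cross-checks the solver against an
interior-point quadratic program (`kernlab::ipop`, objective agreement to
$10^{-5}$) and a reference SVM (`e1071::svm`, decision values to
$10^{-4}$); neither is a runtime dependency.

A practical regime worth knowing: when $C$ is very small every $\alpha_i$
sits at its bound and $w \propto \sum_i y_i x_i$, the group-mean
difference. That regime gives powerful, stable weight maps but has no
free support vectors, so the bias is only interval-identified and
cross-site classification can collapse to one class. CV-selected $C$
(typically $2^{-5}$–$2^{-4}$ on the synthetic cohorts) avoids both
extremes, which is why the pipeline always selects $C$ rather than fixing
it.

# The synthetic cohort generator

No imaging data are distributed, so the package ships a generator whose
defaults *are* the study conditions the pipeline targets:

* **Design.** Two sites: 50 patients / 51 controls with ages
  38.8 (6.9) / 36.5 (7.1) years, and 49 / 48 with 28.1 (5.0) / 26.9 (3.3)
  years. Clinical scores (PANSS subscales, onset age, CPZ-equivalent
  dose, JART IQ) are drawn from the corresponding per-site summary
  distributions; PANSS total is the sum of its subscales, duration equals
  age minus onset, and patient-only variables are missing for controls.
* **Template.** A deterministic, seed-dependent "brain": an ellipsoid at
  80% of the field of view holding density 0.55 plus low-frequency random
  bumps (SD 0.06), apodized by the generator's intrinsic smoothing so the
  0.2 mask threshold cleanly separates brain from background.
* **Subject effects.** GM = template + site intensity shift + age slope
  $\times$ (age − cohort mean age) + sex offset + patient region
  reduction + smoothed noise, clipped to [0, 1]. Age, sex and noise terms
  are multiplied by the brain envelope (no tissue outside the head).
  Noise is white Gaussian (SD 0.4 before smoothing) convolved at the same
  8 mm FWHM as the imaging smoothness, giving realistic spatial
  autocorrelation — permutation inference behaves very differently on
  white noise. The resulting within-group voxel SD is about 0.08.
* **Disease effect.** Ellipsoidal regions in which patients lose GM; the
  loss at the region core is `effect_d` times the site's analytic
  within-group SD (smoothed noise plus age- and sex-variance terms), so
  the core Cohen's d equals `effect_d` by construction; the profile is 1
  on the inner half-radius and falls quadratically to 0 at the boundary.
  Defaults: two regions with d = 1.2. The union of the regions is
  returned as a ground-truth mask for localization checks.
* **Clinical coupling.** A region may be linked to one clinical variable
  with a target Spearman $\rho$: the score is a linear function of the
  standardized regional GM plus independent Gaussian noise with latent
  Pearson correlation $2\sin(\pi\rho/6)$ — the bivariate-normal value
  whose Spearman correlation is $\rho$ — then mapped to the score's
  per-site mean/SD and truncated to its valid range. Targets with
  $|\rho| \ge 0.99$ are rejected as unattainable under score
  discretization. The default links the second region to CPZ dose at
  $\rho = -0.35$.
* **Site effects.** Site B carries a +0.005 bulk density offset and extra
  scanner noise (SD 0.1 pre-smoothing, added in quadrature). These values
  are deliberately modest: with the ten-year between-site age gap of the
  design, the age slope (−0.0015 density/year) already produces a ~0.015
  bulk offset between sites, and substantially larger offsets make the
  transferred decision threshold — not the weight direction — fail,
  which contradicts the ~72% cross-site accuracy regime this analysis
  emulates. Modulated GM densities from matched 3 T scanners differ
  mostly in noise and smoothness, not bulk level.

What the generator does **not** emulate: T1 acquisition, segmentation and
registration error, skull/CSF/white-matter compartments, regionally
heterogeneous aging, site-dependent smoothness, non-Gaussian score
distributions, or diffuse whole-brain disease effects outside the
configured regions. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and calibrated under controlled
conditions, not that the classifier would attain any particular accuracy
on real cohorts.

# Numerical and design choices

* **Mask rule.** Strictly greater than threshold; boundary equality is
  excluded. The mask and the nuisance regression pool both sites before
  the train/test split, replicating the analysis as described — a mild
  information leak. A `strict_split` mode fits the mask and regression on
  the training site only and applies them to the test site, for
  methodological comparison.
* **Smoothing boundary.** Zero-padded convolution renormalized by the
  smoothed all-ones volume: constants are preserved exactly and GM totals
  near the brain edge are not deflated. Order of operations: smooth
  first, then build the mask from the smoothed means.
* **Weight-test sidedness.** The literal one-sided rule ("proportion of
  null weights greater than or equal to the observed") would leave large
  *negative* weights non-significant even though reported significant
  regions carry positive mean weights only; the default is therefore
  two-sided on $|w|$, with the literal signed rule selectable. This is a
  deliberate, documented divergence.
* **Null granularity.** Each voxel is compared to its own permutation
  null (per-voxel null), not to a pooled or max-statistic null; tallies
  are streamed so memory is O(voxels), not O(voxels × B).
* **p floor and BH arithmetic.** All permutation p-values are
  `max(count, 1)/B`, so the smallest reportable p is $1/B$ (2e-4 at the
  fidelity default B = 5000). This interacts with FDR: the BH step-up can
  only reject $k$ voxels if $1/B \le q k / m$, i.e. at $m$ mask voxels at
  least $m / (qB)$ voxels must reach the floor. Desk-scale runs must pick
  B accordingly (e.g. B = 200 over an ~3500-voxel mask can *never*
  produce a discovery at q = 0.05); the analysis scripts use B = 2000 on
  the 32³ lattice and the test suites B = 1000 on 24³.
* **Cluster extent.** "More than 100 voxels" is resolution-relative: 100
  voxels on a ~1.5 mm VBM lattice is ~340 mm³, which is ~5 voxels at the
  4 mm desk resolution. The package default keeps 100 (fidelity); the
  desk-scale scripts and suites use 20 voxels (1280 mm³), still
  conservative in mm³. Connectivity defaults to 26 (vertex-sharing),
  with 6/18 selectable; components are reported smallest-first.
* **Centers of gravity** are unweighted voxel centroids mapped through
  the affine (0-based voxel convention, as in the NIfTI standard).
* **Determinism.** Every stochastic stage draws from a local RNG stream
  seeded from a master seed; subject order is canonicalized before
  analysis, so results are independent of input row order, and two runs
  with the same configuration produce byte-identical manifests.
* **CV accuracy reporting** pools held-out predictions over folds at the
  selected C (non-nested, matching the apparent original procedure); this
  is optimistically biased and a nested scheme is the unbiased variant.
  Per-permutation re-selection of C is available but off by default
  (fixed C is standard and far cheaper).
* **Demographic statistics** are computed from summary statistics (means,
  SDs, counts) so printed cohort tables can be checked directly. One
  printed value in the target tables (a sex chi-square of 0.04) is not
  reproducible from the printed counts under any standard formula
  (with/without continuity correction gives 0.24/0.09) and is treated as
  a typographical inconsistency; the other site's value (0.009)
  reproduces exactly.

# Problem sizes used by the tests

The unit suites run on 8³–16³ lattices with 4–24 subjects per group. The
stochastic acceptance suites use: 20 seeds of a null cohort (effect d = 0,
16³, 12/12 per site, B = 200) for chance-level transfer and FDR family
error; 20 seeds of the full-design signal cohort (24³, 50/51 + 49/48,
B = 1000, CV-selected C) for cross-site accuracy > 65% and truth-mask
Dice > 0.3; and 20 seeds of a 50-patient cohort for recovery of an
injected ROI–score correlation within ±0.25. The analysis scripts run the
same pipeline once at 32³ with B = 2000. These sizes were chosen so each
property is measured with enough replicates to be stable while the whole
suite stays desk-scale; the full-fidelity configuration (B = 5000,
extent 100) remains the package default.

# Known limitations

* The solver is specialized to the linear kernel (by design — the weight
  map is the object of inference); no probability calibration.
* Cluster-level inference is extent-thresholding only; no cluster-mass or
  TFCE statistics, and no anatomical atlas lookup (regions are reported
  as coordinates).
* The permutation test for cross-site performance permutes training
  labels and retrains; permuting test labels of a fixed model is offered
  as an alternative, and the two answer different questions.
* Summary-statistic demographic tests assume pooled-variance t; Welch
  variants are not provided because the target tables use the pooled
  form.
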