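# gmsvm — cross-site SVM classification of gray matter density maps

`gmsvm` is an R implementation of a multivariate pattern analysis (MVPA)
pipeline for structural MRI case-control studies acquired at **two
independent imaging sites**. It is written for neuroimaging
methodologists who want a fully scripted, reproducible version of the
classic voxel-based-morphometry + linear SVM workflow: train a classifier
on the gray-matter (GM) density maps of one site, test it on the other
site's cohort, map which voxels drive the classification, and relate
those regions to clinical scores.

Because case-control MRI data are rarely shareable, the package also
ships a **synthetic two-site cohort generator** that reproduces the
statistical structure the analysis assumes — two scanners with different
cohort sizes, age distributions and intensity/noise profiles, age- and
sex-related GM variation, configurable focal disease effects with known
ground truth, and clinical scores coupled to regional GM at a chosen
correlation. Every stage of the pipeline is tested end-to-end against
that generator.

## The method

For subject volumes $v_i$ and labels $y_i \in \{-1\ (\text{patient}),
+1\ (\text{control})\}$:

1. **Smooth** each volume with an 8 mm FWHM Gaussian
   ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, voxel sizes from
   the affine).
2. **Mask**: keep voxel $v$ iff the mean smoothed GM over all subjects of
   both sites exceeds 0.2.
3. **Residualize** age and sex per site by OLS, adding the site intercept
   back so densities stay on the GM scale.
4. **Classify** with a soft-margin linear SVM, solved by a compiled SMO
   routine on the dual
   $\min_\alpha \frac12\alpha^\top Q\alpha - e^\top\alpha$,
   $0 \le \alpha_i \le C$, $y^\top\alpha = 0$; $C$ is selected by
   stratified ten-fold cross-validation. Report accuracy, sensitivity,
   specificity, PPV, NPV (patient = positive class) and rank AUC, with
   label-permutation p-values ($p = \max(\#\{\text{null} \ge
   \text{obs}\}, 1)/B$, so the smallest reportable p is $1/B$).
5. **Weight-map inference**: retrain on $B$ label permutations to get a
   per-voxel null of SVM weights; two-sided p on $|w_v|$; FDR
   (Benjamini–Hochberg) at $q < 0.05$; connected components
   (26-connectivity) above a cluster-extent threshold; report voxel
   count, center of gravity (mm) and mean weight per cluster; intersect
   the two site-models' maps into an overlap map.
6. **Clinical correlations**: Spearman $\rho$ between cluster mean GM and
   patients' clinical variables (PANSS, onset age, illness duration,
   CPZ-equivalent dose, premorbid IQ), per model, with BH correction
   across the ROI × variable family, plus ROI–ROI correlation matrices
   and summary-statistic demographic tests (pooled t, 2×2 chi-square).

See `vignettes/cross-site-gm-svm.Rmd` for the full methods account,
including the generator's model and the package's numerical choices.

## Worked example

The numbered scripts under `analysis/` run the whole experiment on a
desk-scale synthetic cohort (32³ lattice of 4 mm voxels, 101 + 97
subjects, disease effect d = 1.2 in two ellipsoidal regions, one coupled
to antipsychotic dose at Spearman ρ = −0.35):

```sh
Rscript analysis/01_simulate.R      # cohort -> results/cohort/
Rscript analysis/02_preprocess.R    # mask + features -> results/preprocess/
Rscript analysis/03_classify.R      # CV + cross-site performance
Rscript analysis/04_weight_maps.R   # significance maps, clusters, overlap
Rscript analysis/05_clinical.R      # demographics + ROI correlations
```

A run with the shipped configuration prints, for the site-A model
(`analysis/03_classify.R`):

```
CV-selected C = 0.03125
Ten-fold CV on siteA:
accuracy 85.1%  sensitivity 76.0%  specificity 94.1%
Cross-site test on siteB:
accuracy 69.1%  sensitivity 40.8%  specificity 97.9%
PPV 95.2%  NPV 61.8%  AUC 0.9477
Permutation p: accuracy 0.01, AUC 0.001 (B = 1000)
```

i.e. within-site CV is optimistic (85%) relative to true cross-site
transfer (69–77% across directions and seeds), exactly the gap this
design quantifies. `analysis/04_weight_maps.R` then recovers the two
injected regions:

```
significance_map: 8550 voxels, B = 2000; 141 significant at FDR q < 0.05
  cluster n_voxels  cog_x_mm  cog_y_mm  cog_z_mm  mean_weight
1       1       57    -16.9     -13.5      -6.9      0.0798
2       2       84     -0.6      22.0      10.5      0.0739
Dice overlap with the generator truth mask: 0.569
```

The cluster centers of gravity sit on the injected region centers
(0, 22, 10) and (−18, −14, −6) mm. Finally `analysis/05_clinical.R`
recovers the injected dose coupling on the linked region
(`CPZ_mg ρ = −0.33, p = 0.019, n = 49` for the site-B model) with no
cell surviving the family-wise FDR — the expected outcome at n ≈ 50 and
|ρ| ≈ 0.35.

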