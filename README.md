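# chpqc

Quantitative comparison of choroid plexus (ChP) segmentations across MRI
sequences and raters.

The choroid plexus — the thin vascular tissue in the brain ventricles that
produces cerebrospinal fluid — is delineated most reliably on
contrast-enhanced T1-weighted MRI (CE-T1w), but contrast injection is
invasive and often unavailable, so studies fall back on plain T1w or FLAIR
images. `chpqc` is for imaging scientists who need to decide, with numbers,
whether those non-contrast segmentations can stand in for the reference
standard. Given co-registered NIfTI volumes and binary masks it computes:

* **Contrast**: per-subject SNR and CNR of the ChP against a ventricular
  background region, built by subtracting the union of all ChP masks from
  the lateral-ventricle mask and eroding with a spherical kernel of 2 mm
  radius (physical mm, anisotropy-aware):

  SNR = mean(ROI) / sd(background),
  CNR = (mean(ROI) − mean(background)) / sd(background)

* **Overlap and volume agreement** vs a reference sequence: Dice
  coefficient 2·TP/(2·TP+FP+FN), absolute volumes in mL, signed and
  absolute percentage volume difference
  ΔVol% = 100·(V_seg − V_ref)/V_ref, cohort Pearson volume correlation,
  and inter-rater ICC(2,1) on absolute volumes from two-way ANOVA mean
  squares.

* **Spatial variability**: slice-wise error profiles
  100·(N_seg(i) − N_ref(i))/N_ref along template axes (axial z,
  coronal y, world-mm slice coordinates), and voxel-wise frequency
  (probability) maps with difference maps against the reference.

* **Statistics**: one-way ANOVA with post hoc pairwise t-tests across
  sequences, one-sample t-tests on ΔVol%, and two-sample t-tests between
  non-reference sequences, two-tailed at α = 0.05.

* **Phantoms**: a synthetic cohort generator with known ground-truth
  contrast, Dice degradation and signed volume bias (e.g. a FLAIR-like
  +28 % overestimation), so every stage has a recovery test without
  patient data.

## Worked example

Generate a 6-subject phantom cohort and run the full pipeline:

```r
library(chpqc)
spec   <- phantom_spec(n_subjects = 6, seed = 7)
cohort <- generate_cohort(spec)
rep <- run_pipeline(run_config(output_dir = "chpqc_out", seed = 7),
                    cohort = cohort)
rep$cohort_summary[, c("sequence", "snr_mean", "cnr_mean", "vol_ml_mean",
                       "dsc_mean", "dvol_pct_mean", "icc")]
#>   sequence snr_mean cnr_mean vol_ml_mean dsc_mean dvol_pct_mean   icc
#> 1      T1w    11.19     4.95        1.14    0.676          3.81 0.733
#> 2    FLAIR     8.89     6.57        1.41    0.681         28.29 0.845
#> 3   CE-T1w    22.98    17.78        1.10       NA            NA 0.710
```

Reading the table: the CE-T1w analogue has by far the best contrast
(SNR 23.0, CNR 17.8 vs 11.2/5.0 for T1w), exactly as its intensity model
prescribes; the FLAIR-like masks overestimate the reference volume by
+28.3 % on average (1.41 vs 1.10 mL) while T1w-like masks are nearly
unbiased (+3.8 %); both non-contrast analogues overlap the reference with
Dice ≈ 0.68; the `icc` column is inter-rater agreement on absolute volume
(reference and self-comparison cells are `NA` by design). The statistical
battery confirms the volume inflation:

```r
subset(rep$stats, test == "one_way_anova")[, c("metric", "statistic",
                                               "df", "p_value")]
#>            metric statistic   df  p_value
#> 1       volume_ml     194.5 2,15 1.87e-11
#> 5             snr    3057.5 2,15 2.60e-20
#> 9             cnr    4711.5 2,15 1.02e-21
#> 17 interrater_dsc      21.1 2,15 4.32e-05
```

All tables (`contrast.tsv`, `overlap.tsv`, `interrater.tsv`,
`cohort_summary.tsv`, `stats.tsv`, `slice_profiles.tsv`), frequency maps
(NIfTI) and a run log land in `chpqc_out/`. Disk-based cohorts use one
directory per subject (`<sequence>.nii.gz`,
`<sequence>_chp_<rater>.nii.gz`, `ventricles.nii.gz`); see
`simulate_cohort()` / `read_cohort()`. The methods vignette
(`vignettes/chpqc-methods.Rmd`) documents the models, conventions and
phantom design.

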