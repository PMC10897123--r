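---
title: "Methods: quantifying agreement between choroid plexus segmentations"
author: "chpqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying agreement between choroid plexus segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chpqc)
```

## The problem

The choroid plexus (ChP) is a thin, vascular structure inside the brain
ventricles whose volume is increasingly used as an imaging biomarker in
neuroinflammatory and neurodegenerative disease. The reference standard for
delineating it is contrast-enhanced T1-weighted MRI (CE-T1w), but contrast
injection is invasive and not always available, so segmentations are often
drawn on plain T1w or FLAIR images instead. Deciding whether those
non-contrast segmentations are good enough requires a quantitative
comparison: how visible is the ChP on each sequence, how well do the masks
overlap, how biased are the volumes, where in the ventricles do the
sequences disagree, and how reproducible is the delineation across raters.

`chpqc` implements that comparison as a pipeline over co-registered NIfTI
volumes. Registration and segmentation themselves are out of scope: every
subject enters the pipeline as a set of volumes and binary masks already on
one voxel grid, and the package verifies that contract
(`validate_common_space()`, affine agreement within $10^{-4}$ mm, a
tolerance chosen because resampled NIfTI headers carry float32 rounding)
rather than fixing violations silently.

## Contrast metrics and the background region

Visibility of the ChP against the surrounding cerebrospinal fluid is
summarized per subject and sequence by

$$\mathrm{SNR} = \frac{\overline{I}_{\mathrm{ROI}}}{s_{\mathrm{bg}}},
\qquad
\mathrm{CNR} = \frac{\overline{I}_{\mathrm{ROI}} -
\overline{I}_{\mathrm{bg}}}{s_{\mathrm{bg}}},$$

where the ROI is the sequence's own ChP mask and the background is a
ventricular reference region. The background is built by subtracting the
union of all sequences' ChP masks from the lateral-ventricle mask and then
eroding with a spherical kernel of 2 mm radius, in that order, so that the
surviving voxels are comfortably inside CSF. Three numerical choices
matter:

* **The kernel is defined in physical millimetres**, not voxels: an integer
  offset belongs to the structuring element iff its world-space norm is at
  most the radius (closed ball, so the axis voxels at exactly 2 mm are
  included). On 1 mm isotropic grids this coincides with a 2-voxel ball; on
  anisotropic grids the kernel automatically flattens (e.g. ±1 voxel
  through-plane at 2 mm slice thickness). The kernel size is a
  configuration option (`erosion_radius_mm`); 2 mm is the default radius —
  if a 1 mm interpretation of "a 2 mm spherical kernel" is wanted for
  sensitivity analysis, it is a one-argument change.
* **Voxels outside the grid count as background** during erosion, so border
  voxels always erode away. This is the conservative direction: a voxel
  whose neighborhood cannot be verified is never admitted to the noise
  region.
* **$s_{\mathrm{bg}}$ is the sample SD** (denominator $n-1$): the
  background is treated as a sample of the noise process. The convention is
  recorded in the run log.

Useful algebraic facts, asserted as tests: $\mathrm{SNR} - \mathrm{CNR} =
\overline{I}_{\mathrm{bg}} / s_{\mathrm{bg}}$ identically; both metrics are
invariant under global positive scaling of the image; adding a constant
shifts SNR but not CNR. Intensities are used raw — both metrics are ratio
scaled and any affine intensity normalization would cancel or be absorbed.

## Overlap and volume agreement

Against a designated reference mask (CE-T1w by default) the package
computes, per subject: the Dice similarity coefficient
$2TP/(2TP+FP+FN)$, absolute volumes in mL (voxel count times voxel volume),
the signed percentage volume difference
$\Delta\mathrm{Vol}\% = 100\,(V_{seg}-V_{ref})/V_{ref}$ and its absolute
value. Two empty masks make Dice undefined; the package raises an error
rather than returning a conventional 0 or 1, because that situation always
indicates broken upstream masks, never a measurement. Cohort-level
agreement is summarized by the Pearson correlation of per-subject volumes
(one point per subject, requiring $n \ge 3$).

Inter-rater agreement on absolute volumes uses the two-way random-effects,
absolute-agreement, single-measurement intraclass correlation ICC(2,1),
computed from the two-way ANOVA mean squares:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$

The absolute-agreement form is the default because the scientific question
is whether specific raters produce the same volumes, not merely correlated
ones; the consistency form ICC(3,1) is available via `variant =` and the
choice is written to the output metadata. A subtlety uncovered during
testing: the textbook claim that ICC equals the Pearson correlation when
the two rater columns share mean and variance is exact only for ICC(3,1)
(where it reduces to $2\,\mathrm{cov}/(\mathrm{var}_a+\mathrm{var}_b)$);
the ICC(2,1) sample estimator keeps a finite-sample $\tfrac{k}{n}(MS_C -
MS_E)$ term even at exactly equal column means, and only converges to the
Pearson value as $n$ grows. The test suite asserts the exact identity on
ICC(3,1). An all-identical rating matrix has no variance to apportion; it
returns 1 with a warning.

## Spatial variability

Where along the ventricles do sequences disagree? For each subject $s$ and
slice $i$ along a chosen template axis, the slice error is

$$e_s(i) = 100 \cdot \frac{N_{seg,s}(i) - N_{ref,s}(i)}{N_{ref,s}},$$

the per-slice voxel surplus normalized by the subject's **total** reference
volume. The total (not the per-slice count) is the denominator because
per-slice reference counts can legitimately be zero at the structure's
extremes; the normalization also gives a conservation law used as a test
invariant: summing $e_s(i)$ over slices recovers the subject's
$\Delta\mathrm{Vol}\%$ exactly, along either axis. Profiles report the mean
and SD of $e_s(i)$ across subjects — the mean of per-subject normalized
errors, which differs from a normalized mean error when reference volumes
vary across subjects; the former weights subjects equally and is what the
package computes. Slice positions are reported as world-mm coordinates of
slice centers, so template-space locations ("z = −12 mm") are addressable.
Axis handling assumes an axis-aligned template affine, with the
voxel-axis-to-anatomical-axis mapping in configuration (`axis_map`);
oblique affines are not supported.

Frequency maps give the complementary voxel-wise view: each voxel's value
is the fraction of subjects whose mask covers it (always an exact multiple
of $1/n$), and difference maps subtract the reference sequence's map. No
thresholding or smoothing is applied.

## Statistical battery

Sequences are compared with one-way ANOVA followed by post hoc pairwise
two-sample t-tests on SNR, CNR and absolute volume; signed
$\Delta\mathrm{Vol}\%$ of each non-reference sequence is tested against
zero with a one-sample t-test; and the two non-reference sequences are
compared on $\Delta\mathrm{Vol}\%$ and $|\Delta\mathrm{Vol}\%|$ with
two-sample t-tests. All tests are two-tailed at $\alpha = 0.05$ by
default. Post hoc tests are uncorrected for multiplicity by default (a
Bonferroni option exists and the choice is logged), and two-sample tests
default to the pooled equal-variance form, the classical companion of
one-way ANOVA; Welch and paired modes are available as sensitivity
options. The design is strictly speaking repeated-measures (the same
subjects appear in each sequence group); the independent-groups battery is
the default deliberately, with `paired = TRUE` available, because the
cross-sequence comparison is conventionally reported that way and the
paired variant is strictly more powerful — flipping it on cannot hide an
effect the default finds. Zero-variance inputs (e.g. a paired test on
identical samples) raise explicit errors instead of returning a silent
p-value.

## The phantom generator

No public ChP dataset with per-sequence manual masks exists, so every
pipeline stage is validated against synthetic cohorts with known ground
truth. Each phantom subject has two ellipsoidal "lateral ventricles"
(default semi-axes 7×20×9 mm, mirrored at ±15 mm from the midline, with
per-subject jitter of 1 mm SD on centers and 5 % SD on radii) each
containing a thin curved tube of "choroid plexus" (default radius 2.2 mm,
half-length 16 mm, bowed laterally and arched vertically), on a 96³ grid
at 1 mm isotropic — the grid and voxel size matching typical 3D structural
acquisitions. Intensities are three-level (zero outside the ventricles,
CSF level inside, ChP level inside the truth mask) plus stationary Gaussian
noise; the pipeline's contrast metrics involve only first and second
moments, so Rician or structured noise would add realism without adding
discriminative power at this scale.

Per-sequence intensity parameters are chosen so that the implied SNR
(`chp_mean/noise_sd`) and CNR (`(chp_mean − background_mean)/noise_sd`)
reproduce the contrast ordering characteristic of the three sequences
(T1w 13.73/7.44, FLAIR 13.09/10.77, CE-T1w 23.77/18.49) — CE-T1w the most
conspicuous, FLAIR intermediate in CNR because CSF suppression darkens the
background. Mask perturbations emulate the two failure modes of interest:

* **Systematic volume bias** — the truth mask is grown (or shrunk) through
  exact Euclidean distance shells in mm, a physical-distance dilation
  mirroring boundary effects such as FLAIR's intrinsic blurring. Whole
  shells are taken in distance order; the marginal shell is sampled
  independently with the probability that makes the *expected* achieved
  volume equal the target exactly, so cohort-mean recovery tests need no
  fudge factors. Defaults: +28.02 % for the FLAIR analogue, +3.52 % for
  T1w, 0 for CE-T1w. A bias at or below −100 %, or a container too tight
  to supply the requested volume, is an explicit error.
* **Boundary noise** — inner-boundary voxels (face-connectivity) are
  flipped off with probability $p$ and outer-shell voxels inside the
  ventricle flipped on with probability $p\,n_{in}/n_{out}$, preserving
  expected volume while degrading Dice monotonically in $p$. The balancing
  also gives per-subject volumes nonzero variance, which keeps one-sample
  t-tests on the zero-bias condition well-defined. Defaults (0.46 / 0.37 /
  0.05 per sequence, 0.15 for the second rater, chosen once from the
  geometry of the default phantom) place sequence-vs-reference Dice near
  0.67–0.68 and inter-rater Dice near 0.87–0.90, the agreement levels
  typical of this task.

Rater 1's mask *is* the sequence mask; additional raters are re-draws
around rater 1's mask with bias 0 and the rater boundary noise, so
inter-rater agreement is high while inter-sequence disagreement is driven
by the sequence model — matching how disagreement decomposes in practice.

All randomness flows from one integer seed through fixed per-subject,
per-purpose offsets, so subject $k$ is bit-identical regardless of cohort
size and two runs with equal seeds produce byte-identical NIfTI trees and
tables.

What the phantom does **not** emulate: real ChP anatomy (the geometry is
schematic, not atlas-derived; default truth volumes are near 1 mL versus
roughly 3 mL in adults), partial-volume boundaries, bias fields, Rician
noise, inter-subject registration error, or rater biases that correlate
with anatomy. Passing recovery tests therefore demonstrates that the
*metrics and pipeline* are correct and well-calibrated, not that any
particular sequence is adequate on real patients.

## Problem sizes used in the validation suite

The test suite exercises: oracle equivalence of every voxel metric against
brute-force enumeration on 100 random 16³ instances (exact for counting
metrics, $10^{-9}$ for ratios); slice-profile conservation to $10^{-9}$ on
phantom subjects; parameter recovery (volume biases, SNR, CNR, each within
3 SEM of target) on a 30-subject cohort at the default 96³ grid; ICC
against an independent `aov` mean-squares route, including a 200-subject
pure-noise matrix (|ICC| < 0.1); type-I error of the ANOVA and t-tests
within [0.03, 0.07] over 1,000 null simulations; and byte-identical
end-to-end reruns on a reduced 4-subject, 48³ cohort (determinism is
independent of problem size, so the smallest representative cohort is
used).

## Known limitations

* Geometry must be shared exactly (one grid per subject); the package never
  resamples.
* Slice profiles assume axis-aligned affines.
* The repeated-measures structure of sequence comparisons is only honoured
  when `paired = TRUE` is requested.
* ICC variants beyond single-measurement two-way forms (e.g. average-score
  ICC(2,k)) are not implemented.
* The phantom's schematic geometry means absolute metric levels (e.g. mean
  |ΔVol%| at fixed boundary noise) should not be read as predictions for
  clinical data.
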