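Package: chpqc
Title: Quantitative Comparison of Choroid Plexus Segmentations Across
    MRI Sequences and Raters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how well choroid-plexus (ChP)
    segmentations drawn on different MRI sequences (T1w, FLAIR,
    contrast-enhanced T1w) or by different raters agree with a reference.
    Computes signal-to-noise and contrast-to-noise ratios against a
    ventricular background region built by mask subtraction and
    spherical (physical-mm) morphological erosion; Dice overlap, absolute
    volumes, signed and absolute percentage volume differences, Pearson
    volume correlation and inter-rater ICC(2,1); slice-wise volume error
    profiles along template axes and voxel-wise frequency (probability)
    maps with difference maps; and the accompanying statistical battery
    (one-way ANOVA, post hoc and one-/two-sample t-tests). Includes a
    synthetic phantom generator with known ground-truth contrast, Dice
    and volume-bias parameters so every pipeline stage has a recovery
    test without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
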