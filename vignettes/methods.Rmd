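---
title: "Quantifying DAB immunohistochemistry and scoring target suitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DAB immunohistochemistry and scoring target suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcTASC)
```

## The problem

Fluorescence-guided surgery needs a molecular target that is strongly and
widely expressed in tumor tissue and nearly absent from the surrounding
normal tissue. For soft tissue sarcoma (STS) — a rare, heterogeneous family
of mesenchymal tumors affecting humans, dogs, and cats alike — fibroblast
activation protein alpha (FAP) is a candidate: a cell-surface protease
expressed by cancer-associated fibroblasts and by mesenchymal tumor cells
themselves. ihcTASC implements the analysis chain used to evaluate such a
candidate from DAB (diaminobenzidine) immunohistochemistry: pixel-level
quantification of the brown chromogen, a semiquantitative visual expression
score, tumor-to-normal contrast ratios, and the seven-criterion target
selection criteria (TASC) rubric that condenses the evidence into a single
suitability score out of 22.

## Pixel-level quantification

DAB staining is quantified on a single-channel intensity map in [0, 255]
where **lower pixel values mean stronger brown staining**. Each pixel is
assigned one of five levels by closed integer bands:

| level | immunoreactivity | pixel values |
|---|---|---|
| 0 | background (negative) | 176–255 |
| 1 | weak | 131–175 |
| 2 | intermediate | 101–130 |
| 3 | strong | 71–100 |
| 4 | very strong | 0–70 |

The bands are disjoint and tile [0, 255] completely; the value 176, which
sits between the printed level-1 band and the "above 176" background
description, is assigned to background so that the level-1 upper bound stays
exactly 175. The thresholds are a configuration object
(`LevelThresholds()`), validated for disjointness and coverage before use.

For real RGB images the intensity map is derived by standard
Ruifrok–Johnston color deconvolution: per-channel optical densities are
projected onto the DAB stain vector (published H-DAB defaults,
configurable), and the DAB density $d$ is mapped back to a
transmission-scale value $v = \mathrm{round}(255 \cdot 10^{-d})$. Only the
monotone contract is normative — more chromogen always means a lower value,
and pure white maps to 255; proprietary scanner pixel values cannot be
reproduced bit-exactly, so the printed thresholds are applied to this map.
A pass-through mode accepts single-channel images unchanged, which is how
the synthetic generator's images are consumed. Values are quantized to
integers before classification because the thresholds are printed as
integers.

Per region of interest (ROI) — tumor, peritumoral epidermis/dermis, adipose
or muscle, the matching healthy controls, or inflamed tissue — the package
measures each level's area (pixel count × pixel size²), excludes artifacts,
and computes:

* the **total positive area**, the sum of the level 1–4 areas;
* **normalized areas**: because ROIs differ in size, every area is
  rescaled to a standard reporting area of 10 high-power (×400) fields,
  2.37 mm² = 2,370,000 µm². The normalization divides by the
  *artifact-free* ROI area — the rubric should not be diluted by glass or
  debris that carries no tissue;
* the **mean intensity (MI)**, the arithmetic mean pixel value. By default
  MI is taken over all non-artifact ROI pixels; whether it should instead
  cover only positive pixels is not externally fixed, so
  `measureROI(..., miPixels = "positive")` exposes the alternative.

Area conservation (level areas + artifact area = ROI area) holds exactly by
construction and is asserted on every fixture in the test suite.

Artifact exclusion is rule-based: saturated white (glass; all channels
≥ 250), near-black debris (all channels ≤ 10), and the reserved synthetic
artifact color. This replaces proprietary AI tissue segmentation, which is
out of scope; the rules are deliberately conservative and are only expected
to be complete on synthetic data, where artifacts carry the reserved color.

## The semiquantitative expression score

The visual score multiplies two components:

* a **percentage score** binning the percent of FAP-positive tumor cells:
  under 1% → 1, 1–10% → 2, over 10% up to 50% → 3, over 50% → 4. The
  printed bins jump from "10%" to "11%"; continuous inputs strictly between
  10 and 11 fall in the 3+ bin via half-open binning, keeping the mapping
  total;
* an **intensity score** 0 (none) to 3 (strong).

The product is the **final grade of positivity**, binned as 0 = no
expression, 1–3 = low, 4–6 = intermediate, 8–12 = high. Only
{0, 1, 2, 3, 4, 6, 8, 9, 12} are reachable; the gap grade 7 between the
intermediate and high bins is unreachable and is asserted by test rather
than mapped. For inhomogeneously stained tumors the **hotspot rule**
applies: if more than one-third of the tumor area shows a staining
intensity above the area-majority grade, scoring uses the strong-signal
region only (`hotspotAssessment()`; threshold exactly 1/3, strict
inequality, operationalized on area fractions).

## Tumor-to-normal ratio and the TASC rubric

A tumor's T/N ratio divides its normalized positive area by the mean
normalized positive area of non-neoplastic tissue (peritumoral plus healthy
control compartments) of its species group. Healthy controls are collected
per species, not per entity, so entities share the species-level control
pool; the default pools all control measurements flat, with a
compartment-wise-mean option (`tnRatio(..., compartmentMeans = TRUE)`) since
the flat-vs-stratified choice is not externally fixed. Tumors without
evaluable peritumoral tissue are recorded as non-evaluable rather than
imputed.

The TASC rubric scores seven criteria. For FAP, I (extracellular,
cell-surface localization) = 5, V (prior in vivo imaging) = 2, VI
(enzymatic activity) = 1, VII (target-mediated internalization) = 1 are
literature-based constants. The evidence-driven criteria are:

* **II** — diffuse overexpression: 4 points when tumors with ≥ 50%
  FAP-positive cells form the group majority, else 0;
* **III** — T/N ratio: 3 points when tumors with T/N > 10 form the
  majority of evaluable tumors, else 0;
* **IV** — prevalence of overexpression: the integer percent of
  overexpressing tumors binned as ≥ 90 → 6, 70–89 → 5, 50–69 → 3,
  below 50 (including below 10) → 0.

Two decisions here were genuinely open. First, the "majority": the rubric's
prose says strictly more than half, but the reference results score a group
at exactly half (11/22) as a pass — so the default is ≥ 50%
(`majorityMode = "gte50"`), with the strict reading available as `"gt50"`
and a regression test pinning the flip. Second, a tumor "overexpresses"
when at least 10% of its cells show intermediate-to-strong staining; the
≥ 10% reading is the default with `overexpressionMode = "gt10"` as the
switch. Criterion IV percentages are rounded half-up to integers before
binning, matching how such percentages are conventionally printed.

The bundled `stsCriterionInputs()` table carries the per-group evidence for
the cross-species STS cohorts used as the worked example (39 human, 53
canine, 24 feline tumors). In the MPNST group the reported percentage (90%)
is inconsistent with its count (7/10 = 70%); criterion IV follows the
reported percentage, which is why the table carries both columns and the
percentage takes precedence when present.

## The synthetic-data generator

Because the original slides are external, the generator produces inputs
with known ground truth at the study's own scale.

**Images.** Pixels are assigned to levels in exact counts from the target
fractions and placed at the center value of each band (35, 85, 115, 153,
215), optionally with Gaussian pixel noise (rounded, clipped). Ground truth
records the exact per-level counts, so noiseless recovery by the quantifier
must be *exact*, and with noise SD 5 the band centers sit ≥ 4 standard
deviations from every positive/background boundary, keeping the total
positive area within 2% of truth. The DAB color model is synthesized
directly in intensity space with an invertible optical-density RGB
rendering — the generator-quantifier round trip is exactly testable, which
a photorealistic renderer would not be. Artifacts are rendered in a
reserved color (pure magenta) the brown rendering cannot produce.
Deliberately not emulated: nuclei and cell instances, hematoxylin
counterstain texture, scanner vignetting, compression artifacts — so
passing recovery tests demonstrates the measurement arithmetic, not
robustness to real-slide color variation.

**Cohorts.** One row per tumor with grade (per-entity distributions),
percent positive cells (normal, clipped to [0, 100] — clipping rather than
resampling, accepting a small documented bias toward the interior at the
extremes), intensity grade, and a T/N ratio drawn lognormal with
$\sigma = 1$ and $\mu = \ln 10 + \sigma\,\Phi^{-1}(f)$ so that
$P(T/N > 10) = f$, the group's specified exceedance fraction. Per-entity
percent-positive means and SDs are reported per species only, so entities
inherit their species values; the ungraded human DFSP cohort is assigned
grade 3 like the other (predominantly grade-3) human entities. The
normalized stained area is generated as a monotone function of percent
positivity and intensity with lognormal scatter, reproducing the strong
positive coupling between the visual score and the measured area that the
correlation stage is expected to detect.

All randomness flows from a single seed; generation restores the caller's
RNG state, and identical seeds give byte-identical bundles (asserted via
manifest checksums).

## Statistics

The reporting stage mirrors the study's tests on pipeline outputs:
Kruskal–Wallis across tissue classes with Dunn's post-hoc z tests on all
pairs (average ranks, tie-corrected variance, Bonferroni family adjustment
by default — the adjustment variant is not externally fixed and is
switchable), Spearman rank correlation with average-rank tie handling
(large-sample p-values), and Pearson's chi-squared without continuity
correction (the correction choice is likewise not externally fixed; the
uncorrected statistic matches the closed form asserted in the tests). A
Shapiro–Wilk normality check is reported alongside but never gates the
nonparametric pipeline. Dunn's test is implemented in the package; for two
groups its squared z equals the tie-corrected Kruskal–Wallis statistic,
which the tests use as an independent cross-check. Both tests' type-I error
is verified by Monte-Carlo null calibration (1,000 replicates) to be within
±0.02 of the nominal 0.05.

## Problem sizes and numerical choices

The test fixtures use 64–128 px images (the measurement arithmetic is
resolution-exact, so small images prove the same identities as whole-slide
rasters), cohort tables at the study's actual sizes (116 tumors), and
1,000-replicate null calibrations. Degenerate inputs are defined errors: an
ROI that is entirely artifact (MI undefined), a zero mean control area
(undefined T/N, reported and excluded rather than imputed), empty groups,
and zero-margin contingency tables. Ties in ranks use average ranks
throughout.

## Limitations

The pipeline evaluates IHC evidence only; it does not model inter-rater
agreement, cell-level counting, stain normalization across scanners, or
whole-slide pyramidal formats. Cohort-level percentages and correlation
coefficients computed on synthetic cohorts characterize the generator, not
any real cohort: only the rubric arithmetic, the measurement identities,
and the statistical calibration transfer to real data unchanged.
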