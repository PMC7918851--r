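---
title: "Methods: quantifying CAF-modulated cisplatin sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying CAF-modulated cisplatin sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafsens)
```

## The biological question and the measurement chain

Cancer-associated fibroblasts (CAFs) are the dominant stromal component of
head and neck squamous cell carcinomas (HNSCC), and their secreted factors
can shift how tumor cells respond to platinum chemotherapy. The package
implements the quantitative chain used to study this in coculture
clonogenic assays with patient-derived CAFs:

1. **Colony quantification.** Cancer cells seeded at clonal density form
   colonies over weeks; fixed colonies stained with trypan blue are
   photographed, and the *fraction of the well area covered by colonies*
   is the survival readout.
2. **Sensitizing ratio.** The treated/untreated area ratio under CAF
   coculture is contrasted against the same ratio without coculture, on a
   log2 scale.
3. **Relative gene expression.** A 20-assay qPCR panel is analyzed by the
   comparative Ct method against dual housekeepers (ACTB, PSMB2), with a
   per-CAF pairwise baseline isolating the cisplatin effect from the
   coculture effect.
4. **Platinum mass balance.** ICP-MS platinum concentrations in the
   culture media before and after treatment close a mass balance around
   the CAFs, yielding uptaken and effluxed amounts.
5. **Statistics.** One-sample and paired t-tests, Pearson correlation of
   expression with log2 colony area, two-component PCA and hierarchical
   clustering tie phenotype to expression.

Raw images, Ct tables and ICP-MS readings from the original experiments
are not numerically available, so a synthetic-data generator with known
ground truth stands in for them; every stage is validated against what was
planted.

## Colony segmentation

Images are 8-bit sRGB rasters. They are converted to CIELAB (D65, via
`grDevices::convertColor`) and thresholded on the b channel, the
blue-yellow opponent axis: trypan-blue-stained colonies fall far on the
blue pole (the default stain color RGB (70, 80, 160) sits at b = -44.8)
while unstained background is near b = 0. A *single fixed threshold* is
applied to every image of a batch.

Two genuinely open readings existed here. "The blue component of the image
transformed into Lab color space" names a channel but neither a sign nor a
value; we take CIELAB b with colonies *below* the threshold as the primary
reading (blue = negative b is the colorimetric definition), default
threshold b = -5, and expose both the direction and the raw RGB blue
channel as options so either reading is reproducible. No morphological
cleanup is applied by default — the procedure is a bare threshold — but a
minimum-object-size filter is available (`min_size`, via EBImage) for
images with speckle noise. Colony *counting* is deliberately not
implemented: the survival readout is area, not count.

The well region defaults to the whole image; `circular_roi()` builds a
center + radius mask for plate scans whose corners are not well area.
Coordinates are (row, col), 1-based, as R matrices index.

With the default palette the two classes are ~45 b-units apart while
pixel noise at the default sd = 3 intensity units moves b by roughly 1
unit, so misclassification is negligible — which is what the ground-truth
recovery tests (|estimated - true fraction| <= 0.01 over 50 seeded
plates) confirm. That shows correctness of the machinery, not robustness
to real-world artifacts (uneven illumination, meniscus shadows, stain
debris), which the generator does not emulate.

## The sensitizing ratio

For per-condition mean area fractions \(a\):

$$\mathrm{ratio} = -\log_2\!\left(
  \frac{a_{cis+CAF}/a_{cis-CAF}}{a_{cis+nc}/a_{cis-nc}}\right)$$

The non-cocultured control scores exactly 0; positive values mean the CAF
*sensitizes* the cancer cells to cisplatin, negative values that it
supports resistance. The score is invariant to rescaling all four areas,
antisymmetric under swapping the coculture and control pairs, and
decomposes into the difference of the two arms' log2 survival ratios —
all of which are tested as identities.

Choices the definition leaves open:

* **Replicate aggregation.** The ratio is computed on per-condition mean
  area fractions (`sensitizing_table()`); replicate wells are averaged
  before the log.
* **Classification.** Only the sign is defined; we call |ratio| < 0.05
  "neutral" (`classify_sensitizing()`), since at that magnitude the sign
  is below the noise floor of the assay.
* **Zero areas** make the log undefined and raise an error naming the
  offending well rather than propagating infinities.

## Comparative Ct expression

The classic delta-delta-Ct model with amplification efficiency fixed at 2:
one cycle earlier equals one doubling. The reference Ct of a sample is the
arithmetic mean of the ACTB and PSMB2 mean Cts — arithmetic mean on the Ct
scale is the geometric mean on the expression scale, the standard
dual-housekeeper combination. Replicates are averaged to a mean Ct per
gene and sample before the delta-delta step; replicate-wise fold changes
(each target replicate against its replicate's housekeeper reading) are
retained for the one-sample t-tests and provide the standard error.

Undetected reactions are censored at Ct = 45, the end of the PCR program,
and flagged; a gene undetected in *all* replicates of a condition yields a
missing fold change that is excluded from correlations, never an infinite
one.

Two calibrators are first-class (`fresh_medium`, `depleted_medium`)
because the published analyses are ambiguous about which non-cocultured
baseline anchors the heatmaps; all fold-change identities (shift
invariance per sample, calibrator transitivity) hold under either. The
cisplatin-effect analysis uses `pairwise_baseline()`: each CAF's
no-cisplatin arm is set to 0 and its cisplatin-influenced arm becomes the
difference of the two arms' fold changes, removing the among-CAF coculture
effect; the common calibrator cancels algebraically.

## Platinum mass balance

Cells were dosed with 5 uM cisplatin. Whatever platinum is missing from
the medium after 24 h must be in (or on) the CAFs:

$$n_{CAF} = n_{added} - c_{post} \cdot V$$

and platinum found in *fresh* medium conditioned after the treatment can
only have been effluxed: \(n_{released} = c_{released} \cdot V\). ICP-MS
samples are measured at a 10-fold dilution, undone by
`correct_dilution()` before the balance.

The medium volume is a required configuration value (default 2 mL) — the
amounts in nmol are explicit functions of it, and both concentrations (uM)
and amounts (nmol) are reported. Negative balances within 5% of the added
dose are clamped to 0 as measurement noise; larger violations abort,
because the balance presumes a closed system. The recurrence comparison
(`compare_by_group()`) uses the pooled-variance two-sample t-test: with 2
recurrent vs 5 non-recurrent donors, Welch's correction leaves ~1.9
degrees of freedom and essentially no power, while the pooled test keeps
df = 5; with such small groups the equal-variance assumption is the
conventional and defensible choice.

## Statistical layer

* t-test wrappers delegate to `stats::t.test` and are cross-checked in the
  tests against textbook formulas to 1e-10; their type-I error is verified
  by simulation (1000 null draws, rejection rate within [0.03, 0.07] at
  alpha = 0.05).
* `expression_area_correlation()` computes per-gene Pearson correlations
  between fold changes and log2 area fractions across CAFs, dropping
  missing pairs; p-values are reported raw by default (the analyses this
  reproduces used a plain p < 0.05 level), with Benjamini-Hochberg behind
  the `adjust` flag.
* Zero area fractions are floored at half the minimal nonzero observed
  fraction before the log2 transform and flagged.
* `pca_two_components()` is SVD-based (`stats::prcomp`), column-centered,
  optionally unit-scaled, truncated to two components; the tests compare
  it against an independent eigen-decomposition of the covariance matrix.
* `cluster_heatmap()` defaults to Euclidean distance with complete
  linkage — the published figures name only plotting tools, not
  parameters, so we fix the most common defaults and expose both. Leaf
  orders and dendrograms are returned independently of the optional
  pheatmap figure. Both raw log2 and row-standardized scaling modes are
  available (`scale_rows`), since the published heatmap scaling is not
  stated.
* `cd90_positivity()` implements isotype gating: the gate is a quantile of
  the isotype control (default 0.99 — the quantile used originally is not
  stated, and 1% false-positive allowance is the common convention), and
  positivity is the fraction of stained events above it.

## What the synthetic generator emulates

`synthetic_config()` fixes the study conditions: seven CAF donors (ids and
recurrence status from the packaged clinical table), 5 uM cisplatin in
2 mL of medium, 10-fold ICP-MS dilution, a 20-gene panel with two
housekeepers, three qPCR replicates per gene and condition (replication
was not reported; three is the field's default for TaqMan assays).

* **Plate images**: stain-colored disks (log-normal radii, e^mu = 5 px,
  sigma = 0.25) placed uniformly in a circular well on a near-white
  background, Gaussian pixel noise sd 3, 8-bit clipping. Overlaps merge;
  the truth is the union mask. Untreated colony counts are uniform on
  30–60 per well; treatment scales counts by a survival factor (0.4 for
  controls) modulated per CAF by the planted sensitizing effect.
* **Ct tables**: planted log2 fold changes written directly into target
  Cts; by default resistance-associated genes (VEGFA, PGE2S, COX2, EGFR,
  NANOG) rise where the planted sensitizing effect is negative and CCL2
  tracks sensitization, mirroring the expression-phenotype structure the
  statistics should detect.
* **Platinum tables**: planted uptake fractions (0.6 for
  recurrence-associated donors, 0.3 otherwise — a planted effect in the
  direction the group comparison should find) and a 20% efflux fraction.
* **Flow samples**: a two-component log-normal mixture with a planted 96%
  positive fraction.

Every generator keys an independent RNG substream off the master seed via
a label hash, so outputs are byte-identical under a fixed configuration
and no global RNG state is touched. The planted sensitizing ratio is
defined from the *realized* ground-truth masks, which is why a noise-free
run must reproduce it to float tolerance, not approximately.

What the generator does **not** emulate: illumination gradients, colony
morphology beyond disks, qPCR efficiency differences between assays,
plate-position effects, ICP-MS drift, or doublets/debris in flow data.
Passing the closure and recovery tests therefore demonstrates that the
estimators invert the planted data-generating model; it does not certify
performance on laboratory images or instruments.

## Problem sizes and determinism

The test suite runs the image stages at 96-pixel plates (10–25 colonies)
and the acceptance-style checks at the full 192-pixel default with 50
seeded plates, 200 recovery seeds for the comparative-Ct estimator and
1000 null seeds for the t-test calibration — sizes chosen so the whole
suite completes in about a minute while keeping Monte-Carlo standard
errors well inside the asserted margins. `run_pipeline()` writes every
table with the seed in a comment header plus a JSON manifest (seed,
configuration digest, package and R versions), and identical
configurations produce identical files.

## Known limitations

* The segmentation threshold value used on the original images was never
  published; the default (-5 on CIELAB b) is a package choice that
  cleanly separates the synthetic palette, not a claim of fidelity.
* The per-CAF sensitizing ratios and the heatmap figures of the original
  study exist only as plots, so no numerical reproduction of those
  panels is possible; the package instead proves its identities and
  recovery properties on planted data.
* Eq-style mass balance attributes all missing platinum to the CAFs;
  adsorption to plasticware or degradation is not modeled.
* The expression layer assumes perfect (2.0) amplification efficiency, as
  the comparative Ct method does; no standard-curve correction is
  offered.
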