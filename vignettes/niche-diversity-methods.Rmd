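---
title: "Spatial niche segmentation and Hill-number diversity for bone-marrow metabolomics"
author: "msiNiche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial niche segmentation and Hill-number diversity for bone-marrow metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Progression from MGUS (monoclonal gammopathy of undetermined significance) to
multiple myeloma (MM) involves metabolic reprogramming of clonal plasma cells
*and* of the bone-marrow microenvironment around them. Bulk metabolomics of
marrow plasma averages both compartments away; mass-spectrometry imaging
(MSI) keeps them apart: each tissue section is a grid of pixels, each pixel a
vector of metabolite intensities. **msiNiche** implements the full analysis
chain for such data:

1. **Segmentation** — partition each section by bisecting k-means on
   normalised pixel spectra, call the plasma-cell-rich niche from marker
   features, and check the called niche pixel fraction against the pathology
   plasma-cell percentage.
2. **Differential statistics** — assumption-routed two-group tests per
   metabolite, BH control, and the joint tissue-by-plasma log2 fold-change
   classification into eight directional classes.
3. **Proliferation coupling** — per-stage correlations of niche metabolite
   levels with the S-phase fraction, and the segmentation gain
   $\Delta|\rho| = |\rho_{\text{niche}}| - |\rho_{\text{whole}}|$.
4. **Ecological diversity** — Hill numbers at $q = 2$ within and between
   compartments, with nonparametric cohort inference.
5. **Multivariate summaries** — PCA, PERMANOVA, PLS-VIP rankings per spatial
   cluster, and a monotone stage-trend screen.

Because matched MSI + plasma cohorts are rarely public, the package ships a
**synthetic cohort generator** that reproduces the statistical structure this
chain assumes, so every stage is testable end to end. All empirical
statements below are computed by the test suite or `scripts/acceptance.R`.

# Models and procedures

## Normalisation

Each pixel is scaled to unit total ion current (TIC), then `log1p`, then
each feature is z-scored across the pixels of its section. Diversity
profiles are built from the raw TIC scale only (z-scores can be negative and
are meaningless as abundances). The TIC step is idempotent; constant
features are left at zero rather than divided by a zero standard deviation;
all-zero pixels are dropped with a warning.

## Bisecting k-means and niche calling

Starting from one cluster, the cluster with the largest within-cluster sum
of squared Euclidean distances is split by 2-means (k-means++
initialisation, 10 restarts, best SSE kept, ties broken by the earliest
restart) until `K` clusters exist. Selecting by SSE rather than size targets
the most heterogeneous region first. The run is deterministic given the
seed, and the split tree records `K - 1` splits with SSE before and after.

Niche calling scores each cluster by its mean marker z-score and designates
the marker-high side of the **largest gap** in the sorted cluster scores
(requiring the top cluster to exceed 0). We use a gap rule rather than a
fixed threshold because section-wide z-scoring changes the scale of the
marker contrast with niche size: in a 5 % niche section the niche cluster
sits several z-units above everything else, while in an 80 % niche section
the niche fragments are compressed towards zero and the microenvironment is
strongly negative. A fixed cut that works in one regime fails in the other;
the gap is large and unambiguous in both. With two clusters the rule reduces
to "pick the marker-high cluster". If no cluster is marker-positive the
niche set is empty and the niche fraction 0.

The default `k_sections = 6`: the generator's microenvironment is patchy
(see below), and a small MGUS niche is only reliably isolated once the
segmentation has enough splits to separate the stromal patches first. `K`
is a config knob; on cleaner tissue `K = 2`–`4` behaves identically.

Concordance with pathology uses the transforms
$x = \log_{10}(\text{fraction} + 10^{-4})$ and
$y = \mathrm{logit}(\text{PC\%})$ for the Pearson correlation, and the
original scales for Spearman. Proportions entering any logit are clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, since the logit is
undefined at the boundaries.

## Routed two-group tests

Per metabolite (one value per subject — compartment means, never pixels, so
pixel pseudo-replication cannot inflate significance): Shapiro–Wilk on each
group at $\alpha = 0.05$; if both pass, Brown–Forsythe Levene
(median-centred) chooses Student's versus Welch's t; otherwise a two-sided
Mann–Whitney U (exact when both groups have $n \le 8$ and no ties). Fold
changes are computed on raw intensity means (MM over MGUS) so the FC–FC
axes stay interpretable; volcano significance requires both $q < 0.05$ and
$|\log_2 FC| \ge 0.58$ (a 1.5-fold change, $\log_2 1.5$ rounded to two
decimals). Both knobs live in `analysisConfig()`.

The eight directional FC–FC classes partition the plane outside the
threshold box: concordant (`both_up`, `both_down`), compartment-restricted
(four `*_only` classes), and offset (two opposite-sign classes); everything
inside the box is `unchanged`. The classification is sign-symmetric by
construction.

## Hill-number diversity

For a relative-abundance profile $p$, $^2D = 1/\sum_i p_i^2$ (inverse
Simpson concentration) and evenness $E = {}^2D / K_{\text{eff}}$ with
$K_{\text{eff}}$ the number of strictly positive abundances. The paper-style
paired two-community beta is
$\beta = {}^2D_\gamma / {}^2D_{\alpha,w}$, where $\gamma$ pools the two
compartment profiles with pixel-count weights. Two alpha options are
exposed:

* `"arithmetic"` (default) — the literal pixel-count-weighted *arithmetic*
  mean of the two $^2D$ values. This reading can produce $\beta < 1$
  (similar profiles, unequal weights, unequal $^2D$); occurrences are
  reported as a diagnostic message.
* `"jost"` — the weighted *harmonic* mean,
  $^2D_{\alpha,w} = (w_a + w_b) / (w_a C_a + w_b C_b)$ with
  $C = \sum p^2$, which guarantees $\beta \ge 1$ by convexity of the
  squared pooled profile (equality iff the profiles coincide). The
  property suite verifies this over 500 random instances.

$K_{\text{eff}}$ is interpreted as richness (count of non-zero features);
if it were read as the panel size, $E$ would rescale by a constant per
panel, leaving all rank-based inference unchanged.

Cohort inference: two-sided Mann–Whitney on evenness and on beta between
MGUS and MM; Cliff's
$\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\}) / (n_x n_y)$ in the
MGUS-versus-MM orientation (negative = higher in MM); OLS of
$\mathrm{logit}(E)$ on $\mathrm{logit}(\text{PC\%})$ with HC3
heteroskedasticity-consistent standard errors,
$(X'X)^{-1} X' \mathrm{diag}\!\left(e_i^2/(1-h_{ii})^2\right) X (X'X)^{-1}$.

## PERMANOVA, VIP, trends

PERMANOVA uses Euclidean distances on z-scored features (no metric is
canonical here; Bray–Curtis is inapplicable after signed normalisation),
the pairwise-distance sums-of-squares identity, and seeded label
permutations with the add-one rule $p = (1 + \#\{F^\ast \ge F\})/(1 + B)$,
$B = 999$ by default — $p$ is never 0. The implementation is cross-checked
against `vegan::adonis2` (R², pseudo-F exact) and against exhaustive
enumeration of all label assignments at $n = 6$.

VIP scores come from a NIPALS PLS of a one-vs-rest cluster indicator
(2 components by default):
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$,
so the mean squared VIP is exactly 1 — asserted in the tests, and checked
to machine precision against the mixOmics reference.

The stage-trend screen Spearman-correlates subject-level niche means with
the ordered stage code (non-progressive MGUS, progressive MGUS, MM; the
spacing is irrelevant to Spearman), BH-adjusts across metabolites, and
flags monotone *increasers* one-sidedly ($\rho > 0$, $q < 0.05$); a strict
variant additionally requires non-decreasing stage medians.

# The synthetic cohort generator

`simParams()` / `simulateCohort()` emulate a 10 + 10 cohort (three MGUS
subjects progressive), one 64 × 64 section per subject, 60 metabolites.

* **Niches** are unions of random discs hitting a target pixel fraction
  exactly (greedy accounting, the last disc trimmed from the rim inwards):
  MGUS 3–7 %, MM 50–90 %, matching typical marrow plasma-cell ranges. The
  subject's true `pc_percent` *is* the realised fraction — conserved by
  construction. No quantitative niche-shape statistics exist to match, so
  disc geometry is a documented free choice.
* **Intensities** are log-normal: baseline (meanlog $\log 100$, sdlog 0.5)
  × $2^{\text{effect}}$ × per-pixel noise (sdlog 0.5), with per-subject,
  per-feature random effects (0.3 log2). Multiplicative effects compose
  additively in log space, matching the downstream log2FC analyses.
* **Planted structure**: plasma-cell markers up in the niche with
  stage-scaled effects (1.8/2.2/2.6 log2) — MM niches are nearly pure
  clonal infiltrates, so the plasma-cell program dominates them more
  strongly, which is what drives the MM evenness deficit; kynurenine-like
  features stepping +1.5 log2 per stage in the niche (the monotone-trend
  and dominance signal; progressive MGUS niches carry intermediate
  effects); tryptophan-like features enriched outside niches; broad MM-up
  (+1.25 log2) and MM-down features; nucleotide-like proliferation-coupled
  features whose niche level tracks the within-stage z of log S-phase with
  a negative sign in MGUS and positive in MM (the stage reversal).
  Effect sizes were fixed at design time so the generator clearly expresses
  the phenomena the pipeline is meant to detect; several-fold changes are
  unremarkable for MSI metabolite contrasts.
* **Microenvironment patchiness**: 0–5 disc-blob subregions per subject
  carrying compositional feature shifts (1.5 log2) that preserve expected
  TIC, so stromal patches never perturb the *relative* marker signal. An
  optional per-patch noise multiplier (off by default) emulates erratic
  patches (hemorrhage, fat); with it, the K = 6 Simpson index spans roughly
  0.4–0.8 across MGUS subjects. Without heterogeneous within-region noise,
  SSE-driven bisecting k-means splits homogeneous tissue evenly and the
  Simpson index barely varies — a structural property of the algorithm, not
  a bug.
* **Bulk plasma** is a convex combination (weight 0.8) of the subject's
  tissue niche mean and independent log-normal noise; with weight 1 and no
  pixel noise it equals the niche mean exactly (tested).

What the generator does *not* emulate: instrument artefacts (peak overlap,
mass drift, matrix clusters), spatial autocorrelation of noise, anatomy
(trabecular bone, vessels), batch effects, or missing-value structure of
real LC–MS panels. Passing tests therefore demonstrate correctness of the
statistical machinery under the assumed generative structure, not robustness
to every artefact of real acquisitions.

# Numerical choices and degenerate inputs

* All randomness flows from explicit seeds; stage seeds in `runAll()` are
  fixed offsets from the master seed so stages can be re-run in isolation.
* Zero-variance features: correlations return `NA` with a flag; z-scores
  clamp the SD to leave zeros; the routed test treats a constant group as
  non-normal, and two identical groups return $p = 1$ with a degenerate
  flag.
* Zero group means in fold changes are offset by a small epsilon and
  flagged; non-finite fold changes are excluded from the FC–FC table with
  a message.
* Abundance profiles must sum to 1 within $10^{-9}$; violations are typed
  errors, never silent renormalisation.
* Empty split children in 2-means trigger re-initialisation (up to 5 × 10
  restarts) before a typed error.
* Validation is total: malformed tables (missing coordinate columns,
  duplicate pixels, negative intensities, unknown group labels, conflicting
  pathway rows) raise classed errors (`msiFormatError`,
  `msiValidationError`), never silent `NA`s.

# Problem sizes used by the checks

The acceptance checks run the default cohort (20 subjects, 64 × 64 grids,
60 features) once for segmentation recovery, plus 100 independent cohort
replicates for the trend-recovery and evenness-deficit power estimates,
1,000 null replicates for test calibration, 50 random instances per
brute-force oracle, and exhaustive permutation enumeration at $n = 6$.
These sizes give Monte-Carlo error comfortably below the asserted margins
while keeping a full run to a few minutes on one core.

# Known limitations

* The niche-calling gap rule assumes the marker set is informative; with
  uninformative markers the gap is noise and the call should be overridden
  manually (the functions accept explicit labels).
* The arithmetic two-community alpha is kept as the default for
  definitional fidelity even though it can yield $\beta < 1$; users wanting
  a guaranteed decomposition should use `alphaMean = "jost"`.
* PERMANOVA is one-way and Euclidean/precomputed-distance only; no
  dispersion (PERMDISP) test is included.
* `imzML` ingestion is out of scope; the on-disk interchange format is the
  TSV pixel table.
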