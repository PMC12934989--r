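# msiNiche

Spatial-plus-systemic metabolomics analysis for plasma-cell disorders:
niche segmentation of mass-spectrometry-imaging (MSI) data, cross-compartment
differential statistics, proliferation coupling, and a Hill-number
ecological diversity framework, for studying progression from MGUS
(monoclonal gammopathy of undetermined significance) to multiple myeloma
(MM).

## Who this is for

Bone-marrow biopsies imaged by MSI give a pixel-level metabolite map of the
tissue; matched bone-marrow plasma gives a bulk systemic profile of the same
patient. **msiNiche** is for analysts who want to go from those two inputs
(plus subject metadata and a metabolite–pathway map) to:

- per-section segmentation into plasma-cell-rich niches vs microenvironment,
  validated against the pathology plasma-cell percentage;
- per-metabolite MM-vs-MGUS statistics in each compartment and the joint
  tissue x plasma fold-change classification (eight directional classes);
- metabolite–proliferation coupling per disease stage, and the gain in
  coupling obtained by restricting to segmented niches;
- scale-aware heterogeneity metrics: within-niche evenness and paired
  niche-vs-microenvironment beta diversity, with cohort-level inference.

A synthetic cohort generator (`simParams()` / `simulateCohort()`) reproduces
the full data structure, so the pipeline runs end to end with no external
data.

## The statistics at the core

- **Segmentation**: bisecting k-means on TIC-normalised, log, z-scored pixel
  spectra — the highest-SSE cluster is split by 2-means (k-means++, 10
  restarts) until K clusters; plasma-cell-rich clusters are called from
  marker features by the largest gap in per-cluster mean marker z-scores.
- **Concordance**: Pearson on transformed scales,
  x = log10(niche fraction + 1e-4), y = logit(PC%), Spearman on original
  scales.
- **Routed tests**: Shapiro–Wilk → (Levene, median-centred) → Student /
  Welch t, otherwise Mann–Whitney U; Benjamini–Hochberg control; volcano
  significance needs q < 0.05 and |log2FC| >= 0.58 (1.5-fold).
- **Diversity** (Hill q = 2): ²D = 1/Σp², evenness E = ²D/K_eff, paired
  two-community β = ²D_γ / ²D_α,w with pixel-count weights (arithmetic or
  harmonic alpha); Mann–Whitney, Cliff's δ, and HC3-robust OLS of logit(E)
  on logit(PC%) at the cohort level.
- **Multivariate**: PERMANOVA (seeded permutations, add-one rule), NIPALS
  PLS-VIP rankings per spatial cluster, Spearman-based monotone stage-trend
  screen.

## Worked example

```r
library(msiNiche)

params <- simParams(grid = c(32, 32), seed = 7)   # 10 MGUS + 10 MM subjects
cohort <- simulateCohort(params)

cohort$datasets[["MM01"]]
#> MSIDataset 'MM01' (subject MM01): 60 features x 1024 pixels
#>   assays: intensities

res <- segmentSection(cohort$datasets[["MM01"]], K = 6,
                      markers = cohort$truth$nicheMarkers, seed = 7)
res$seg
#> SegmentationResult: 1024 pixels in 6 clusters
#>   niche clusters: 2,3,4,5 (fraction 0.875)
```

The called niche fraction (0.875) matches this subject's true plasma-cell
fraction (0.875) exactly. Across all 20 subjects, the called fractions track
the pathology plasma-cell percentages:

```r
fractions <- vapply(names(cohort$datasets), function(id)
  nicheFraction(segmentSection(cohort$datasets[[id]], K = 6,
    markers = cohort$truth$nicheMarkers, seed = 7)$seg), numeric(1))
conc <- concordance(fractions, cohort$subjects$pc_percent)
round(c(pearson_r = conc$pearson_r, spearman_rho = conc$spearman_rho), 3)
#>    pearson_r spearman_rho
#>        0.989        0.999
```

The diversity framework on the called segmentation shows the two planted
progression signatures — lower within-niche evenness in MM (local metabolic
dominance) and higher paired beta diversity in MM (niche–microenvironment
decoupling), with Cliff's δ negative, i.e. higher beta in MM:

```r
masks <- lapply(names(cohort$datasets), function(id)
  isNichePixel(segmentSection(cohort$datasets[[id]], K = 6,
    markers = cohort$truth$nicheMarkers, seed = 7)$seg))
div <- diversityReport(cohort$datasets, masks, cohort$subjects)
str(div$cohort)
#> List of 6
#>  $ mw_p_evenness        : num 0.000183
#>  $ mw_p_beta            : num 0.000583
#>  $ cliffs_delta_evenness: num 1
#>  $ cliffs_delta_beta    : num -0.92
#>  $ ols_slope            : num -0.224
#>  $ ols_hc3_p            : num 6.48e-08
```

`runAll(analysisConfig(seed = 1), "out/")` executes the whole chain
(simulate → segment → differential → FC–FC → coupling → diversity →
multivariate) and writes TSV/JSON outputs plus a manifest with file digests;
re-running the same config reproduces identical outputs.

## The vignette

`vignettes/niche-diversity-methods.Rmd` documents the models, the generator
design (what it emulates and what it deliberately does not), the numerical
edge-case rules, and the open design choices.
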