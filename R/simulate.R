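#' Simulation parameters for a synthetic MGUS/MM cohort
#'
#' Defines the generative model used to exercise the whole pipeline without
#' patient data. Defaults emulate the study design the package targets:
#' 10 MGUS-like and 10 newly diagnosed MM subjects, three of the MGUS
#' subjects being progressive (plasmacytoma-like marrows that carry MM-level
#' niche metabolic effects at MGUS-level niche size), one 64 x 64 section per
#' subject, and a 60-metabolite panel. Plasma-cell-rich niches are unions of
#' random discs hitting a stage-dependent target pixel fraction exactly
#' (MGUS 3-7%, MM 50-90%, mirroring pathology plasma-cell ranges).
#' Intensities are log-normal: multiplicative compartment/stage effects
#' (log2 units) compose additively in log space with per-subject random
#' effects and per-pixel noise.
#'
#' The default feature panel plants, by name:
#' \describe{
#'   \item{`pc_marker_*`}{niche markers, up in the plasma-cell compartment in
#'     every stage (used for niche calling).}
#'   \item{`kyn_like_*`}{kynurenine-arm-like stage-trend features whose niche
#'     abundance steps up by `trendDelta` log2 units per stage
#'     (non-progressive MGUS, progressive MGUS, MM).}
#'   \item{`trp_like_*`}{tryptophan-like features enriched in the
#'     microenvironment outside niches.}
#'   \item{`mm_up_*` / `mm_down_*`}{broad MM-niche up/down effects (also
#'     present in progressive MGUS niches).}
#'   \item{`nuc_coupled_*`}{proliferation-coupled nucleotide-like features:
#'     their niche abundance tracks the subject S-phase score negatively in
#'     MGUS stages and positively in MM (the stage reversal).}
#' }
#'
#' @param nPerGroup subjects per diagnosis group.
#' @param nProgressive number of MGUS subjects given progressive (MM-like)
#'   niche effects.
#' @param grid section dimensions `c(H, W)`, each >= 16.
#' @param nFeatures metabolite panel size (>= 20).
#' @param nicheFractionMGUS,nicheFractionMM target niche pixel fraction
#'   ranges; the MM range must lie strictly above the MGUS range.
#' @param nNicheMarkers,nStageTrend,nMicroMarkers,nMMUp,nMMDown,nCoupled
#'   counts of planted feature types (capped so they fit the panel).
#' @param nicheMarkerEffect niche-marker effect, log2 units; either a
#'   scalar or one value per stage. The default grows with stage, emulating
#'   the increasing purity and metabolic dominance of the clonal plasma-cell
#'   program as niches fill with clonal cells.
#' @param microMarkerEffect,mmUpEffect,mmDownEffect planted effect sizes,
#'   log2 units.
#' @param trendDelta log2 step per stage for stage-trend features; 0 plants
#'   no trend.
#' @param couplingBeta log2 shift per within-stage standard deviation of
#'   log S-phase for proliferation-coupled features.
#' @param baselineMeanLog,baselineSdLog log-normal baseline intensity
#'   parameters (natural log).
#' @param subjectSdLog2 SD of per-subject, per-feature random effects
#'   (log2 units).
#' @param noiseSigma SD of per-pixel log-intensity noise (natural log).
#' @param bulkCoupling convex-combination weight tying the bulk plasma
#'   profile to the subject's tissue niche mean (1 = identical).
#' @param bulkSigma SD of the independent log-normal component of the bulk
#'   profile.
#' @param nMicroRegions number of patchy microenvironment subregions per
#'   section (disc-union blobs outside the niche) carrying their own
#'   per-subject feature shifts — the source of intra-precursor spatial
#'   heterogeneity that the K = 6 Simpson scan picks up.
#' @param microRegionSdLog2 SD (log2) of the subregion feature shifts.
#' @param microRegionFraction target pixel-fraction range per subregion.
#' @param microRegionNoiseMult range of per-subregion pixel-noise
#'   multipliers. The default `c(1, 1)` keeps noise homogeneous; ranges
#'   reaching ~3-4 emulate erratic marrow patches (hemorrhage, fat) whose
#'   spectra are locally unstable, which widens the per-subject spread of
#'   cluster dominance in the spatial-heterogeneity scan.
#' @param seed simulation seed.
#' @return a list of class `"SimulationParams"`; the planted effect array is
#'   in `$effects` (features x compartment x stage, log2 units).
#' @seealso [simulateCohort()], [plantStageTrend()]
#' @export
simParams <- function(nPerGroup = 10L, nProgressive = 3L,
                      grid = c(64L, 64L), nFeatures = 60L,
                      nicheFractionMGUS = c(0.03, 0.07),
                      nicheFractionMM = c(0.50, 0.90),
                      nNicheMarkers = 4L, nStageTrend = 4L,
                      nMicroMarkers = 2L, nMMUp = 6L, nMMDown = 2L,
                      nCoupled = 3L,
                      nicheMarkerEffect = c(1.8, 2.2, 2.6),
                      microMarkerEffect = 1.5,
                      mmUpEffect = 1.25, mmDownEffect = 1.0,
                      trendDelta = 1.5, couplingBeta = 0.6,
                      baselineMeanLog = log(100), baselineSdLog = 0.5,
                      subjectSdLog2 = 0.3, noiseSigma = 0.5,
                      bulkCoupling = 0.8, bulkSigma = 0.3,
                      nMicroRegions = 5L, microRegionSdLog2 = 1.5,
                      microRegionFraction = c(0.05, 0.30),
                      microRegionNoiseMult = c(1, 1),
                      seed = 1L) {
  if (any(grid < 16))
    .msiError("msiValidationError", "grid dimensions must be >= 16")
  if (nFeatures < 20)
    .msiError("msiValidationError", "nFeatures must be >= 20")
  rng <- c(nicheFractionMGUS, nicheFractionMM)
  if (any(rng <= 0) || any(rng >= 1))
    .msiError("msiValidationError", "niche fraction ranges must lie in (0, 1)")
  if (nicheFractionMM[1L] <= nicheFractionMGUS[2L])
    .msiError("msiValidationError",
              "the MM niche-fraction range must lie strictly above the MGUS range")
  if (nProgressive > nPerGroup)
    .msiError("msiValidationError", "nProgressive cannot exceed nPerGroup")

  if (length(nicheMarkerEffect) == 1L) nicheMarkerEffect <- rep(nicheMarkerEffect, 3L)
  if (length(nicheMarkerEffect) != 3L)
    .msiError("msiValidationError",
              "nicheMarkerEffect must have length 1 or 3 (one value per stage)")
  mk <- function(prefix, n) if (n > 0) sprintf("%s_%d", prefix, seq_len(n)) else character()
  nicheMarkers <- mk("pc_marker", nNicheMarkers)
  trendF   <- mk("kyn_like", nStageTrend)
  microF   <- mk("trp_like", nMicroMarkers)
  mmUpF    <- mk("mm_up", nMMUp)
  mmDownF  <- mk("mm_down", nMMDown)
  coupledF <- mk("nuc_coupled", nCoupled)
  planted <- c(nicheMarkers, trendF, microF, mmUpF, mmDownF, coupledF)
  if (length(planted) > nFeatures)
    .msiError("msiValidationError",
              "planted feature counts exceed nFeatures")
  filler <- sprintf("met_%03d", seq_len(nFeatures - length(planted)))
  features <- c(planted, filler)

  eff <- array(0, dim = c(nFeatures, 2L, 3L),
               dimnames = list(features, c("niche", "micro"), .STAGES))
  if (length(nicheMarkers))
    eff[nicheMarkers, "niche", ] <-
      matrix(nicheMarkerEffect, length(nicheMarkers), 3L, byrow = TRUE)
  if (length(microF)) eff[microF, "micro", ] <- microMarkerEffect
  if (length(mmUpF)) eff[mmUpF, "niche", c("MGUS_prog", "MM")] <- mmUpEffect
  if (length(mmDownF)) eff[mmDownF, "niche", c("MGUS_prog", "MM")] <- -mmDownEffect

  params <- structure(list(
    nPerGroup = as.integer(nPerGroup), nProgressive = as.integer(nProgressive),
    grid = as.integer(grid), nFeatures = as.integer(nFeatures),
    nicheFractionMGUS = nicheFractionMGUS, nicheFractionMM = nicheFractionMM,
    features = features, effects = eff,
    nicheMarkers = nicheMarkers, microMarkers = microF,
    mmUp = mmUpF, mmDown = mmDownF,
    trendFeatures = character(), coupledFeatures = coupledF,
    couplingSigns = c(MGUS_nonprog = -1, MGUS_prog = -1, MM = 1),
    couplingBeta = couplingBeta,
    baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
    subjectSdLog2 = subjectSdLog2, noiseSigma = noiseSigma,
    bulkCoupling = bulkCoupling, bulkSigma = bulkSigma,
    nMicroRegions = as.integer(nMicroRegions),
    microRegionSdLog2 = microRegionSdLog2,
    microRegionFraction = microRegionFraction,
    microRegionNoiseMult = microRegionNoiseMult,
    seed = as.integer(seed)), class = "SimulationParams")
  if (length(trendF))
    params <- plantStageTrend(params, trendF, trendDelta)
  params
}

#' @export
print.SimulationParams <- function(x, ...) {
  cat(sprintf("SimulationParams: %d+%d subjects (%d progressive), %dx%d grid, %d features\n",
              x$nPerGroup, x$nPerGroup, x$nProgressive,
              x$grid[1L], x$grid[2L], x$nFeatures))
  cat(sprintf("  planted trend features: %s\n",
              if (length(x$trendFeatures)) paste(x$trendFeatures, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Plant a monotone stage trend into the simulation
#'
#' Sets the selected features' expected niche abundance to increase by
#' `delta` log2 units at each stage step (non-progressive MGUS 0,
#' progressive MGUS `delta`, MM `2 * delta`), so with `delta = 1` the
#' expected niche means stand in ratio 1:2:4. `delta = 0` leaves the effect
#' array untouched and does not record the features as planted.
#'
#' @param params a `"SimulationParams"` list.
#' @param features feature ids to plant (must be in the panel).
#' @param delta log2 step per stage, >= 0.
#' @return the modified `"SimulationParams"`.
#' @export
plantStageTrend <- function(params, features, delta) {
  stopifnot(inherits(params, "SimulationParams"))
  if (delta < 0)
    .msiError("msiValidationError", "delta must be >= 0")
  bad <- setdiff(features, params$features)
  if (length(bad))
    .msiError("msiValidationError",
              sprintf("feature(s) not in panel: %s", paste(bad, collapse = ", ")))
  if (delta == 0) return(params)
  params$effects[features, "niche", ] <-
    matrix(delta * c(0, 1, 2), length(features), 3L, byrow = TRUE)
  params$trendFeatures <- union(params$trendFeatures, features)
  params
}

# union-of-discs niche mask hitting `target` pixels exactly.
# Returns a logical vector over the H*W row-major grid.
.nicheMask <- function(H, W, target) {
  n <- H * W
  if (target < 1 || target > n)
    .msiError("msiValidationError",
              "infeasible niche fraction; choose a smaller (or positive) fraction")
  gx <- rep(seq_len(W) - 1L, times = H)
  gy <- rep(seq_len(H) - 1L, each = W)
  mask <- logical(n)
  rmax <- max(3, 0.12 * min(H, W))
  iter <- 0L
  while (sum(mask) < target) {
    iter <- iter + 1L
    if (iter > 10000L)
      .msiError("msiValidationError",
                "could not cover the requested niche fraction; use a smaller fraction")
    cx <- stats::runif(1, 0, W - 1)
    cy <- stats::runif(1, 0, H - 1)
    r <- stats::runif(1, 2.5, rmax)
    d2 <- (gx - cx)^2 + (gy - cy)^2
    disc <- which(d2 <= r^2 & !mask)
    if (!length(disc)) next
    need <- target - sum(mask)
    if (length(disc) > need)   # trim the last disc from the rim inwards
      disc <- disc[order(d2[disc])][seq_len(need)]
    mask[disc] <- TRUE
  }
  mask
}

#' Simulate a full synthetic cohort
#'
#' Generates one MSI section per subject with a planted two-compartment
#' structure (plasma-cell-rich niche vs microenvironment), matched bulk
#' plasma profiles as a convex combination of the subject's tissue niche
#' mean and independent log-normal noise, subject metadata (diagnosis group,
#' stage, realised plasma-cell fraction, S-phase proliferation score), and
#' the ground truth needed to score recovery. The subject's `pc_percent`
#' equals the realised niche pixel fraction exactly.
#'
#' @param params a `"SimulationParams"` list from [simParams()].
#' @return a list with elements
#'   \describe{
#'     \item{`datasets`}{named list of [MSIDataset-class], one per subject.}
#'     \item{`subjects`}{[S4Vectors::DataFrame] with `subject_id`, `group`,
#'       `stage`, `pc_percent`, `sphase` and a `plasma` matrix column.}
#'     \item{`truth`}{list with per-section niche masks (`compartments`),
#'       exact `pcPercent`, and the planted feature sets.}
#'   }
#' @examples
#' p <- simParams(grid = c(16, 16), nFeatures = 20, nMMUp = 2, nMMDown = 0,
#'                seed = 7)
#' cohort <- simulateCohort(p)
#' cohort$subjects[1:3, c("group", "stage", "pc_percent")]
#' @export
simulateCohort <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  .withSeed(params$seed, {
    H <- params$grid[1L]; W <- params$grid[2L]
    nf <- params$nFeatures
    feats <- params$features
    n <- 2L * params$nPerGroup

    ids <- c(sprintf("MGUS%02d", seq_len(params$nPerGroup)),
             sprintf("MM%02d", seq_len(params$nPerGroup)))
    group <- rep(c("MGUS", "MM"), each = params$nPerGroup)
    stage <- rep("MGUS_nonprog", n)
    if (params$nProgressive > 0)  # the last MGUS subjects are progressive
      stage[seq(params$nPerGroup - params$nProgressive + 1L,
                params$nPerGroup)] <- "MGUS_prog"
    stage[group == "MM"] <- "MM"

    sphase <- ifelse(group == "MGUS",
                     stats::rlnorm(n, log(0.6), 0.7),
                     stats::rlnorm(n, log(0.9), 1.0))
    # within-stage standardised log S-phase drives proliferation coupling
    zsph <- numeric(n)
    for (s in unique(stage)) {
      i <- stage == s
      v <- log(sphase[i])
      zsph[i] <- if (sum(i) > 1 && stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else 0
    }

    baseline <- stats::rlnorm(nf, params$baselineMeanLog, params$baselineSdLog)
    names(baseline) <- feats

    fracTarget <- ifelse(group == "MGUS",
                         stats::runif(n, params$nicheFractionMGUS[1L],
                                      params$nicheFractionMGUS[2L]),
                         stats::runif(n, params$nicheFractionMM[1L],
                                      params$nicheFractionMM[2L]))

    coords <- data.frame(x = rep(seq_len(W) - 1L, times = H),
                         y = rep(seq_len(H) - 1L, each = W))
    datasets <- vector("list", n); names(datasets) <- ids
    compartments <- vector("list", n); names(compartments) <- ids
    pcPercent <- numeric(n); names(pcPercent) <- ids
    plasma <- matrix(NA_real_, n, nf, dimnames = list(ids, feats))

    coupled <- params$coupledFeatures
    for (i in seq_len(n)) {
      mask <- .nicheMask(H, W, round(fracTarget[i] * H * W))
      pcPercent[i] <- mean(mask)
      u <- stats::rnorm(nf, 0, params$subjectSdLog2)   # subject random effects
      offN <- params$effects[, "niche", stage[i]] + u
      offM <- params$effects[, "micro", stage[i]] + u
      if (length(coupled))
        offN[coupled] <- offN[coupled] +
          params$couplingBeta * params$couplingSigns[[stage[i]]] * zsph[i]
      logMu <- matrix(log(baseline) + log(2) * offM, nf, H * W)
      rownames(logMu) <- feats
      noiseMult <- rep(1, H * W)
      if (any(mask))
        logMu[, mask] <- log(baseline) + log(2) * offN
      # patchy microenvironment subregions: per-subject spatial heterogeneity.
      # The subregion count varies by subject, so some marrows are nearly
      # uniform and others strongly patchy. Shifts are compositional: they
      # redistribute signal among non-marker features while preserving the
      # expected total ion current, so stromal patches never perturb the
      # relative plasma-cell marker signal after TIC scaling.
      if (params$nMicroRegions > 0) {
        shiftable <- setdiff(feats, params$nicheMarkers)
        nReg <- sample.int(params$nMicroRegions + 1L, 1L) - 1L
        for (k in seq_len(nReg)) {
          fr <- stats::runif(1, params$microRegionFraction[1L],
                             params$microRegionFraction[2L])
          sub <- .nicheMask(H, W, round(fr * H * W)) & !mask
          if (any(sub)) {
            e <- stats::rnorm(length(shiftable), 0, params$microRegionSdLog2)
            w <- baseline[shiftable] * 2^offM[shiftable]
            balance <- log(sum(w)) - log(sum(w * 2^e))
            logMu[shiftable, sub] <- logMu[shiftable, sub] +
              log(2) * e + balance
            noiseMult[sub] <- stats::runif(1, params$microRegionNoiseMult[1L],
                                           params$microRegionNoiseMult[2L])
          }
        }
      }
      intens <- exp(logMu + stats::rnorm(nf * H * W, 0,
                                         rep(params$noiseSigma * noiseMult,
                                             each = nf)))
      dimnames(intens) <- list(feats, NULL)
      datasets[[i]] <- MSIDataset(intens, coords, sectionId = ids[i],
                                  subjectId = ids[i])
      compartments[[i]] <- mask
      nicheMean <- if (any(mask)) rowMeans(intens[, mask, drop = FALSE])
                   else rowMeans(intens)
      indep <- baseline * exp(stats::rnorm(nf, 0, params$bulkSigma))
      plasma[i, ] <- params$bulkCoupling * nicheMean +
        (1 - params$bulkCoupling) * indep
    }

    subjects <- DataFrame(subject_id = ids, group = group, stage = stage,
                          pc_percent = pcPercent, sphase = sphase,
                          row.names = ids)
    subjects$plasma <- plasma
    truth <- list(compartments = compartments, pcPercent = pcPercent,
                  trendFeatures = params$trendFeatures,
                  coupledFeatures = params$coupledFeatures,
                  couplingSigns = params$couplingSigns,
                  nicheMarkers = params$nicheMarkers,
                  microMarkers = params$microMarkers,
                  baseline = baseline, sphaseZ = zsph)
    list(datasets = datasets, subjects = subjects, truth = truth)
  })
}

#' Per-subject compartment mean profiles
#'
#' Collapses each subject's section to mean raw (or TIC-normalised)
#' intensities over a compartment, yielding the subjects-by-metabolites
#' matrix used by the cohort-level statistics (one value per subject, so
#' pixel pseudo-replication never enters two-group tests).
#'
#' @param datasets named list of [MSIDataset-class].
#' @param masks named list of logical per-pixel niche indicators (ground
#'   truth or `isNichePixel()` of a segmentation), same order as `datasets`.
#' @param region `"niche"`, `"micro"`, or `"whole"`.
#' @param assayName assay to average (default raw `"intensities"`).
#' @return numeric matrix subjects x features.
#' @export
subjectMeanMatrix <- function(datasets, masks = NULL,
                              region = c("niche", "micro", "whole"),
                              assayName = "intensities") {
  region <- match.arg(region)
  if (region != "whole" && is.null(masks))
    .msiError("msiValidationError", "masks are required unless region='whole'")
  rows <- lapply(seq_along(datasets), function(i) {
    m <- assay(datasets[[i]], assayName)
    keep <- switch(region,
                   whole = rep(TRUE, ncol(m)),
                   niche = masks[[i]],
                   micro = !masks[[i]])
    if (!any(keep)) rep(NA_real_, nrow(m)) else rowMeans(m[, keep, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(datasets)
  out
}
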