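#' Hill number of order 2 (inverse Simpson concentration)
#'
#' `2D = 1 / sum(p^2)`, the effective number of equally abundant features in
#' an abundance profile; 1 for a single-species profile, `K` for a uniform
#' profile over `K` features. The input must be a valid relative-abundance
#' profile (non-negative, summing to 1).
#'
#' @param p relative-abundance vector.
#' @param tol tolerance on `sum(p) == 1`.
#' @return numeric `2D >= 1`.
#' @export
hillD2 <- function(p, tol = 1e-9) {
  if (any(p < 0))
    .msiError("msiValidationError", "abundances must be non-negative")
  if (abs(sum(p) - 1) > tol)
    .msiError("msiValidationError", "abundance profile must sum to 1")
  1 / sum(p^2)
}

#' Hill-number evenness
#'
#' `E = 2D / K_eff` with `K_eff` the number of strictly positive entries
#' (effective richness); `E = 1` iff the profile is uniform on its support,
#' and appending zero-abundance features leaves `E` unchanged.
#'
#' @inheritParams hillD2
#' @return evenness in `(0, 1]`.
#' @export
evenness <- function(p, tol = 1e-9) {
  keff <- sum(p > 0)
  if (keff == 0)
    .msiError("msiValidationError", "profile has no positive abundances")
  hillD2(p, tol) / keff
}

#' Simpson's diversity index
#'
#' `1 - sum(p^2)` over proportions `p` (renormalised if needed); 0 when a
#' single class holds everything.
#'
#' @param p proportions (or counts).
#' @return Simpson index in `[0, 1)`.
#' @export
simpsonIndex <- function(p) {
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Paired two-community beta diversity at q = 2
#'
#' `beta = 2D_gamma / 2D_alpha,w` for one subject's two compartments.
#' The gamma profile is the pixel-count-weighted pool
#' `(w_a p_a + w_b p_b) / (w_a + w_b)`. The within-community alpha is either
#' the weighted *arithmetic* mean of the two `2D` values (the literal
#' pixel/count-weighted-mean definition, default) or the weighted
#' *harmonic* mean `1 / ((w_a C_a + w_b C_b) / (w_a + w_b))` with
#' `C = sum(p^2)` (Jost's alpha for q = 2), which guarantees `beta >= 1`
#' by convexity of the squared pooled profile. Under the arithmetic option
#' `beta < 1` can occur and is reported via a diagnostic message.
#'
#' @param pA,pB relative-abundance profiles over the same feature universe.
#' @param wA,wB positive community weights (pixel counts).
#' @param alphaMean `"arithmetic"` (default) or `"jost"`.
#' @param tol tolerance on profile normalisation.
#' @return numeric beta (1 for identical profiles under both options).
#' @export
betaTwoCommunity <- function(pA, pB, wA, wB,
                             alphaMean = c("arithmetic", "jost"),
                             tol = 1e-9) {
  alphaMean <- match.arg(alphaMean)
  if (length(pA) != length(pB))
    .msiError("msiValidationError", "profiles must share one feature universe")
  if (wA <= 0 || wB <= 0)
    .msiError("msiValidationError", "weights must be positive")
  dA <- hillD2(pA, tol); dB <- hillD2(pB, tol)
  gamma <- (wA * pA + wB * pB) / (wA + wB)
  dG <- hillD2(gamma, tol)
  alpha <- if (alphaMean == "arithmetic") {
    (wA * dA + wB * dB) / (wA + wB)
  } else {
    (wA + wB) / (wA * sum(pA^2) + wB * sum(pB^2))
  }
  beta <- dG / alpha
  if (alphaMean == "arithmetic" && beta < 1 - 1e-12)
    message(sprintf("beta = %.4f < 1 under the arithmetic alpha option", beta))
  beta
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`; ties contribute
#' zero. With `x` = MGUS and `y` = MM, negative values indicate higher
#' values in MM.
#'
#' @param x,y numeric samples (both non-empty).
#' @return delta in `[-1, 1]`.
#' @export
cliffsDelta <- function(x, y) {
  if (!length(x) || !length(y))
    .msiError("msiValidationError", "both samples must be non-empty")
  mean(sign(outer(x, y, "-")))
}

#' HC3-robust regression of evenness on plasma-cell percentage
#'
#' OLS of `logit(evenness)` on `logit(pc_percent)` (both epsilon-clamped)
#' with the HC3 heteroskedasticity-consistent covariance
#' `(X'X)^-1 X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^-1` and a two-sided t
#' test on the slope (n - 2 degrees of freedom).
#'
#' @param evennessValues per-subject evenness in (0, 1].
#' @param pcPercent per-subject plasma-cell fractions.
#' @param eps clamping epsilon for the logits.
#' @return list `slope`, `se_hc3`, `t`, `p_hc3`, `fit` (the `lm` object).
#' @export
evennessVsPcRegression <- function(evennessValues, pcPercent, eps = 1e-6) {
  if (length(evennessValues) < 4)
    .msiError("msiValidationError", "need at least 4 subjects")
  x <- logitTransform(pcPercent, eps)
  y <- logitTransform(evennessValues, eps)
  if (stats::sd(x) == 0)
    .msiError("msiValidationError", "predictor is collinear (constant)")
  fit <- stats::lm(y ~ x)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  ct <- lmtest::coeftest(fit, vcov. = vc)
  list(slope = unname(stats::coef(fit)["x"]),
       se_hc3 = ct["x", "Std. Error"],
       t = ct["x", "t value"], p_hc3 = ct["x", "Pr(>|t|)"], fit = fit)
}

#' Per-subject diversity report with cohort inference
#'
#' Builds, for every subject, TIC-normalised mean abundance profiles of the
#' plasma-cell-rich and microenvironment compartments (renormalised to sum
#' to 1 over the feature panel; raw TIC intensities, never z-scores, so
#' abundances stay non-negative), and computes the Hill `2D` of each
#' compartment, within-niche evenness, and the paired two-community beta
#' with pixel-count weights. Cohort-level inference is attached via
#' [cohortDiversityTests()].
#'
#' @param datasets named list of [MSIDataset-class] (raw; TIC normalisation
#'   is applied internally).
#' @param masks named list of logical niche indicators per pixel (ground
#'   truth or called segmentation).
#' @param subjects DataFrame with `subject_id`, `group`, `pc_percent`.
#' @param features optional feature panel to restrict profiles to.
#' @param alphaMean alpha-mean option passed to [betaTwoCommunity()].
#' @return list with `perSubject` (data.frame: `subject_id`, `group`,
#'   `pc_percent`, `d2_niche`, `d2_micro`, `keff_niche`, `evenness_niche`,
#'   `beta`, `w_niche`) and `cohort` (see [cohortDiversityTests()]).
#' @export
diversityReport <- function(datasets, masks, subjects, features = NULL,
                            alphaMean = "arithmetic") {
  stopifnot(length(datasets) == length(masks))
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    raw <- assay(d, "intensities")
    if (!is.null(features)) raw <- raw[features, , drop = FALSE]
    tic <- sweep(raw, 2, colSums(assay(d, "intensities")), "/")
    m <- masks[[i]]
    if (!any(m) || all(m))
      .msiError("msiValidationError",
                sprintf("section %d has an empty compartment", i))
    profile <- function(keep) {
      v <- rowMeans(tic[, keep, drop = FALSE])
      v / sum(v)
    }
    pN <- profile(m); pM <- profile(!m)
    wN <- sum(m); wM <- sum(!m)
    data.frame(subject_id = names(datasets)[i],
               d2_niche = hillD2(pN), d2_micro = hillD2(pM),
               keff_niche = sum(pN > 0),
               evenness_niche = evenness(pN),
               beta = betaTwoCommunity(pN, pM, wN, wM, alphaMean),
               w_niche = wN / (wN + wM), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  idx <- match(per$subject_id, subjects$subject_id)
  per$group <- subjects$group[idx]
  per$pc_percent <- subjects$pc_percent[idx]
  per <- per[, c("subject_id", "group", "pc_percent", "d2_niche", "d2_micro",
                 "keff_niche", "evenness_niche", "beta", "w_niche")]
  list(perSubject = per, cohort = cohortDiversityTests(per))
}

#' Cohort-level diversity tests
#'
#' Two-sided Mann-Whitney tests of within-niche evenness and paired beta
#' between MGUS and MM, Cliff's delta for both (MGUS-vs-MM orientation, so
#' negative delta means higher values in MM), and the HC3-robust
#' evenness-vs-plasma-cell-percentage regression.
#'
#' @param perSubject data.frame as produced by [diversityReport()] (columns
#'   `group`, `evenness_niche`, `beta`, `pc_percent`).
#' @return list `mw_p_evenness`, `mw_p_beta`, `cliffs_delta_evenness`,
#'   `cliffs_delta_beta`, `ols_slope`, `ols_hc3_p`.
#' @export
cohortDiversityTests <- function(perSubject) {
  g <- perSubject$group
  if (sum(g == "MGUS") < 3 || sum(g == "MM") < 3)
    .msiError("msiValidationError", "need at least 3 subjects per group")
  ev <- perSubject$evenness_niche
  be <- perSubject$beta
  mwE <- suppressWarnings(stats::wilcox.test(ev[g == "MGUS"], ev[g == "MM"],
                                             exact = FALSE))
  mwB <- suppressWarnings(stats::wilcox.test(be[g == "MGUS"], be[g == "MM"],
                                             exact = FALSE))
  reg <- evennessVsPcRegression(ev, perSubject$pc_percent)
  list(mw_p_evenness = mwE$p.value, mw_p_beta = mwB$p.value,
       cliffs_delta_evenness = cliffsDelta(ev[g == "MGUS"], ev[g == "MM"]),
       cliffs_delta_beta = cliffsDelta(be[g == "MGUS"], be[g == "MM"]),
       ols_slope = reg$slope, ols_hc3_p = reg$p_hc3)
}
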