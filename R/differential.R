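#' Assumption-routed two-group test
#'
#' Routes a two-group comparison through the classical decision tree:
#' Shapiro-Wilk normality on each group; if both pass (p >= `shapiroAlpha`),
#' a Brown-Forsythe Levene test (median-centred) decides between Student's
#' t (equal variances) and Welch's t; if either group is non-normal, a
#' two-sided Mann-Whitney U is used (exact when both groups have n <= 8 and
#' no ties, normal approximation with tie correction otherwise). Groups in
#' which every value is identical are treated as non-normal; when both
#' groups are entirely identical the result is `p = 1` with a degenerate
#' flag.
#'
#' @param x,y numeric group values (each n >= 3).
#' @param alpha significance level carried into the result (not used for
#'   routing).
#' @param shapiroAlpha alpha for the Shapiro-Wilk routing decision.
#' @param leveneAlpha alpha for the variance-homogeneity decision.
#' @return list with `test_used` (`"student_t"`, `"welch_t"`,
#'   `"mann_whitney"`), `statistic`, `p`, and `degenerate`.
#' @export
routeAndTest <- function(x, y, alpha = 0.05, shapiroAlpha = 0.05,
                         leveneAlpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3)
    .msiError("msiValidationError", "each group needs at least 3 values")
  if (stats::sd(c(x, y)) == 0)
    return(list(test_used = "mann_whitney", statistic = 0, p = 1,
                degenerate = TRUE))
  normp <- function(v) {
    if (stats::sd(v) == 0) return(0)   # constant group: not normal
    stats::shapiro.test(v)$p.value
  }
  bothNormal <- normp(x) >= shapiroAlpha && normp(y) >= shapiroAlpha
  if (bothNormal) {
    lev <- car::leveneTest(c(x, y),
                           factor(rep(c("a", "b"), c(length(x), length(y)))),
                           center = stats::median)
    equalVar <- lev[["Pr(>F)"]][1L] >= leveneAlpha
    tt <- stats::t.test(x, y, var.equal = equalVar)
    list(test_used = if (equalVar) "student_t" else "welch_t",
         statistic = unname(tt$statistic), p = tt$p.value,
         degenerate = FALSE)
  } else {
    exact <- length(x) <= 8 && length(y) <= 8 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    list(test_used = "mann_whitney", statistic = unname(wt$statistic),
         p = wt$p.value, degenerate = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' the mapping is order-preserving and an empty input yields an empty
#' output.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted q-values, same order as the input.
#' @export
bhAdjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    .msiError("msiValidationError", "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Volcano table: routed tests plus fold changes for every metabolite
#'
#' Log2 fold changes are computed on raw (unlogged) intensity means,
#' MM over MGUS; significance requires both `q < alpha` and
#' `|log2fc| >= fcThreshold`. Zero group means are offset by `eps` and
#' flagged.
#'
#' @param mat numeric matrix, subjects x metabolites (raw intensities).
#' @param groups factor/character of `"MGUS"`/`"MM"` per subject.
#' @param alpha significance level applied to BH q-values.
#' @param fcThreshold log2 fold-change threshold (default `log2(1.5)`
#'   rounded to two decimals).
#' @param eps offset used when a group mean is exactly zero.
#' @return data.frame with one row per metabolite: `metabolite`,
#'   `test_used`, `statistic`, `p`, `q`, `log2fc`, `flag`
#'   (`"up_in_MM"`, `"up_in_MGUS"`, `"ns"`), `zero_mean`.
#' @export
volcano <- function(mat, groups, alpha = 0.05, fcThreshold = 0.58,
                    eps = 1e-9) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2)
    .msiError("msiValidationError", "need at least 2 metabolites")
  groups <- as.character(groups)
  if (!all(groups %in% .GROUPS))
    .msiError("msiValidationError", "groups must be MGUS or MM")
  gm <- groups == "MGUS"
  res <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[gm, j]; y <- mat[!gm, j]
    rt <- routeAndTest(x, y, alpha)
    mMGUS <- mean(x); mMM <- mean(y)
    zero <- mMGUS == 0 || mMM == 0
    fc <- log2((mMM + if (mMM == 0) eps else 0) /
               (mMGUS + if (mMGUS == 0) eps else 0))
    data.frame(metabolite = colnames(mat)[j] %||% sprintf("m%d", j),
               test_used = rt$test_used, statistic = rt$statistic,
               p = rt$p, log2fc = fc, zero_mean = zero,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out$flag <- "ns"
  sig <- out$q < alpha & abs(out$log2fc) >= fcThreshold
  out$flag[sig & out$log2fc > 0] <- "up_in_MM"
  out$flag[sig & out$log2fc < 0] <- "up_in_MGUS"
  out[, c("metabolite", "test_used", "statistic", "p", "q", "log2fc",
          "flag", "zero_mean")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.FCFC_CLASSES <- c("both_up", "both_down", "tissue_up_only",
                   "tissue_down_only", "plasma_up_only", "plasma_down_only",
                   "tissue_up_plasma_down", "tissue_down_plasma_up",
                   "unchanged")

#' Eight-way directional fold-change classification
#'
#' Classifies each metabolite by its tissue and plasma log2 fold changes
#' (MM vs MGUS) against a symmetric threshold `t` (default 0.58, a 1.5-fold
#' change): both beyond `+t` / `-t` give the concordant classes, exactly one
#' axis beyond the threshold gives the four "only" classes, opposite signs
#' both beyond it give the two offset classes, anything else is
#' `"unchanged"`.
#'
#' @param log2fcTissue,log2fcPlasma numeric vectors of log2 fold changes.
#' @param threshold positive log2 threshold.
#' @return character vector of class labels.
#' @export
fcfcClassify <- function(log2fcTissue, log2fcPlasma, threshold = 0.58) {
  if (threshold <= 0)
    .msiError("msiValidationError", "threshold must be positive")
  t <- log2fcTissue; p <- log2fcPlasma
  tc <- ifelse(t >= threshold, 1L, ifelse(t <= -threshold, -1L, 0L))
  pc <- ifelse(p >= threshold, 1L, ifelse(p <= -threshold, -1L, 0L))
  out <- rep("unchanged", length(t))
  out[tc == 1 & pc == 1]   <- "both_up"
  out[tc == -1 & pc == -1] <- "both_down"
  out[tc == 1 & pc == 0]   <- "tissue_up_only"
  out[tc == -1 & pc == 0]  <- "tissue_down_only"
  out[tc == 0 & pc == 1]   <- "plasma_up_only"
  out[tc == 0 & pc == -1]  <- "plasma_down_only"
  out[tc == 1 & pc == -1]  <- "tissue_up_plasma_down"
  out[tc == -1 & pc == 1]  <- "tissue_down_plasma_up"
  out[is.na(t) | is.na(p)] <- NA_character_
  out
}

#' Build the tissue-by-plasma FC-FC table
#'
#' Matches metabolites by exact identifier between the two compartments,
#' classifies them with [fcfcClassify()], and drops (with a message)
#' metabolites whose fold change is not finite in either compartment.
#'
#' @param tissueFC,plasmaFC named numeric vectors of log2 fold changes.
#' @param threshold positive log2 threshold.
#' @return data.frame `metabolite`, `log2fc_tissue`, `log2fc_plasma`,
#'   `class` over the shared metabolites.
#' @export
fcfcTable <- function(tissueFC, plasmaFC, threshold = 0.58) {
  shared <- intersect(names(tissueFC), names(plasmaFC))
  if (!length(shared))
    .msiError("msiValidationError", "no shared metabolites between compartments")
  t <- tissueFC[shared]; p <- plasmaFC[shared]
  ok <- is.finite(t) & is.finite(p)
  if (any(!ok))
    message(sprintf("excluding %d metabolite(s) with non-finite fold change",
                    sum(!ok)))
  data.frame(metabolite = shared[ok],
             log2fc_tissue = unname(t[ok]), log2fc_plasma = unname(p[ok]),
             class = fcfcClassify(t[ok], p[ok], threshold),
             stringsAsFactors = FALSE)
}

#' Tally FC-FC classes by pathway
#'
#' Contingency counts of metabolites per (class, super-pathway,
#' sub-pathway), suitable for Sankey-style rendering. Unannotated
#' metabolites count under `"other"`; empty combinations are absent
#' (no zero rows).
#'
#' @param table data.frame from [fcfcTable()].
#' @param map a [PathwayMap-class].
#' @return data.frame `class`, `super_pathway`, `sub_pathway`, `n`.
#' @export
pathwayTally <- function(table, map) {
  stopifnot(is(map, "PathwayMap"))
  if (!nrow(table))
    return(data.frame(class = character(), super_pathway = character(),
                      sub_pathway = character(), n = integer()))
  sup <- suppressMessages(superPathway(map, table$metabolite))
  sub <- subPathway(map, table$metabolite)
  agg <- stats::aggregate(list(n = rep(1L, nrow(table))),
                          by = list(class = table$class, super_pathway = sup,
                                    sub_pathway = sub), FUN = sum)
  agg[order(agg$class, -agg$n), , drop = FALSE]
}
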