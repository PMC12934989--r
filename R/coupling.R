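#' Metabolite-proliferation correlations per disease stage
#'
#' For every metabolite and every stage subset with at least `minN`
#' subjects, correlates the subject-level compartment mean against the
#' S-phase proliferation score (Pearson with p-value, Spearman, and the
#' simple-regression slope of proliferation on the metabolite z-score —
#' whose sign equals the Pearson sign by construction). Zero-variance
#' metabolites yield `NA` with a flag.
#'
#' @param tissueMeans numeric matrix, subjects x metabolites.
#' @param sphase per-subject proliferation score.
#' @param stages per-subject stage labels; use a single constant label to
#'   pool all subjects.
#' @param minN minimum subjects per stage subset (default 4).
#' @return data.frame `stage`, `metabolite`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `slope_beta1`, `flag_constant`.
#' @export
proliferationCorrelations <- function(tissueMeans, sphase, stages,
                                      minN = 4L) {
  tissueMeans <- as.matrix(tissueMeans)
  stopifnot(nrow(tissueMeans) == length(sphase),
            length(stages) == length(sphase))
  out <- list()
  for (s in unique(stages)) {
    i <- which(stages == s)
    if (length(i) < minN) next
    sp <- sphase[i]
    for (j in seq_len(ncol(tissueMeans))) {
      v <- tissueMeans[i, j]
      if (stats::sd(v) == 0 || stats::sd(sp) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          stage = s, metabolite = colnames(tissueMeans)[j],
          pearson_r = NA_real_, pearson_p = NA_real_,
          spearman_rho = NA_real_, slope_beta1 = NA_real_,
          flag_constant = TRUE, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(v, sp, method = "pearson")
      rho <- stats::cor(v, sp, method = "spearman")
      z <- (v - mean(v)) / stats::sd(v)
      beta1 <- stats::cov(z, sp) / stats::var(z)   # = r * sd(sphase)
      out[[length(out) + 1L]] <- data.frame(
        stage = s, metabolite = colnames(tissueMeans)[j],
        pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
        spearman_rho = rho, slope_beta1 = beta1,
        flag_constant = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    .msiError("msiValidationError",
              sprintf("no stage subset has >= %d subjects", minN))
  do.call(rbind, out)
}

#' Segmentation gain in correlation strength
#'
#' The improvement `delta_abs_rho = |rho_niche| - |rho_whole|` obtained by
#' correlating within the segmented plasma-cell-rich region instead of the
#' whole marrow, sorted descending. Depends only on the magnitudes of the
#' two correlations.
#'
#' @param rhoNiche,rhoWhole named numeric vectors of per-metabolite
#'   correlations over a matched metabolite list.
#' @return data.frame `metabolite`, `rho_niche`, `rho_whole`,
#'   `delta_abs_rho`, sorted by decreasing gain.
#' @export
segmentationGain <- function(rhoNiche, rhoWhole) {
  if (is.null(names(rhoNiche)) || is.null(names(rhoWhole)) ||
      !setequal(names(rhoNiche), names(rhoWhole)) ||
      length(rhoNiche) != length(rhoWhole))
    .msiError("msiValidationError", "metabolite lists must match")
  rhoWhole <- rhoWhole[names(rhoNiche)]
  d <- abs(rhoNiche) - abs(rhoWhole)
  out <- data.frame(metabolite = names(rhoNiche),
                    rho_niche = unname(rhoNiche),
                    rho_whole = unname(rhoWhole),
                    delta_abs_rho = unname(d), stringsAsFactors = FALSE)
  out[order(-out$delta_abs_rho), , drop = FALSE]
}

#' Correlation-partner sets around an anchor metabolite
#'
#' Pearson-correlates the anchor against every other metabolite and
#' partitions partners at `+/- rThreshold` (no p-value filter is applied);
#' the anchor itself belongs to neither set.
#'
#' @param anchor metabolite id present in `mat`.
#' @param mat numeric matrix, subjects x metabolites (n >= 5 subjects).
#' @param rThreshold positive Pearson threshold (default 0.30).
#' @return list with `positive`, `negative` (character vectors) and `r`
#'   (named vector of all anchor correlations).
#' @export
correlationPartnerSets <- function(anchor, mat, rThreshold = 0.30) {
  mat <- as.matrix(mat)
  if (!anchor %in% colnames(mat))
    .msiError("msiValidationError", sprintf("anchor '%s' not in matrix", anchor))
  if (nrow(mat) < 5)
    .msiError("msiValidationError", "need at least 5 subjects")
  a <- mat[, anchor]
  if (stats::sd(a) == 0)
    .msiError("msiValidationError", "anchor is constant")
  others <- setdiff(colnames(mat), anchor)
  r <- vapply(others, function(m) {
    v <- mat[, m]
    if (stats::sd(v) == 0) NA_real_ else stats::cor(a, v)
  }, numeric(1))
  list(positive = others[!is.na(r) & r > rThreshold],
       negative = others[!is.na(r) & r < -rThreshold],
       r = r)
}

#' Pathway over-representation by the hypergeometric upper tail
#'
#' For each pathway, tests whether the metabolite set overlaps the pathway
#' more than expected when drawing `length(set)` metabolites uniformly from
#' the background (one-sided hypergeometric upper tail). Pathways are
#' ranked by ascending p; the top `k` are returned together with the
#' metabolite ratio `overlap / set size`.
#'
#' @param set metabolite ids (must be a subset of `background`).
#' @param background metabolite universe (e.g. all metabolites detected in
#'   the same compartment).
#' @param map a [PathwayMap-class].
#' @param k number of top pathways to report (default 5).
#' @param level annotate at `"sub"`- or `"super"`-pathway level.
#' @return data.frame `pathway`, `overlap`, `set_size`, `pathway_size`,
#'   `background_size`, `p`, `metabolite_ratio`, ascending in `p`.
#' @export
pathwayOverrepresentation <- function(set, background, map, k = 5L,
                                      level = c("sub", "super")) {
  stopifnot(is(map, "PathwayMap"))
  level <- match.arg(level)
  if (!all(set %in% background))
    .msiError("msiValidationError", "set must be a subset of background")
  if (!length(set))
    return(data.frame(pathway = character(), overlap = integer(),
                      set_size = integer(), pathway_size = integer(),
                      background_size = integer(), p = numeric(),
                      metabolite_ratio = numeric()))
  ann <- suppressMessages(
    if (level == "sub") subPathway(map, background)
    else superPathway(map, background))
  names(ann) <- background
  N <- length(background); n <- length(set)
  res <- lapply(unique(ann), function(pw) {
    members <- background[ann == pw]
    m <- length(members)
    ov <- length(intersect(set, members))
    p <- stats::phyper(ov - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, set_size = n, pathway_size = m,
               background_size = N, p = p, metabolite_ratio = ov / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p), , drop = FALSE]
  utils::head(out, k)
}

#' Pairwise correlation network for a pathway's metabolites
#'
#' All pairwise Pearson correlations among the pathway members plus edges
#' from each member to every other detected metabolite; edges with
#' `p < alpha` are flagged significant. When `groups` is supplied the
#' network is computed separately per group (panels may differ in which
#' members are detected).
#'
#' @param members pathway metabolite ids present in `mat` (>= 2).
#' @param mat numeric matrix, subjects x metabolites.
#' @param alpha significance level for edge flagging.
#' @param groups optional per-subject group labels.
#' @return data.frame `group`, `from`, `to`, `r`, `p`, `significant`
#'   (member-member edges listed once; member-other edges included).
#' @export
pairwisePathwayNetwork <- function(members, mat, alpha = 0.05,
                                   groups = NULL) {
  mat <- as.matrix(mat)
  members <- intersect(members, colnames(mat))
  if (length(members) < 2)
    .msiError("msiValidationError", "need at least 2 detected pathway members")
  runOne <- function(m, label) {
    edge <- function(a, b) {
      va <- m[, a]; vb <- m[, b]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0)
        return(data.frame(group = label, from = a, to = b, r = NA_real_,
                          p = NA_real_, significant = FALSE))
      ct <- stats::cor.test(va, vb)
      data.frame(group = label, from = a, to = b,
                 r = unname(ct$estimate), p = ct$p.value,
                 significant = ct$p.value < alpha, stringsAsFactors = FALSE)
    }
    pairs <- utils::combn(members, 2L)
    mm <- lapply(seq_len(ncol(pairs)), function(i) edge(pairs[1L, i], pairs[2L, i]))
    others <- setdiff(colnames(m), members)
    mo <- lapply(members, function(a) lapply(others, function(b) edge(a, b)))
    do.call(rbind, c(mm, unlist(mo, recursive = FALSE)))
  }
  if (is.null(groups)) return(runOne(mat, "all"))
  do.call(rbind, lapply(unique(groups), function(g)
    runOne(mat[groups == g, , drop = FALSE], g)))
}

#' Per-pathway regression-slope summaries
#'
#' Summarises the per-metabolite proliferation regression slopes (`beta1`
#' from [proliferationCorrelations()]) by pathway and stage: the slope
#' distribution plus counts of positively and negatively coupled
#' metabolites. Pathways with no metabolites are omitted.
#'
#' @param coupling data.frame from [proliferationCorrelations()].
#' @param map a [PathwayMap-class].
#' @param level `"super"` or `"sub"` pathway level.
#' @return data.frame `stage`, `pathway`, `n`, `n_positive`, `n_negative`,
#'   `beta_median`, `beta_min`, `beta_max`.
#' @export
pathwaySlopeSummary <- function(coupling, map, level = c("super", "sub")) {
  stopifnot(is(map, "PathwayMap"))
  level <- match.arg(level)
  cp <- coupling[!coupling$flag_constant & is.finite(coupling$slope_beta1), ]
  if (!nrow(cp))
    return(data.frame(stage = character(), pathway = character(),
                      n = integer(), n_positive = integer(),
                      n_negative = integer(), beta_median = numeric(),
                      beta_min = numeric(), beta_max = numeric()))
  cp$pathway <- suppressMessages(
    if (level == "super") superPathway(map, cp$metabolite)
    else subPathway(map, cp$metabolite))
  sp <- split(cp, list(cp$stage, cp$pathway), drop = TRUE)
  out <- lapply(sp, function(d) data.frame(
    stage = d$stage[1L], pathway = d$pathway[1L], n = nrow(d),
    n_positive = sum(d$slope_beta1 > 0), n_negative = sum(d$slope_beta1 < 0),
    beta_median = stats::median(d$slope_beta1),
    beta_min = min(d$slope_beta1), beta_max = max(d$slope_beta1),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$stage, out$pathway), , drop = FALSE]
}
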