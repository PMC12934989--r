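#' PCA scores with a deterministic sign convention
#'
#' Centred (optionally unit-scaled) principal components via SVD. Each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive, making repeated runs bit-identical.
#'
#' @param mat numeric matrix, samples x features.
#' @param nComponents number of components to return.
#' @param scale. unit-scale features before the decomposition.
#' @return list `scores` (samples x components), `loadings`,
#'   `explained` (fraction of variance per component).
#' @export
pcaScores <- function(mat, nComponents = 2L, scale. = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2)
    .msiError("msiValidationError", "need at least 2 samples")
  sds <- apply(mat, 2, stats::sd)
  if (all(sds == 0))
    .msiError("msiValidationError", "constant matrix has no principal components")
  if (scale.) mat <- mat[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  k <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  list(scores = sc, loadings = rot,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

# Gower-style sums of squares from a distance matrix
.permanovaSS <- function(d2, groups) {
  n <- nrow(d2)
  ssTot <- sum(d2[upper.tri(d2)]) / n
  ssW <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) > 1)
      ssW <- ssW + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  c(total = ssTot, within = ssW, between = ssTot - ssW)
}

#' PERMANOVA with seeded permutation inference
#'
#' One-way permutational multivariate analysis of variance on a distance
#' matrix. Sums of squares come from the pairwise-distance identity
#' (total SS = sum of squared distances / n, within-group SS analogously
#' per group), the pseudo-F is `(SS_b / df_b) / (SS_w / df_w)`, and the
#' p-value is `(1 + #\{F_perm >= F_obs\}) / (1 + nPerm)` under random
#' relabelling — never reported as 0.
#'
#' @param x samples x features matrix (Euclidean distances are computed,
#'   optionally after per-feature z-scoring) or a `dist` object.
#' @param groups per-sample group labels (>= 2 groups, each n >= 2).
#' @param nPerm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param zscore z-score features before the Euclidean distance (ignored
#'   for `dist` input).
#' @return list `r2`, `f_stat`, `p`, `n_perm`, `ss`.
#' @export
permanova <- function(x, groups, nPerm = 999L, seed = 1L, zscore = TRUE) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2)
    .msiError("msiValidationError", "need at least 2 groups")
  if (any(table(groups) < 2))
    .msiError("msiValidationError", "each group needs at least 2 samples")
  d <- if (inherits(x, "dist")) x else {
    m <- as.matrix(x)
    if (zscore) m <- .zscoreCols(m)
    stats::dist(m)
  }
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  if (n != length(groups))
    .msiError("msiValidationError", "groups must match the number of samples")
  dfB <- length(unique(groups)) - 1L
  dfW <- n - length(unique(groups))
  fOf <- function(g) {
    ss <- .permanovaSS(d2, g)
    (ss["between"] / dfB) / (ss["within"] / dfW)
  }
  ss <- .permanovaSS(d2, groups)
  fObs <- unname((ss["between"] / dfB) / (ss["within"] / dfW))
  exceed <- .withSeed(seed, {
    sum(vapply(seq_len(nPerm),
               function(i) unname(fOf(sample(groups))) >= fObs, logical(1)))
  })
  list(r2 = unname(ss["between"] / ss["total"]), f_stat = fObs,
       p = (1 + exceed) / (1 + nPerm), n_perm = as.integer(nPerm),
       ss = ss)
}

# one-response NIPALS PLS; returns per-component weights and explained SSY
.pls1 <- function(X, y, A) {
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- y - mean(y)
  p <- ncol(X)
  W <- matrix(0, p, A); ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1L), drop = FALSE]
                      ssy <- ssy[seq_len(a - 1L)]; break }
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    pLoad <- drop(crossprod(X, t)) / tt
    q <- sum(y * t) / tt
    ssy[a] <- q^2 * tt            # response variance captured by component a
    X <- X - tcrossprod(t, pLoad)
    y <- y - q * t
    W[, a] <- w
  }
  list(W = W, ssy = ssy)
}

#' Variable importance in projection (VIP) per spatial cluster
#'
#' Fits a NIPALS partial-least-squares model of a one-vs-rest cluster
#' indicator on the pixel (or sample) feature matrix and scores each
#' feature by `VIP_j = sqrt(p * sum_a(SSY_a w_ja^2) / sum_a SSY_a)`, so the
#' mean squared VIP over features is exactly 1. The top `k` features per
#' cluster are reported, with flags for features shared by the top-k lists
#' of two or more clusters.
#'
#' @param mat numeric matrix, samples x features.
#' @param labels per-sample cluster labels (>= 2 distinct values), or a
#'   two-level response for a single model.
#' @param nComponents PLS components (default 2, capped at `n - 1`).
#' @param topK length of the per-cluster ranking (default 20).
#' @return list with `vip` (features x clusters matrix), `top` (list of
#'   ranked top-k feature ids per cluster), `shared` (features in the
#'   top-k of >= 2 clusters).
#' @export
plsVip <- function(mat, labels, nComponents = 2L, topK = 20L) {
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2)
    .msiError("msiValidationError", "response has a single class")
  if (nrow(mat) <= nComponents)
    .msiError("msiValidationError", "need more samples than components")
  p <- ncol(mat)
  feats <- colnames(mat) %||% sprintf("f%d", seq_len(p))
  clusters <- if (length(lev) == 2) lev[1L] else lev
  vip <- matrix(NA_real_, p, length(clusters),
                dimnames = list(feats, as.character(clusters)))
  for (cl in clusters) {
    y <- as.numeric(labels == cl)
    fit <- .pls1(mat, y, min(nComponents, nrow(mat) - 1L))
    if (!ncol(fit$W))
      .msiError("msiValidationError", "degenerate response or predictors")
    num <- drop(fit$W^2 %*% fit$ssy)
    vip[, as.character(cl)] <- sqrt(p * num / sum(fit$ssy))
  }
  top <- lapply(as.data.frame(vip), function(v)
    feats[order(-v)][seq_len(min(topK, p))])
  names(top) <- colnames(vip)
  counts <- table(unlist(top))
  list(vip = vip, top = top,
       shared = names(counts)[counts >= 2])
}

#' Monotone stage-trend screen (trend volcano)
#'
#' Spearman-correlates each metabolite's subject-level value against the
#' ordered stage code (non-progressive MGUS = 0, progressive MGUS = 1,
#' MM = 2; the spacing is irrelevant to Spearman), BH-adjusts across
#' metabolites, and flags monotone increasers (`rho > 0` and `q < alpha`).
#' With `strict = TRUE` the flag additionally requires non-decreasing
#' stage medians.
#'
#' @param mat numeric matrix, subjects x metabolites.
#' @param stages per-subject stage labels (levels of `.STAGES` or integer
#'   codes); at least 2 distinct stages.
#' @param alpha significance level on q-values.
#' @param strict require non-decreasing stage medians as well.
#' @return data.frame `metabolite`, `spearman_rho`, `p`, `q`,
#'   `monotone_flag`.
#' @export
trendVolcano <- function(mat, stages, alpha = 0.05, strict = FALSE) {
  mat <- as.matrix(mat)
  code <- if (is.numeric(stages)) stages
          else as.integer(factor(stages, levels = .STAGES)) - 1L
  if (length(unique(code)) < 2)
    .msiError("msiValidationError", "all subjects are in one stage")
  res <- lapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    if (stats::sd(v) == 0)
      return(data.frame(metabolite = colnames(mat)[j], spearman_rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(v, code, method = "spearman",
                                           exact = FALSE))
    data.frame(metabolite = colnames(mat)[j] %||% sprintf("m%d", j),
               spearman_rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p)
  out$q[ok] <- bhAdjust(out$p[ok])
  out$monotone_flag <- !is.na(out$q) & out$spearman_rho > 0 & out$q < alpha
  if (strict) {
    for (j in which(out$monotone_flag)) {
      med <- tapply(mat[, j], code, stats::median)
      if (any(diff(med[order(as.numeric(names(med)))]) < 0))
        out$monotone_flag[j] <- FALSE
    }
  }
  out
}
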