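#' Normalize pixel spectra
#'
#' Adds two assays to an [MSIDataset-class]: `"tic"`, each pixel scaled to
#' unit total ion current, and `"norm"`, `log1p` of the TIC-scaled values
#' z-scored per feature across the pixels of the section (constant features
#' are left at zero rather than divided by a zero standard deviation).
#' Pixels whose total ion current is zero are dropped with a warning.
#' The TIC step is idempotent: renormalising already TIC-scaled pixels
#' changes nothing.
#'
#' @param data an [MSIDataset-class].
#' @return the dataset with `"tic"` and `"norm"` assays added (possibly
#'   fewer pixels).
#' @export
normalizePixels <- function(data) {
  stopifnot(is(data, "MSIDataset"))
  raw <- assay(data, "intensities")
  tic <- colSums(raw)
  if (any(tic == 0)) {
    warning(sprintf("dropping %d all-zero pixel(s)", sum(tic == 0)))
    data <- data[, tic > 0]
    raw <- assay(data, "intensities")
    tic <- colSums(raw)
  }
  ticm <- sweep(raw, 2, tic, "/")
  norm <- t(.zscoreCols(t(log1p(ticm))))
  assays(data)[["tic"]] <- ticm
  assays(data)[["norm"]] <- norm
  data
}

# squared-Euclidean within-cluster sum of squares around the centroid
.sse <- function(m) {
  if (nrow(m) < 2L) return(0)
  sum(sweep(m, 2, colMeans(m), "-")^2)
}

# k-means++ initial centers for k = 2
.kppInit <- function(m) {
  i1 <- sample.int(nrow(m), 1L)
  d2 <- rowSums(sweep(m, 2, m[i1, ], "-")^2)
  if (all(d2 == 0)) return(NULL)
  i2 <- sample.int(nrow(m), 1L, prob = d2)
  rbind(m[i1, ], m[i2, ])
}

# best-of-`restarts` 2-means split; returns list(assign (1/2), sse) or NULL
.bestSplit <- function(m, restarts) {
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- .kppInit(m)
    if (is.null(cen)) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = cen, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2L) next
    if (is.null(best) || km$tot.withinss < best$sse)
      best <- list(assign = km$cluster, sse = km$tot.withinss)
  }
  best
}

#' Bisecting k-means segmentation
#'
#' Partitions pixels by repeated binary splits: starting from a single
#' cluster, the cluster with the largest within-cluster sum of squared
#' Euclidean distances is split by 2-means (k-means++ initialisation, best
#' of `restarts` runs by SSE, ties broken by the earliest restart) until
#' `K` clusters exist. Deterministic given `seed`.
#'
#' @param x numeric matrix, observations (pixels) in rows — typically
#'   `pixelMatrix(data, "norm")` — or an [MSIDataset-class] that has been
#'   normalised.
#' @param K number of final clusters (>= 1, <= number of rows).
#' @param seed RNG seed for initialisation.
#' @param restarts 2-means restarts per split.
#' @return a [SegmentationResult-class] with labels in `1..K` and a split
#'   tree of exactly `K - 1` rows.
#' @export
bisectingKmeans <- function(x, K, seed = 1L, restarts = 10L) {
  if (is(x, "MSIDataset")) x <- pixelMatrix(x, "norm")
  x <- as.matrix(x)
  n <- nrow(x)
  if (K < 1L) .msiError("msiValidationError", "K must be >= 1")
  if (K > n) .msiError("msiValidationError", "K cannot exceed the number of pixels")
  labels <- rep(1L, n)
  tree <- data.frame(step = integer(), parent = integer(),
                     sse_before = numeric(), sse_after = numeric(),
                     child1 = integer(), child2 = integer())
  .withSeed(seed, {
    k <- 1L
    while (k < K) {
      sse <- vapply(seq_len(k), function(c) .sse(x[labels == c, , drop = FALSE]),
                    numeric(1))
      target <- which.max(sse)   # ties: lowest cluster id
      idx <- which(labels == target)
      split <- NULL
      for (try in 1:5) {
        split <- .bestSplit(x[idx, , drop = FALSE], restarts)
        if (!is.null(split)) break
      }
      if (is.null(split))
        .msiError("msiValidationError",
                  sprintf("cluster %d could not be split (identical pixels?)", target))
      k <- k + 1L
      labels[idx[split$assign == 2L]] <- k
      tree <- rbind(tree, data.frame(step = k - 1L, parent = target,
                                     sse_before = sse[target],
                                     sse_after = split$sse,
                                     child1 = target, child2 = k))
    }
  })
  new("SegmentationResult", labels = labels, K = as.integer(K), tree = tree,
      nicheLabels = integer(), nicheFraction = 0,
      clusterMarkerZ = numeric())
}

#' Call plasma-cell-rich clusters from marker features
#'
#' Computes each cluster's mean marker z-score (from the `"norm"` assay)
#' and designates as niche the marker-high side of the largest gap in the
#' sorted cluster z-scores, provided the maximal cluster z exceeds
#' `threshold` (default 0). The gap rule is scale-free: in a small-niche
#' section the niche cluster's z is far above micro clusters that drift
#' slightly positive, while in a niche-dominated section (where
#' section-wide z-scoring compresses the niche fragments towards zero and
#' pushes the microenvironment strongly negative) all genuine niche
#' fragments sit above the gap. With two clusters this reduces to picking
#' the marker-high cluster. If no cluster exceeds the threshold the niche
#' set is empty and the fraction 0.
#'
#' @param seg a [SegmentationResult-class] for `data`'s pixels.
#' @param data the normalised [MSIDataset-class].
#' @param markers non-empty character vector of marker feature ids (e.g.
#'   plasma-cell markers; in the synthetic cohort the planted
#'   `pc_marker_*` set).
#' @param threshold absolute mean-z threshold the top cluster must exceed.
#' @return the segmentation with `nicheLabels`, `nicheFraction` and
#'   `clusterMarkerZ` filled in.
#' @export
callNicheClusters <- function(seg, data, markers, threshold = 0) {
  stopifnot(is(seg, "SegmentationResult"), is(data, "MSIDataset"))
  if (!length(markers))
    .msiError("msiValidationError", "markers must be non-empty")
  missing <- setdiff(markers, featureIds(data))
  if (length(missing))
    .msiError("msiValidationError",
              sprintf("marker(s) not in panel: %s", paste(missing, collapse = ", ")))
  norm <- assay(data, "norm")[markers, , drop = FALSE]
  labels <- clusterLabels(seg)
  z <- vapply(seq_len(seg@K),
              function(c) mean(norm[, labels == c, drop = FALSE]),
              numeric(1))
  niche <- if (max(z) <= threshold) {
    integer()
  } else if (seg@K == 1L) {
    1L
  } else {
    zs <- sort(z)
    cut <- zs[which.max(diff(zs))]     # marker-high side of the largest gap
    which(z > cut)
  }
  seg@clusterMarkerZ <- z
  seg@nicheLabels <- as.integer(niche)
  seg@nicheFraction <- mean(labels %in% niche)
  validObject(seg)
  seg
}

#' Convenience wrapper: normalise, segment and call niches for one section
#'
#' @inheritParams callNicheClusters
#' @inheritParams bisectingKmeans
#' @param data a raw [MSIDataset-class].
#' @return list with the normalised `data` and the called `seg`mentation.
#' @export
segmentSection <- function(data, K = 6L, markers, seed = 1L, threshold = 0) {
  data <- normalizePixels(data)
  seg <- bisectingKmeans(pixelMatrix(data, "norm"), K = K, seed = seed)
  seg <- callNicheClusters(seg, data, markers, threshold)
  list(data = data, seg = seg)
}

#' Concordance of niche pixel fraction with pathology plasma-cell percentage
#'
#' Pearson correlation is computed on transformed scales —
#' `x = log10(fraction + 1e-4)`, `y = logit(pc_percent)` (epsilon-clamped) —
#' and Spearman on the original scales.
#'
#' @param nicheFractions per-subject called niche pixel fractions.
#' @param pcPercents per-subject plasma-cell fractions in `[0, 1]`.
#' @param eps clamping epsilon for the logit.
#' @return list with `x`, `y` (transformed values), `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
concordance <- function(nicheFractions, pcPercents, eps = 1e-6) {
  if (length(nicheFractions) != length(pcPercents) || length(nicheFractions) < 3)
    .msiError("msiValidationError",
              "need equal-length vectors with at least 3 subjects")
  x <- log10(nicheFractions + 1e-4)
  y <- logitTransform(pcPercents, eps)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .msiError("msiValidationError",
              "correlation undefined: zero variance in a transformed vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  st <- suppressWarnings(
    stats::cor.test(nicheFractions, pcPercents, method = "spearman",
                    exact = FALSE))
  list(x = x, y = y,
       pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       spearman_rho = unname(st$estimate), spearman_p = st$p.value)
}

#' Spatial heterogeneity scan
#'
#' Segments a section at `K` clusters (default 6) and summarises the cluster
#' pixel proportions `p` with Simpson's diversity index `1 - sum(p^2)`.
#'
#' @inheritParams bisectingKmeans
#' @param K number of clusters (>= 2).
#' @return list with `labels`, `proportions` and `simpson`.
#' @export
spatialHeterogeneity <- function(x, K = 6L, seed = 1L) {
  if (K < 2L) .msiError("msiValidationError", "K must be >= 2")
  seg <- bisectingKmeans(x, K = K, seed = seed)
  p <- as.numeric(table(factor(clusterLabels(seg), levels = seq_len(K)))) /
    length(clusterLabels(seg))
  list(labels = clusterLabels(seg), proportions = p,
       simpson = 1 - sum(p^2))
}
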