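test_that("pixel normalisation: TIC proportionality, idempotence, degenerate rules", {
  m <- rbind(metA = c(2, 1, 0), metB = c(2, 3, 0), const = c(0, 0, 0))
  d <- MSIDataset(m, data.frame(x = 0:2, y = c(0, 0, 0)), "s")
  expect_warning(dn <- normalizePixels(d), "all-zero")
  tic <- assay(dn, "tic")
  expect_equal(unname(tic[, 1]), c(0.5, 0.5, 0))    # pixel (2,2) -> (0.5,0.5)
  expect_equal(unname(colSums(tic)), c(1, 1))
  # TIC step is idempotent
  expect_equal(sweep(tic, 2, colSums(tic), "/"), tic)
  # constant feature is left at zero by the clamped z-score
  expect_true(all(assay(dn, "norm")["const", ] == 0))
})

test_that("bisecting k-means recovers planted structure and obeys the tree contract", {
  set.seed(10)
  # K = 1: single label, empty tree
  x <- matrix(rnorm(40), 20, 2)
  s1 <- bisectingKmeans(x, K = 1)
  expect_equal(unique(clusterLabels(s1)), 1L)
  expect_equal(nrow(splitTree(s1)), 0L)
  expect_error(bisectingKmeans(x, K = 21), class = "msiValidationError")

  # two well-separated clouds -> exact recovery
  x2 <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, mean = 10), 30, 2))
  s2 <- bisectingKmeans(x2, K = 2, seed = 3)
  expect_equal(ari(clusterLabels(s2), rep(1:2, each = 30)), 1)

  # three clouds: the first split isolates the highest-SSE cloud
  set.seed(4)
  cl <- list(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 2, 0.2), 20, 2),
             matrix(rnorm(44, 30, 0.2), 22, 2))
  x3 <- do.call(rbind, cl)
  planted <- rep(1:3, times = c(20, 20, 22))
  # brute-force SSE if each cloud were removed: the far cloud dominates SSE,
  # so the first binary split must separate it from the other two
  s3a <- bisectingKmeans(x3, K = 2, seed = 5)
  tab <- table(clusterLabels(s3a), planted == 3)
  expect_equal(min(ari(clusterLabels(s3a), planted == 3)), 1)
  s3 <- bisectingKmeans(x3, K = 3, seed = 5)
  expect_equal(ari(clusterLabels(s3), planted), 1)

  # every split reduces the split cluster's SSE; K-1 splits recorded
  expect_true(all(splitTree(s3)$sse_after <= splitTree(s3)$sse_before))
  expect_equal(nrow(splitTree(s3)), 2L)

  # deterministic under a fixed seed
  expect_identical(clusterLabels(bisectingKmeans(x3, K = 3, seed = 5)),
                   clusterLabels(s3))

  # invariant to feature order and pixel order up to relabelling
  sPerm <- bisectingKmeans(x3[, 2:1], K = 3, seed = 9)
  expect_equal(ari(clusterLabels(sPerm), planted), 1)
  ord <- sample(nrow(x3))
  sRow <- bisectingKmeans(x3[ord, ], K = 3, seed = 9)
  expect_equal(ari(clusterLabels(sRow), planted[ord]), 1)
})

test_that("total within-cluster SSE is non-increasing in K along the bisecting path", {
  set.seed(21)
  x <- matrix(rnorm(300), 100, 3)
  sse <- vapply(1:6, function(K) {
    lab <- clusterLabels(bisectingKmeans(x, K, seed = 7))
    sum(vapply(unique(lab), function(c)
      msiNiche:::.sse(x[lab == c, , drop = FALSE]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("niche calling follows the marker z-score rule", {
  # 2 clusters with marker means (+, -) -> niche is the positive cluster
  set.seed(2)
  base <- matrix(rlnorm(4 * 60, log(50), 0.1), nrow = 4,
                 dimnames = list(c("mk1", "mk2", "o1", "o2"), NULL))
  base[c("mk1", "mk2"), 1:20] <- base[c("mk1", "mk2"), 1:20] * 8
  d <- MSIDataset(base, data.frame(x = 0:59, y = rep(0, 60)), "s")
  out <- segmentSection(d, K = 2, markers = c("mk1", "mk2"), seed = 1)
  expect_length(nicheLabels(out$seg), 1L)
  expect_equal(nicheFraction(out$seg), 20 / 60)
  expect_true(all(which(isNichePixel(out$seg)) == 1:20))
  zs <- out$seg@clusterMarkerZ
  expect_gt(zs[nicheLabels(out$seg)], 0)

  # when no cluster is marker-positive the niche set is empty
  seg <- bisectingKmeans(pixelMatrix(out$data, "norm"), K = 2, seed = 1)
  called <- callNicheClusters(seg, out$data, c("mk1", "mk2"), threshold = 10)
  expect_length(nicheLabels(called), 0L)
  expect_equal(nicheFraction(called), 0)

  expect_error(callNicheClusters(seg, out$data, character()),
               class = "msiValidationError")
  expect_error(callNicheClusters(seg, out$data, "absent"),
               class = "msiValidationError")
})

test_that("planted two-compartment sections are segmented accurately across replicates", {
  # pure two-compartment sections (no stromal patches), planted effect >= 2
  # sigma, compartments of comparable size (MM sections)
  ok <- vapply(1:20, function(i) {
    p <- smallParams(seed = 600 + i, nMicroRegions = 0)
    co <- simulateCohort(p)
    mm <- names(co$datasets)[co$subjects$group == "MM"]
    id <- sample(mm, 1)
    r <- segmentSection(co$datasets[[id]], K = 2,
                        markers = co$truth$nicheMarkers, seed = i)
    ari(isNichePixel(r$seg), co$truth$compartments[[id]])
  }, numeric(1))
  expect_true(all(ok > 0.9))
})

test_that("concordance applies the stated transforms and handles degeneracies", {
  pc <- c(0.03, 0.05, 0.2, 0.6, 0.8)
  fr <- c(0.02, 0.06, 0.25, 0.55, 0.85)
  cr <- concordance(fr, pc)
  expect_equal(cr$spearman_rho, 1)                     # perfectly monotone
  expect_equal(cr$x, log10(fr + 1e-4))
  expect_equal(cr$y, log(pc / (1 - pc)))
  # fraction = 0 maps to exactly -4 on the transformed scale
  cr0 <- concordance(c(0, 0.1, 0.5), c(0.04, 0.2, 0.7))
  expect_equal(cr0$x[1], -4)
  expect_error(concordance(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3)),
               class = "msiValidationError")
  expect_error(concordance(c(0.1, 0.2), c(0.1, 0.2)),
               class = "msiValidationError")
})

test_that("spatial heterogeneity yields cluster proportions and Simpson index", {
  # six equal, well-separated clouds -> simpson = 1 - 6 (1/6)^2 = 0.8333
  set.seed(8)
  x <- do.call(rbind, lapply(0:5, function(k)
    matrix(rnorm(30, mean = 40 * k, sd = 0.3), 15, 2)))
  sh <- spatialHeterogeneity(x, K = 6, seed = 2)
  expect_equal(sort(sh$proportions), rep(1 / 6, 6))
  expect_equal(sh$simpson, 1 - 6 * (1 / 6)^2, tolerance = 1e-12)
  expect_equal(simpsonIndex(c(1, 0, 0)), 0)            # one cluster holds all
  expect_error(spatialHeterogeneity(x, K = 1), class = "msiValidationError")
})

test_that("synthetic MGUS sections span a wide Simpson range at K = 6", {
  # heterogeneity-emphasising configuration: variably patchy MGUS marrows
  # with erratic (noise-amplified) stromal patches
  p <- simParams(seed = 1, nPerGroup = 20L, grid = c(32L, 32L),
                 microRegionNoiseMult = c(1, 4))
  co <- simulateCohort(p)
  mgus <- names(co$datasets)[co$subjects$group == "MGUS"]
  simp <- vapply(mgus, function(id) {
    d <- normalizePixels(co$datasets[[id]])
    spatialHeterogeneity(pixelMatrix(d, "norm"), K = 6, seed = 1)$simpson
  }, numeric(1))
  expect_gte(diff(range(simp)), 0.3)
  expect_true(all(simp > 0.2 & simp < 0.95))
})
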