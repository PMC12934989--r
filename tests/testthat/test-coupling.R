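test_that("proliferation correlations recover planted coupling and handle degeneracies", {
  set.seed(1)
  sph <- runif(12, 0.2, 5)
  m <- cbind(copy = sph,                       # identical to the score
             flat = rep(3, 12),                # zero variance
             noise = rnorm(12))
  cc <- proliferationCorrelations(m, sph, rep("all", 12))
  expect_equal(cc$pearson_r[cc$metabolite == "copy"], 1)
  expect_equal(cc$spearman_rho[cc$metabolite == "copy"], 1)
  expect_true(cc$flag_constant[cc$metabolite == "flat"])
  expect_true(is.na(cc$pearson_r[cc$metabolite == "flat"]))
  expect_error(proliferationCorrelations(m, sph, rep(c("a", "b", "c", "d"), 3)),
               class = "msiValidationError")

  # planted r = 0.9 at n = 10 is estimated within +-0.15 in most replicates
  hits <- vapply(1:100, function(i) {
    set.seed(100 + i)
    z <- rnorm(10)
    y <- 0.9 * z + sqrt(1 - 0.81) * rnorm(10)
    abs(cor(z, y) - 0.9) <= 0.15
  }, logical(1))
  expect_gt(mean(hits), 0.85)
})

test_that("stage-specific coupling recovers the planted nucleotide sign reversal", {
  p <- smallParams(seed = 77, couplingBeta = 0.8)
  co <- simulateCohort(p)
  nm <- subjectMeanMatrix(co$datasets, co$truth$compartments, "niche")
  cc <- proliferationCorrelations(nm, co$subjects$sphase, co$subjects$group)
  planted <- cc[cc$metabolite %in% co$truth$coupledFeatures, ]
  expect_true(all(planted$pearson_r[planted$stage == "MGUS"] < 0))
  expect_true(all(planted$pearson_r[planted$stage == "MM"] > 0))
})

test_that("segmentation gain depends only on correlation magnitudes", {
  g <- segmentationGain(c(a = 0.8, b = -0.9), c(a = 0.5, b = 0.2))
  expect_equal(g$delta_abs_rho[g$metabolite == "a"], 0.3)
  expect_equal(g$delta_abs_rho[g$metabolite == "b"], 0.7)
  expect_equal(g$metabolite, c("b", "a"))          # sorted descending
  expect_error(segmentationGain(c(a = 1), c(b = 1)),
               class = "msiValidationError")
  # sign invariance
  set.seed(8)
  r1 <- runif(10, -1, 1); r2 <- runif(10, -1, 1)
  names(r1) <- names(r2) <- letters[1:10]
  expect_equal(segmentationGain(r1, r2)$delta_abs_rho,
               segmentationGain(-r1, -r2)$delta_abs_rho)
})

test_that("niche-restricted effects give positive median segmentation gain", {
  p <- smallParams(seed = 55, couplingBeta = 0.8)
  co <- simulateCohort(p)
  mm <- co$subjects$group == "MM"
  nicheM <- subjectMeanMatrix(co$datasets, co$truth$compartments, "niche")[mm, ]
  wholeM <- subjectMeanMatrix(co$datasets, region = "whole")[mm, ]
  sph <- co$subjects$sphase[mm]
  feats <- co$truth$coupledFeatures
  rhoN <- vapply(feats, function(f) cor(nicheM[, f], sph, method = "spearman"),
                 numeric(1))
  rhoW <- vapply(feats, function(f) cor(wholeM[, f], sph, method = "spearman"),
                 numeric(1))
  g <- segmentationGain(rhoN, rhoW)
  expect_gt(median(g$delta_abs_rho), 0)
})

test_that("correlation-partner sets partition at the r threshold", {
  set.seed(12)
  n <- 10
  anchor <- rnorm(n)
  m <- cbind(anchor = anchor, dup = anchor, neg = -anchor,
             matrix(rnorm(n * 200), n, 200,
                    dimnames = list(NULL, sprintf("noise%03d", 1:200))))
  ps <- correlationPartnerSets("anchor", m, rThreshold = 0.30)
  expect_true("dup" %in% ps$positive)
  expect_true("neg" %in% ps$negative)
  expect_false("anchor" %in% c(ps$positive, ps$negative))

  # null occupancy matches the theoretical |r| > 0.30 tail at this n
  tObs <- 0.30 * sqrt(n - 2) / sqrt(1 - 0.09)
  pTail <- 2 * pt(tObs, df = n - 2, lower.tail = FALSE)
  occupancy <- (length(ps$positive) + length(ps$negative) - 2) / 200
  expect_lt(abs(occupancy - pTail), 0.12)

  expect_error(correlationPartnerSets("absent", m),
               class = "msiValidationError")
  expect_error(correlationPartnerSets("anchor", cbind(anchor = rep(1, 6),
                                                      b = rnorm(6))),
               class = "msiValidationError")
})

test_that("hypergeometric over-representation matches the exact tail", {
  map <- pathwayMap(sprintf("m%02d", 1:10),
                    rep(c("pathA", "pathB"), each = 5),
                    sub_pathway = rep(c("pathA", "pathB"), each = 5))
  bg <- sprintf("m%02d", 1:10)
  res <- pathwayOverrepresentation(sprintf("m%02d", 1:4), bg, map)
  pA <- res$p[res$pathway == "pathA"]
  expect_equal(pA, 5 / 210)                      # C(5,4)/C(10,4)
  expect_equal(res$metabolite_ratio[res$pathway == "pathA"], 1)
  # pathway absent from the set -> overlap 0, p near 1
  expect_equal(res$overlap[res$pathway == "pathB"], 0L)
  expect_gt(res$p[res$pathway == "pathB"], 0.9)
  # empty set -> empty result
  expect_equal(nrow(pathwayOverrepresentation(character(), bg, map)), 0L)
  expect_error(pathwayOverrepresentation("zzz", bg, map),
               class = "msiValidationError")
})

test_that("pairwise pathway networks flag significant edges per group", {
  set.seed(3)
  n <- 10
  v <- rnorm(n)
  m <- cbind(t1 = v, t2 = v + rnorm(n, sd = 1e-6), o1 = rnorm(n))
  net <- pairwisePathwayNetwork(c("t1", "t2"), m)
  e <- net[net$from == "t1" & net$to == "t2", ]
  expect_equal(e$r, 1, tolerance = 1e-6)
  expect_true(e$significant)
  expect_equal(nrow(net), 1 + 2)                 # member pair + 2 member-other

  # per-group networks run with unequal detected member panels
  m2 <- matrix(rnorm(20 * 5), 20, 5,
               dimnames = list(NULL, c("w", "x", "y", "z", "q")))
  g <- rep(c("MGUS", "MM"), each = 10)
  net2 <- pairwisePathwayNetwork(c("w", "x", "y", "z"), m2, groups = g)
  expect_setequal(unique(net2$group), c("MGUS", "MM"))

  # independent features are flagged at roughly the nominal rate
  set.seed(4)
  flags <- vapply(1:300, function(i) {
    mm <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
    pairwisePathwayNetwork(c("a", "b"), mm)$significant[1]
  }, logical(1))
  expect_lt(abs(mean(flags) - 0.05), 0.04)
  expect_error(pairwisePathwayNetwork("a", m), class = "msiValidationError")
})

test_that("pathway slope summaries mirror Pearson signs and stage reversal", {
  # beta1 sign equals the Pearson sign for every metabolite (identity)
  set.seed(5)
  sph <- runif(12, 0.1, 6)
  m <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, sprintf("m%d", 1:8)))
  cc <- proliferationCorrelations(m, sph, rep("all", 12))
  expect_true(all(sign(cc$slope_beta1) == sign(cc$pearson_r)))

  map <- pathwayMap(sprintf("m%d", 1:8), rep(c("nucleotide", "lipid"), 4))
  sm <- pathwaySlopeSummary(cc, map)
  expect_true(all(sm$n_positive + sm$n_negative <= sm$n))

  # planted all-positive pathway has no negative slopes
  m2 <- sapply(1:4, function(i) sph * (1 + 0.05 * i) + rnorm(12, sd = 0.01))
  colnames(m2) <- paste0("pos", 1:4)
  cc2 <- proliferationCorrelations(m2, sph, rep("all", 12))
  sm2 <- pathwaySlopeSummary(cc2, pathwayMap(colnames(m2), rep("lipid", 4)))
  expect_equal(sm2$n_negative, 0L)
  expect_equal(sm2$n_positive, 4L)

  # stage reversal: planted nucleotide-like features flip majority sign
  p <- smallParams(seed = 77, couplingBeta = 0.8)
  co <- simulateCohort(p)
  nm <- subjectMeanMatrix(co$datasets, co$truth$compartments, "niche")
  cc3 <- proliferationCorrelations(nm, co$subjects$sphase, co$subjects$group)
  mapN <- pathwayMap(co$truth$coupledFeatures,
                     rep("nucleotide", length(co$truth$coupledFeatures)))
  sm3 <- suppressMessages(
    pathwaySlopeSummary(cc3[cc3$metabolite %in% co$truth$coupledFeatures, ], mapN))
  nuc <- sm3[sm3$pathway == "nucleotide", ]
  expect_gt(nuc$n_negative[nuc$stage == "MGUS"], nuc$n_positive[nuc$stage == "MGUS"])
  expect_gt(nuc$n_positive[nuc$stage == "MM"], nuc$n_negative[nuc$stage == "MM"])
})
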