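test_that("Hill 2D matches hand-evaluated profiles and limits", {
  expect_equal(hillD2(rep(0.25, 4)), 4)                     # uniform limit
  expect_equal(hillD2(c(1, 0, 0)), 1)                       # single species
  expect_equal(hillD2(c(0.7, 0.2, 0.1)), 1 / 0.54)          # 1.85185...
  expect_error(hillD2(c(0.5, 0.4)), class = "msiValidationError")
  expect_error(hillD2(c(-0.1, 1.1)), class = "msiValidationError")
  # invariant under permutation and appended zeros; bounded by [1, K_eff]
  set.seed(1)
  for (i in 1:25) {
    p <- rgamma(sample(2:12, 1), 0.8); p <- p / sum(p)
    d <- hillD2(p)
    expect_equal(hillD2(sample(p)), d)
    expect_equal(hillD2(c(p, 0, 0)), d)
    expect_gte(d, 1)
    expect_lte(d, sum(p > 0) + 1e-12)
  }
})

test_that("evenness is 2D over effective richness with the stated properties", {
  expect_equal(evenness(rep(1 / 5, 5)), 1)                  # uniform -> 1
  p <- c(0.97, 0.01, 0.01, 0.01)
  expect_equal(hillD2(p), 1.0625, tolerance = 1e-4)
  expect_equal(evenness(p), 1.0625 / 4, tolerance = 1e-4)   # ~0.2656
  expect_equal(evenness(c(p, 0, 0)), evenness(p))           # zeros ignored
  expect_error(evenness(rep(0, 3) / 1), class = "msiValidationError")
  # E = 1 iff uniform on the support
  expect_equal(evenness(c(0.5, 0.5, 0)), 1)
  expect_lt(evenness(c(0.6, 0.4)), 1)
})

test_that("two-community beta behaves per definition for both alpha options", {
  # identical communities -> beta = 1 under both options, any weights
  p <- c(0.5, 0.3, 0.2)
  expect_equal(betaTwoCommunity(p, p, 10, 3, "arithmetic"), 1)
  expect_equal(betaTwoCommunity(p, p, 10, 3, "jost"), 1)
  # disjoint uniform supports, equal weights -> beta = 2
  pa <- c(0.5, 0.5, 0, 0); pb <- c(0, 0, 0.5, 0.5)
  expect_equal(betaTwoCommunity(pa, pb, 5, 5, "arithmetic"), 2)
  expect_equal(betaTwoCommunity(pa, pb, 5, 5, "jost"), 2)
  # beta grows monotonically as p_b is mixed away from p_a
  pa <- c(0.6, 0.3, 0.1); pTarget <- c(0.05, 0.15, 0.8)
  betas <- vapply(seq(0, 1, 0.1), function(tmix) {
    pb <- (1 - tmix) * pa + tmix * pTarget
    suppressMessages(betaTwoCommunity(pa, pb, 4, 6, "jost"))
  }, numeric(1))
  expect_true(all(diff(betas) > -1e-12))
  expect_error(betaTwoCommunity(c(1, 0), c(1, 0, 0), 1, 1),
               class = "msiValidationError")
  expect_error(betaTwoCommunity(p, p, 0, 1), class = "msiValidationError")
})

test_that("jost alpha guarantees beta >= 1; arithmetic alpha can dip below with a message", {
  set.seed(42)
  for (i in 1:500) {
    k <- sample(2:6, 1)
    pa <- rgamma(k, 0.7); pa <- pa / sum(pa)
    pb <- rgamma(k, 0.7); pb <- pb / sum(pb)
    w <- runif(2, 1, 20)
    expect_gte(suppressMessages(betaTwoCommunity(pa, pb, w[1], w[2], "jost")),
               1 - 1e-12)
  }
  # frozen counterexample for the literal arithmetic definition
  pa <- c(0.99515, 0.001417, 0.003432); pa <- pa / sum(pa)
  pb <- c(0.69986, 0.136298, 0.163842); pb <- pb / sum(pb)
  expect_message(b <- betaTwoCommunity(pa, pb, 19.448, 12.758, "arithmetic"),
                 "< 1")
  expect_lt(b, 1)
})

test_that("Cliff's delta matches brute-force pair enumeration", {
  expect_equal(cliffsDelta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffsDelta(c(1, 3), c(2, 4)), -0.5)
  expect_error(cliffsDelta(numeric(), 1), class = "msiValidationError")
  set.seed(7)
  for (i in 1:25) {
    x <- sample(0:5, sample(3:12, 1), replace = TRUE)   # ties included
    y <- sample(0:5, sample(3:12, 1), replace = TRUE)
    expect_equal(cliffsDelta(x, y), bruteCliffs(x, y))
  }
})

test_that("HC3 regression matches the sandwich matrix formula", {
  # exact linear relation: slope recovered exactly, zero HC3 variance
  pc <- c(0.1, 0.2, 0.35, 0.5, 0.7, 0.9)
  lx <- log(pc / (1 - pc))
  evn <- plogis(-0.5 * lx)          # logit(evenness) = -0.5 * logit(pc)
  r <- suppressWarnings(evennessVsPcRegression(evn, pc))
  expect_equal(r$slope, -0.5, tolerance = 1e-10)
  expect_equal(r$se_hc3, 0, tolerance = 1e-7)

  # fixed 6-point dataset against the hand-coded sandwich formula
  set.seed(11)
  pc <- runif(6, 0.05, 0.9)
  evn <- plogis(-1 * log(pc / (1 - pc)) + rnorm(6, sd = 0.4))
  r2 <- evennessVsPcRegression(evn, pc)
  X <- cbind(1, log(pc / (1 - pc)))
  V <- bruteHC3(X, log(evn / (1 - evn)))
  tBrute <- (solve(crossprod(X)) %*% crossprod(X, log(evn / (1 - evn))))[2] /
    sqrt(V[2, 2])
  expect_equal(r2$se_hc3, sqrt(V[2, 2]))
  expect_equal(r2$p_hc3, 2 * pt(-abs(tBrute), df = 4))

  # planted slope is recovered within +-0.2 in most replicates at n = 20
  hits <- vapply(1:50, function(i) {
    set.seed(200 + i)
    pc <- runif(20, 0.05, 0.9)
    ly <- -1 * log(pc / (1 - pc)) + rnorm(20, sd = 0.5)
    abs(evennessVsPcRegression(plogis(ly), pc)$slope + 1) <= 0.2
  }, logical(1))
  expect_gt(mean(hits), 0.85)
  expect_error(evennessVsPcRegression(c(0.5, 0.6, 0.7, 0.8),
                                      rep(0.5, 4)),
               class = "msiValidationError")
})

test_that("cohort diversity tests behave under null and planted shifts", {
  set.seed(21)
  mk <- function(ev, be) data.frame(
    group = rep(c("MGUS", "MM"), each = 10),
    evenness_niche = ev, beta = be,
    pc_percent = c(runif(10, 0.03, 0.07), runif(10, 0.5, 0.9)))
  # identical group distributions -> p large
  ev <- rep(seq(0.4, 0.8, length.out = 10), 2)
  be <- rep(seq(1, 1.4, length.out = 10), 2)
  nullRes <- cohortDiversityTests(mk(ev, be))
  expect_gt(nullRes$mw_p_evenness, 0.9)
  expect_equal(nullRes$cliffs_delta_evenness, 0)

  # planted lower-evenness / higher-beta MM (2 IQR shift): powerful detection
  hitsE <- hitsB <- logical(100)
  for (i in 1:100) {
    set.seed(300 + i)
    evM <- runif(10, 0.5, 0.8); iqr <- IQR(evM)
    ev <- c(evM, runif(10, 0.5, 0.8) - 2 * iqr)
    beM <- runif(10, 1, 1.2)
    be <- c(beM, runif(10, 1, 1.2) + 2 * IQR(beM))
    r <- cohortDiversityTests(mk(ev, be))
    hitsE[i] <- r$mw_p_evenness < 0.05
    hitsB[i] <- r$cliffs_delta_beta < 0
  }
  expect_gt(mean(hitsE), 0.9)
  expect_equal(mean(hitsB), 1)      # delta orientation: higher beta in MM -> negative
  expect_error(cohortDiversityTests(mk(ev, be)[1:4, ]),
               class = "msiValidationError")
})

test_that("diversityReport integrates compartment profiles with cohort inference", {
  p <- smallParams(seed = 9)
  co <- simulateCohort(p)
  div <- suppressMessages(
    diversityReport(co$datasets, co$truth$compartments, co$subjects))
  per <- div$perSubject
  expect_equal(nrow(per), 20L)
  expect_true(all(per$d2_niche >= 1 & per$d2_micro >= 1))
  expect_true(all(per$evenness_niche > 0 & per$evenness_niche <= 1))
  expect_true(all(per$keff_niche <= p$nFeatures))
  expect_true(all(c("mw_p_evenness", "mw_p_beta", "ols_slope") %in%
                  names(div$cohort)))
  # MM niches are more dominated than MGUS niches in the generator
  expect_lt(median(per$evenness_niche[per$group == "MM"]),
            median(per$evenness_niche[per$group == "MGUS"]))
})
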