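# shared fixtures: everything is built in code at test time

# small, fast cohort parameters for module-level tests
smallParams <- function(seed = 1L, ...) {
  simParams(grid = c(16L, 16L), nFeatures = 24L, nMMUp = 3L, nMMDown = 1L,
            nStageTrend = 3L, nCoupled = 2L, seed = seed, ...)
}

# a tiny 3-pixel, 2-metabolite pixel table on disk
writeToyPixelTable <- function(path) {
  writeLines(c("x\ty\tmetA\tmetB",
               "0\t0\t1.5\t2.0",
               "1\t0\t0.25\t4.0",
               "0\t1\t3.0\t0.0"), path)
  path
}

writeToySubjectTables <- function(metaPath, plasmaPath = NULL,
                                  nMGUS = 10L, nMM = 10L) {
  ids <- c(sprintf("MGUS%02d", seq_len(nMGUS)), sprintf("MM%02d", seq_len(nMM)))
  grp <- rep(c("MGUS", "MM"), c(nMGUS, nMM))
  pc <- c(stats::runif(nMGUS, 0.03, 0.07), stats::runif(nMM, 0.5, 0.9))
  sph <- stats::runif(nMGUS + nMM, 0.2, 4)
  utils::write.table(
    data.frame(subject_id = ids, group = grp, pc_percent = pc, sphase = sph),
    metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plasmaPath)) {
    m <- matrix(stats::rlnorm(length(ids) * 5), length(ids), 5,
                dimnames = list(NULL, paste0("met", 1:5)))
    utils::write.table(data.frame(subject_id = ids, m), plasmaPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  metaPath
}

# toy pathway map over a feature panel
toyMap <- function(features) {
  sup <- rep(c("nucleotide", "amino acid", "lipid", "carbohydrate"),
             length.out = length(features))
  pathwayMap(features, sup, sub_pathway = paste0(sup, "/sub"))
}

# adjusted Rand index (mclust) with a readable wrapper
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force helpers used as independent oracles
bruteCliffs <- function(x, y) {
  s <- 0L
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {       # step-up with monotonicity
    q[o[i]] <- min(prev, p[o[i]] * m / i)
    prev <- q[o[i]]
  }
  q
}

# hypergeometric upper tail by explicit enumeration of all draws
bruteHyper <- function(overlap, pathwaySize, backgroundSize, setSize) {
  idx <- seq_len(backgroundSize)
  inPath <- idx <= pathwaySize
  draws <- utils::combn(backgroundSize, setSize)
  tailCount <- sum(apply(draws, 2, function(d) sum(inPath[d]) >= overlap))
  tailCount / ncol(draws)
}

# HC3 sandwich covariance from the matrix formula
bruteHC3 <- function(X, y) {
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  e <- drop(y - X %*% beta)
  h <- diag(X %*% XtXi %*% t(X))
  meat <- crossprod(X * (e^2 / (1 - h)^2), X)
  XtXi %*% meat %*% XtXi
}
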