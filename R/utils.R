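# internal helpers shared across modules

# classed condition so callers/tests can distinguish format vs validation faults
.msiError <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "msiError")))
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Clamp proportions away from 0 and 1
#'
#' Proportions that enter a logit transform are clamped to
#' `[eps, 1 - eps]`; the logit is undefined at the boundaries and pathology
#' plasma-cell percentages as well as realised pixel fractions can be exactly
#' 0 or 1 in small sections.
#'
#' @param p numeric vector of proportions.
#' @param eps clamping epsilon (default `1e-6`).
#' @return `p` with all values forced into `[eps, 1 - eps]`.
#' @export
clampProportion <- function(p, eps = 1e-6) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  pmin(pmax(p, eps), 1 - eps)
}

#' Logit transform with epsilon clamping
#'
#' @inheritParams clampProportion
#' @return `log(p / (1 - p))` after clamping.
#' @export
logitTransform <- function(p, eps = 1e-6) {
  p <- clampProportion(p, eps)
  log(p / (1 - p))
}

# zero-variance-safe column z-scoring; constant columns map to zeros
.zscoreCols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
}
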