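# Internal numeric helpers shared across modules.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed cohort percentages use
#' conventional half-up rounding, so proportions are rounded with this
#' helper instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfUp <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package operations do
#' not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a reproducible stage seed from a global seed
#'
#' Mixes a stage label into the run seed so pipeline stages draw from
#' independent but reproducible streams. Result is kept inside the
#' 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @keywords internal
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647L)
}

#' Genomic inflation factor of a p-value vector
#'
#' Median of the implied 1-df chi-square statistics divided by the median
#' of the chi-square(1) distribution; ~1 under the null, >1 under
#' confounding-driven inflation.
#'
#' @param p numeric vector of p-values; NAs ignored.
#' @return scalar inflation factor lambda.
#' @export
#' @examples
#' genomicInflation(runif(1000))
genomicInflation <- function(p) {
  p <- p[is.finite(p)]
  stopifnot(length(p) > 0, all(p >= 0 & p <= 1))
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

# clip betas strictly inside (0,1)
clipBeta <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# residualize rows of Y (sites x samples) on sample-level design X (n x q)
residualizeRows <- function(Y, X) {
  Y - (Y %*% X) %*% solve(crossprod(X), t(X))
}
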