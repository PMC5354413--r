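#' Create a simulation scenario
#'
#' Constructor for [ScenarioConfig-class]. The outcome is generated as
#' \deqn{Y = \gamma_0 + \gamma_G G + \gamma_E E + \gamma_{GE} G E +
#'   \gamma_Z Z + \epsilon}
#' with \eqn{\gamma_0 = 0}, each coefficient set to the square root of its
#' variance fraction (see [coefFromTau()]) and the residual scaled so the
#' outcome variance equals 1.
#'
#' @param n sample size (>= 10).
#' @param caf coded-allele frequency in (0, 0.5].
#' @param tauG,tauE,tauZ,tauGE variance fractions in [0, 1); their sum must
#'   be < 1.
#' @param distE,distZ,distEps \code{"normal"} or \code{"right_skew"} (a
#'   skew-normal standardized to mean 0, variance 1; see [sampleSkewed()]).
#' @param meanE location shift for the exposure (default 0).
#' @param standardize standardize the dosage with theoretical Hardy-Weinberg
#'   moments before it enters the generative model (default TRUE).
#' @param seed integer seed for exact replay, or NULL to use the current RNG
#'   state.
#' @return A [ScenarioConfig-class] object.
#' @examples
#' cfg <- scenarioConfig(n = 400, caf = 0.1, tauGE = 0.2, seed = 1)
#' coh <- buildCohort(cfg)
#' var(outcome(coh))
#' @export
scenarioConfig <- function(n, caf, tauG = 0, tauE = 0, tauZ = 0, tauGE = 0,
                           distE = "normal", distZ = "normal",
                           distEps = "normal", meanE = 0,
                           standardize = TRUE, seed = NULL) {
  new("ScenarioConfig",
      n = as.integer(n), caf = as.numeric(caf),
      tauG = tauG, tauE = tauE, tauZ = tauZ, tauGE = tauGE,
      distE = distE, distZ = distZ, distEps = distEps,
      meanE = meanE, standardize = standardize,
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' @export
setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig: n =", object@n, ", CAF =", object@caf, "\n")
  cat("  variance fractions: G =", object@tauG, ", E =", object@tauE,
      ", Z =", object@tauZ, ", GxE =", object@tauGE, "\n")
  cat("  distributions: E =", object@distE, ", Z =", object@distZ,
      ", eps =", object@distEps, "\n")
  if (!is.null(object@seed)) cat("  seed:", object@seed, "\n")
})

#' @export
setMethod("show", "Cohort", function(object) {
  cat("Cohort of", length(object@y), "individuals",
      sprintf("(CAF %.3g, genotype counts %s)\n", object@config@caf,
              paste(tabulate(object@gRaw + 1L, 3L), collapse = "/")))
  cat("  var(Y) =", signif(var(object@y), 4), "\n")
})

#' Sample genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages 0/1/2 are drawn independently with genotype probabilities
#' ((1-caf)^2, 2 caf (1-caf), caf^2), i.e. Binomial(2, caf).
#'
#' @param n number of individuals (>= 1).
#' @param caf coded-allele frequency in (0, 0.5].
#' @return Integer vector of dosages.
#' @export
sampleGenotypes <- function(n, caf) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer")
  if (length(caf) != 1L || is.na(caf) || caf <= 0 || caf > 0.5)
    stop("'caf' must lie in (0, 0.5]")
  rbinom(n, 2L, caf)
}

.SKEW_SLANT <- 5

#' Sample from a standardized right-skewed normal
#'
#' Draws from a skew-normal with slant parameter \code{alpha} (default 5, a
#' pronounced right skew with skewness about 0.851), recentred and rescaled
#' by its analytic moments so the population mean is 0 and the variance 1.
#' \code{alpha = 0} reduces to the standard normal (used as an internal
#' check mode).
#'
#' @param n number of draws.
#' @param alpha slant parameter (>= 0); default 5.
#' @return Numeric vector with population mean 0 and variance 1.
#' @export
sampleSkewed <- function(n, alpha = .SKEW_SLANT) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer")
  if (alpha == 0) return(rnorm(n))
  delta <- alpha / sqrt(1 + alpha^2)
  # SN(alpha) via the convolution representation delta|U0| + sqrt(1-d^2) U1
  x <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (x - mu) / sqrt(1 - mu^2)
}

.drawDist <- function(n, dist) {
  switch(dist,
         normal = rnorm(n),
         right_skew = sampleSkewed(n),
         stop("unknown distribution: ", dist))
}

#' Coefficient from a variance fraction
#'
#' For standardized, mutually independent predictors with mean 0 and an
#' outcome of unit variance, a term with coefficient \eqn{\gamma} explains a
#' fraction \eqn{\gamma^2} of the outcome variance (this holds for the
#' product term too, since \eqn{var(GE) = E[G^2]E[E^2] = 1}). The coefficient
#' realizing fraction \code{tau} is therefore \eqn{\sqrt{\tau}}.
#'
#' @param tau variance fraction in [0, 1); may be a vector.
#' @return \code{sqrt(tau)}.
#' @export
coefFromTau <- function(tau) {
  if (any(is.na(tau)) || any(tau < 0) || any(tau >= 1))
    stop("'tau' must lie in [0, 1)")
  sqrt(tau)
}

#' Standardize dosages with theoretical Hardy-Weinberg moments
#'
#' Uses mean \code{2*caf} and sd \code{sqrt(2*caf*(1-caf))} rather than the
#' sample moments, so variance-fraction calibration is exact in expectation
#' at any sample size.
#'
#' @param g integer dosage vector.
#' @param caf coded-allele frequency.
#' @return Numeric standardized dosage.
#' @export
standardizeDosage <- function(g, caf) {
  (g - 2 * caf) / sqrt(2 * caf * (1 - caf))
}

#' Build one cohort from a scenario
#'
#' Realizes the generative model of [scenarioConfig()]: draws genotypes,
#' exposure, covariate and residual; scales the residual so
#' \eqn{var(\epsilon) = 1 - (\tau_G + \tau_E + \tau_Z + \tau_{GE})};
#' assembles the outcome. The exposure stored in the cohort is the
#' standardized draw plus \code{meanE}; the generative model uses the
#' centered version, so a nonzero \code{meanE} shifts genotype-wise offsets
#' without altering variance fractions.
#'
#' @param config a [ScenarioConfig-class].
#' @return A [Cohort-class].
#' @export
buildCohort <- function(config) {
  validObject(config)
  if (!is.null(config@seed)) set.seed(config@seed)
  n <- config@n
  gRaw <- sampleGenotypes(n, config@caf)
  gStd <- standardizeDosage(gRaw, config@caf)
  g <- if (config@standardize) gStd else as.numeric(gRaw)
  e0 <- .drawDist(n, config@distE)
  z <- .drawDist(n, config@distZ)
  epsVar <- 1 - (config@tauG + config@tauE + config@tauZ + config@tauGE)
  eps <- .drawDist(n, config@distEps) * sqrt(epsVar)
  y <- coefFromTau(config@tauG) * g +
       coefFromTau(config@tauE) * e0 +
       coefFromTau(config@tauGE) * g * e0 +
       coefFromTau(config@tauZ) * z +
       eps
  new("Cohort", gRaw = as.integer(gRaw), gStd = gStd,
      e = e0 + config@meanE, z = z, eps = eps, y = y, config = config)
}

## ---- accessors ----

#' @describeIn Cohort the outcome vector
#' @param object,x a Cohort
#' @export
outcome <- function(x) x@y

#' @describeIn Cohort raw dosages (0/1/2)
#' @export
dosages <- function(x) x@gRaw

#' @describeIn Cohort standardized dosage
#' @export
dosagesStd <- function(x) x@gStd

#' @describeIn Cohort the interacting exposure E
#' @export
exposure <- function(x) x@e

#' @describeIn Cohort the tested covariate Z
#' @export
covariateZ <- function(x) x@z

#' @describeIn Cohort the true generative residual
#' @export
trueResidual <- function(x) x@eps

#' Export a cohort as a data.frame
#'
#' @param x a [Cohort-class].
#' @param ... unused.
#' @return data.frame with columns sample_id, G, E, Z, Y.
#' @export
setMethod("as.data.frame", "Cohort", function(x, ...) {
  data.frame(sample_id = sprintf("S%04d", seq_along(x@y)),
             G = x@gRaw, E = x@e, Z = x@z, Y = x@y)
})

## ---- randomized-effects grid (robustness study) ----

#' Grid of robustness scenarios
#'
#' Defines the randomized-effects null-interaction study: a grid over sample
#' size, coded-allele frequency, distribution regime (all three continuous
#' variables normal, or all right-skewed) and which of the E/Z main effects
#' are present. The default grid enumerates 4 x 3 x 2 x 4 = 96 cells. Within
#' every replicate the active coefficients are drawn from Uniform(0, 1) and
#' the residual is scaled so the predictors explain a Uniform draw from
#' \code{r2Range} of the outcome variance.
#'
#' @param nList sample sizes (default 100, 500, 1000, 5000).
#' @param cafList coded-allele frequencies (default 0.05, 0.3, 0.5).
#' @param distRegimes subset of \code{c("normal", "right_skew")}.
#' @param mainEffectRegimes subset of \code{c("E_only", "Z_only", "both",
#'   "neither")}; the SNP main effect and the G-by-E interaction coefficient
#'   are always drawn.
#' @param replicatesPerCell replicates per grid cell.
#' @param r2Range range of the per-replicate total explained-variance draw.
#' @param epsRule \code{"uniform_r2"} (default; residual scaled to hit the
#'   drawn R2) or \code{"unit"} (residual variance fixed at 1).
#' @param seed root seed; each cell gets an independent substream.
#' @return A list of class \code{"GridConfig"}.
#' @export
gridConfig <- function(nList = c(100L, 500L, 1000L, 5000L),
                       cafList = c(0.05, 0.3, 0.5),
                       distRegimes = c("normal", "right_skew"),
                       mainEffectRegimes = c("E_only", "Z_only", "both", "neither"),
                       replicatesPerCell = 20000L,
                       r2Range = c(0, 0.8),
                       epsRule = c("uniform_r2", "unit"),
                       seed = 1L) {
  epsRule <- match.arg(epsRule)
  stopifnot(all(distRegimes %in% .validDist),
            all(mainEffectRegimes %in% c("E_only", "Z_only", "both", "neither")),
            length(r2Range) == 2L, r2Range[1] >= 0, r2Range[2] < 1,
            r2Range[1] <= r2Range[2], replicatesPerCell >= 1)
  cells <- expand.grid(n = as.integer(nList), caf = cafList,
                       dist = distRegimes, regime = mainEffectRegimes,
                       stringsAsFactors = FALSE)
  structure(list(cells = cells, replicatesPerCell = as.integer(replicatesPerCell),
                 r2Range = r2Range, epsRule = epsRule, seed = as.integer(seed)),
            class = "GridConfig")
}

#' @export
print.GridConfig <- function(x, ...) {
  cat("GridConfig:", nrow(x$cells), "cells x", x$replicatesPerCell,
      "replicates (eps rule:", x$epsRule, ")\n")
  invisible(x)
}

#' Seed the RNG with a reproducible substream
#'
#' Derives independent L'Ecuyer-CMRG substreams from one root seed so every
#' grid cell (or dataset) can be regenerated in isolation, in any order.
#'
#' @param seed root seed.
#' @param index non-negative substream index (0 = the root stream).
#' @return Invisibly, the assigned \code{.Random.seed}.
#' @export
useSubstream <- function(seed, index = 0L) {
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- .Random.seed
  i <- as.integer(index)
  while (i > 0L) {
    s <- parallel::nextRNGSubStream(s)
    i <- i - 1L
  }
  assign(".Random.seed", s, envir = globalenv())
  invisible(s)
}

#' Draw one randomized-effects replicate
#'
#' Coefficients active under the cell's main-effect regime are drawn from
#' Uniform(0, 1) (the SNP main effect and the G-by-E interaction are always
#' active); predictors are standardized; under the \code{"uniform_r2"} rule
#' the residual variance is set to \eqn{S (1/R^2 - 1)} where \eqn{S} is the
#' systematic variance of the drawn coefficients and \eqn{R^2} a Uniform
#' draw from \code{r2Range}, so the realized explained fraction equals the
#' draw.
#'
#' @param n,caf,dist,regime cell parameters (see [gridConfig()]).
#' @param r2Range explained-variance range.
#' @param epsRule \code{"uniform_r2"} or \code{"unit"}.
#' @return A list with the realized vectors (\code{g}, \code{z}, \code{y}),
#'   the drawn coefficients and the target R2. Uses the current RNG state;
#'   seed via [useSubstream()] for reproducibility.
#' @export
drawGridReplicate <- function(n, caf, dist = "normal", regime = "both",
                              r2Range = c(0, 0.8),
                              epsRule = c("uniform_r2", "unit")) {
  epsRule <- match.arg(epsRule)
  gamG <- runif(1)
  gamGE <- runif(1)
  gamE <- if (regime %in% c("E_only", "both")) runif(1) else 0
  gamZ <- if (regime %in% c("Z_only", "both")) runif(1) else 0
  gRaw <- sampleGenotypes(n, caf)
  g <- standardizeDosage(gRaw, caf)
  e <- .drawDist(n, dist)
  z <- .drawDist(n, dist)
  S <- gamG^2 + gamE^2 + gamZ^2 + gamGE^2
  if (epsRule == "uniform_r2") {
    r2 <- runif(1, r2Range[1], r2Range[2])
    epsVar <- if (r2 > 0) S * (1 / r2 - 1) else Inf
    if (!is.finite(epsVar)) { epsVar <- 1; r2 <- S / (S + 1) }
  } else {
    epsVar <- 1
    r2 <- S / (S + 1)
  }
  eps <- .drawDist(n, dist) * sqrt(epsVar)
  y <- gamG * g + gamE * e + gamGE * g * e + gamZ * z + eps
  list(gRaw = gRaw, g = g, e = e, z = z, eps = eps, y = y,
       gamma = c(G = gamG, E = gamE, GE = gamGE, Z = gamZ),
       targetR2 = r2)
}
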