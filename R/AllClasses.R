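#' @import methods
#' @importFrom stats coef lm median pbeta pchisq pf pnorm qbeta qchisq qf
#'   qnorm rbinom rnorm runif var setNames p.adjust rank complete.cases
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Simulation scenario configuration
#'
#' One fully-specified generative scenario for a single cohort: sample size,
#' coded-allele frequency of the SNP, the fraction of outcome variance
#' assigned to each model term (SNP main effect, exposure main effect,
#' covariate main effect and SNP-by-exposure interaction), the distribution
#' family of each continuous variable, and a seed for exact replay.
#'
#' Variance fractions are interpreted on the standardized-predictor scale:
#' with all predictors standardized to mean 0 and variance 1 and mutually
#' independent, a term with fraction \eqn{\tau} receives coefficient
#' \eqn{\sqrt{\tau}} and the residual is scaled so the outcome variance is 1.
#'
#' @slot n integer(1) sample size (>= 10).
#' @slot caf numeric(1) coded-allele frequency in (0, 0.5].
#' @slot tauG,tauE,tauZ,tauGE numeric(1) variance fractions in [0, 1) whose
#'   sum must be strictly below 1.
#' @slot distE,distZ,distEps character(1), one of \code{"normal"} or
#'   \code{"right_skew"}.
#' @slot meanE numeric(1) location shift added to the exposure after
#'   standardization (affects only intercept-like offsets, not variance
#'   fractions).
#' @slot standardize logical(1); if TRUE (default) the dosage entering the
#'   generative model is standardized with its theoretical Hardy-Weinberg
#'   moments.
#' @slot seed integer(1) or NULL.
#'
#' @seealso [scenarioConfig()], [buildCohort()]
#' @export
setClass("ScenarioConfig",
  representation(
    n = "integer", caf = "numeric",
    tauG = "numeric", tauE = "numeric", tauZ = "numeric", tauGE = "numeric",
    distE = "character", distZ = "character", distEps = "character",
    meanE = "numeric", standardize = "logical", seed = "integerOrNULL"
  ),
  prototype(
    n = 100L, caf = 0.3, tauG = 0, tauE = 0, tauZ = 0, tauGE = 0,
    distE = "normal", distZ = "normal", distEps = "normal",
    meanE = 0, standardize = TRUE, seed = NULL
  )
)

.validDist <- c("normal", "right_skew")

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 10L)
    msg <- c(msg, "'n' must be a single integer >= 10")
  if (length(object@caf) != 1L || is.na(object@caf) ||
      object@caf <= 0 || object@caf > 0.5)
    msg <- c(msg, "'caf' must lie in (0, 0.5]")
  taus <- c(object@tauG, object@tauE, object@tauZ, object@tauGE)
  if (any(is.na(taus)) || any(taus < 0) || any(taus >= 1))
    msg <- c(msg, "variance fractions must lie in [0, 1)")
  if (sum(taus) >= 1)
    msg <- c(msg, "variance fractions must sum to < 1 (residual variance must be positive)")
  for (d in c("distE", "distZ", "distEps")) {
    if (!slot(object, d) %in% .validDist)
      msg <- c(msg, sprintf("'%s' must be one of: %s", d,
                            paste(.validDist, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Realized simulation cohort
#'
#' One replicate drawn from a [ScenarioConfig-class]: raw and standardized
#' genotype dosages, the interacting exposure E, the tested covariate Z, the
#' true generative residual and the outcome, plus the provenance config.
#'
#' @slot gRaw integer dosages in {0, 1, 2}.
#' @slot gStd numeric standardized dosage (theoretical Hardy-Weinberg moments).
#' @slot e,z numeric exposure and covariate vectors.
#' @slot eps numeric true generative residual (retained so that fitted-model
#'   residual variance can be compared against it per genotype class).
#' @slot y numeric outcome.
#' @slot config the generating [ScenarioConfig-class].
#'
#' @export
setClass("Cohort",
  representation(
    gRaw = "integer", gStd = "numeric", e = "numeric", z = "numeric",
    eps = "numeric", y = "numeric", config = "ScenarioConfig"
  )
)

setValidity("Cohort", function(object) {
  n <- length(object@y)
  lens <- c(length(object@gRaw), length(object@gStd), length(object@e),
            length(object@z), length(object@eps))
  if (any(lens != n))
    return("all cohort vectors must share the same length")
  if (any(!object@gRaw %in% 0:2))
    return("raw dosages must be 0, 1 or 2")
  TRUE
})

#' Ordinary least squares fit with leverage bookkeeping
#'
#' Minimal OLS container used by the interaction tests: coefficients,
#' residuals, hat-matrix diagonal, naive covariance and the pieces needed to
#' assemble heteroscedasticity-consistent covariances.
#'
#' @slot coefficients named numeric coefficient vector.
#' @slot residuals numeric residual vector.
#' @slot hat numeric hat-matrix diagonal (one entry per observation).
#' @slot naiveCov naive coefficient covariance \eqn{\hat\sigma^2 (X'X)^{-1}}.
#' @slot xtxInv numeric matrix \eqn{(X'X)^{-1}}.
#' @slot design the model matrix (kept for sandwich assembly).
#' @slot sigma2 numeric(1) residual variance estimate (df-adjusted).
#' @slot dfResidual integer(1).
#'
#' @export
setClass("OLSFit",
  representation(
    coefficients = "numeric", residuals = "numeric", hat = "numeric",
    naiveCov = "matrix", xtxInv = "matrix", design = "matrix",
    sigma2 = "numeric", dfResidual = "integer"
  )
)

setValidity("OLSFit", function(object) {
  p <- length(object@coefficients)
  if (!all(dim(object@naiveCov) == p)) return("naiveCov dimension mismatch")
  if (length(object@hat) != length(object@residuals))
    return("hat and residuals must align")
  TRUE
})

#' Result of a single interaction test
#'
#' @slot strategy character(1), one of \code{"std"}, \code{"hc0"},
#'   \code{"hc3"}, \code{"bin"}, \code{"sat"}.
#' @slot rkt logical(1); was the outcome rank-inverse-normal transformed
#'   before fitting?
#' @slot beta numeric(1) interaction estimate.
#' @slot se numeric(1) standard error under the strategy's covariance.
#' @slot wald numeric(1) Wald chi-square statistic (1 df).
#' @slot p numeric(1) p-value.
#' @slot dfResidual integer(1).
#' @slot droppedColumns character; design columns dropped (saturated model
#'   with an empty genotype class).
#'
#' @export
setClass("InteractionResult",
  representation(
    strategy = "character", rkt = "logical", beta = "numeric",
    se = "numeric", wald = "numeric", p = "numeric",
    dfResidual = "integer", droppedColumns = "character"
  )
)

#' Synthetic genotype + expression screening dataset
#'
#' Container for the two-step trio-screening pipeline: a dosage matrix and an
#' expression matrix over the same samples, genomic coordinates for every SNP
#' and probe (as [GenomicRanges::GRanges]), a transcription-factor flag per
#' probe, and a planted-truth ledger recording which cis effects and
#' interactions were simulated.
#'
#' @slot snpData [SummarizedExperiment::RangedSummarizedExperiment] with one
#'   assay \code{"dosage"} (SNPs x samples) and SNP coordinates as rowRanges.
#' @slot exprData [SummarizedExperiment::RangedSummarizedExperiment] with one
#'   assay \code{"expr"} (probes x samples); \code{rowData(exprData)$is_tf}
#'   flags transcription-factor probes.
#' @slot truth \code{DataFrame} ledger of planted effects (type, snp, probe,
#'   tau, and for interactions the partner probe or \code{"<hidden>"}).
#'
#' @export
setClass("ScreeningDataset",
  representation(
    snpData = "RangedSummarizedExperiment",
    exprData = "RangedSummarizedExperiment",
    truth = "DataFrame"
  )
)

setValidity("ScreeningDataset", function(object) {
  msg <- character()
  if (!identical(colnames(object@snpData), colnames(object@exprData)))
    msg <- c(msg, "sample columns of snpData and exprData must be identical")
  if (!"dosage" %in% SummarizedExperiment::assayNames(object@snpData))
    msg <- c(msg, "snpData must carry a 'dosage' assay")
  if (!"expr" %in% SummarizedExperiment::assayNames(object@exprData))
    msg <- c(msg, "exprData must carry an 'expr' assay")
  if (is.null(SummarizedExperiment::rowData(object@exprData)$is_tf))
    msg <- c(msg, "exprData rowData must contain an 'is_tf' flag")
  dos <- SummarizedExperiment::assay(object@snpData, "dosage")
  if (any(!dos %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})
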