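#' Ordinary least squares with leverage bookkeeping
#'
#' Fits \eqn{y = X\beta + \delta} by least squares and returns, besides the
#' coefficients and residuals, the hat-matrix diagonal and \eqn{(X'X)^{-1}}
#' needed to assemble heteroscedasticity-consistent covariance estimates.
#'
#' @param design numeric model matrix (include the intercept column
#'   yourself; [testInteraction()] does).
#' @param y numeric outcome vector.
#' @return An [OLSFit-class].
#' @examples
#' X <- cbind(1, x = 0:4)
#' fitOls(X, c(1, 3, 2, 5, 4))@coefficients
#' @export
fitOls <- function(design, y) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)) - 1L)
  n <- nrow(design); p <- ncol(design)
  if (length(y) != n) stop("'y' length must match design rows")
  if (n < p + 1L) stop("need at least ncol(design) + 1 observations")
  qrX <- qr(design)
  if (qrX$rank < p) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- qr.coef(qrX, y)
  res <- as.numeric(y - design %*% cf)
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  xtxInv <- chol2inv(qr.R(qrX))
  dimnames(xtxInv) <- list(colnames(design), colnames(design))
  df <- n - p
  sigma2 <- sum(res^2) / df
  new("OLSFit", coefficients = cf, residuals = res, hat = h,
      naiveCov = sigma2 * xtxInv, xtxInv = xtxInv, design = design,
      sigma2 = sigma2, dfResidual = as.integer(df))
}

#' Heteroscedasticity-consistent coefficient covariance
#'
#' White's sandwich estimator
#' \deqn{HC0 = (X'X)^{-1} X' diag(\delta_i^2) X (X'X)^{-1}}
#' and the jackknife-style variant HC3, which replaces \eqn{\delta_i^2} by
#' \eqn{\delta_i^2 / (1 - h_{ii})^2}. HC3 inflates each squared residual by
#' its leverage and is the recommended small-sample choice.
#'
#' @param fit an [OLSFit-class].
#' @param flavor \code{"HC0"} or \code{"HC3"}.
#' @return Coefficient covariance matrix.
#' @export
hcCovariance <- function(fit, flavor = c("HC0", "HC3")) {
  flavor <- match.arg(flavor)
  w <- fit@residuals^2
  if (flavor == "HC3") {
    if (any(fit@hat >= 1 - 1e-12))
      stop("HC3 undefined: an observation has leverage 1")
    w <- w / (1 - fit@hat)^2
  }
  X <- fit@design
  meat <- crossprod(X, w * X)
  fit@xtxInv %*% meat %*% fit@xtxInv
}

.waldFromCov <- function(fit, term, cov, reference = "chisq") {
  beta <- fit@coefficients[[term]]
  se <- sqrt(cov[term, term])
  wald <- (beta / se)^2
  p <- if (reference == "chisq") {
    pchisq(wald, df = 1, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(beta / se), df = fit@dfResidual, lower.tail = FALSE)
  }
  list(beta = beta, se = se, wald = wald, p = p)
}

#' Test a SNP-by-exposure interaction
#'
#' Fits the screening model \eqn{Y \sim G + Z + GZ} (or a robustified
#' variant) and tests the interaction term with a 1-df Wald statistic.
#' Strategies:
#' \describe{
#'   \item{std}{OLS with the naive covariance.}
#'   \item{hc0, hc3}{OLS estimate with the HC0 / HC3 sandwich covariance
#'     (see [hcCovariance()]).}
#'   \item{bin}{Z replaced by a median-split indicator (0 below the median,
#'     1 at or above it); the indicator-by-G term is tested.}
#'   \item{sat}{saturated model with genotype dummy main effects (G = 1,
#'     G = 2; reference G = 0), Z and Z^2 main effects, and the ordinal
#'     G-by-Z interaction term under test. An empty genotype class drops its
#'     dummy (recorded in the result).}
#' }
#'
#' @param y outcome vector.
#' @param g genotype dosage vector (0/1/2; any numeric with >= 2 distinct
#'   values is accepted for the non-saturated strategies).
#' @param z exposure vector.
#' @param strategy one of \code{"std"}, \code{"hc0"}, \code{"hc3"},
#'   \code{"bin"}, \code{"sat"}.
#' @param rkt if TRUE, rank-inverse-normal transform \code{y} first.
#' @param reference \code{"chisq"} (default, Wald chi-square with 1 df) or
#'   \code{"t"} (residual-df Student reference).
#' @return An [InteractionResult-class].
#' @examples
#' set.seed(1)
#' coh <- buildCohort(scenarioConfig(n = 400, caf = 0.3, tauGE = 0.2))
#' testInteraction(outcome(coh), dosages(coh), covariateZ(coh), "hc3")
#' @export
testInteraction <- function(y, g, z,
                            strategy = c("std", "hc0", "hc3", "bin", "sat"),
                            rkt = FALSE, reference = c("chisq", "t")) {
  strategy <- match.arg(strategy)
  reference <- match.arg(reference)
  n <- length(y)
  if (length(g) != n || length(z) != n)
    stop("'y', 'g' and 'z' must share the same length")
  if (length(unique(g)) < 2L)
    stop("untestable variant: 'g' is monomorphic")
  if (length(unique(z)) < 2L)
    stop("degenerate exposure: 'z' is constant")
  if (rkt) y <- rankInverseNormal(y)
  dropped <- character()

  if (strategy %in% c("std", "hc0", "hc3")) {
    X <- cbind(`(Intercept)` = 1, G = g, Z = z, `G:Z` = g * z)
    fit <- fitOls(X, y)
    cov <- switch(strategy,
                  std = fit@naiveCov,
                  hc0 = hcCovariance(fit, "HC0"),
                  hc3 = hcCovariance(fit, "HC3"))
    term <- "G:Z"
  } else if (strategy == "bin") {
    zb <- as.numeric(z >= median(z))
    if (length(unique(zb)) < 2L)
      stop("degenerate exposure: median split is constant")
    X <- cbind(`(Intercept)` = 1, G = g, Zbin = zb, `G:Zbin` = g * zb)
    fit <- fitOls(X, y)
    cov <- fit@naiveCov
    term <- "G:Zbin"
  } else { # sat
    lev <- sort(unique(g))
    if (length(lev) > 3L)
      stop("saturated model requires dosage-coded genotypes (<= 3 classes)")
    ref <- lev[1L]
    dummies <- lapply(lev[-1L], function(l) as.numeric(g == l))
    names(dummies) <- paste0("G", lev[-1L])
    present <- vapply(dummies, function(d) any(d > 0), logical(1))
    dropped <- names(dummies)[!present]
    dummies <- dummies[present]
    X <- cbind(`(Intercept)` = 1,
               do.call(cbind, dummies),
               Z = z, Z2 = z^2, `G:Z` = g * z)
    colnames(X)[seq_along(dummies) + 1L] <- names(dummies)
    fit <- fitOls(X, y)
    cov <- fit@naiveCov
    term <- "G:Z"
  }
  w <- .waldFromCov(fit, term, cov, reference)
  new("InteractionResult", strategy = strategy, rkt = rkt,
      beta = w$beta, se = w$se, wald = w$wald, p = w$p,
      dfResidual = fit@dfResidual, droppedColumns = dropped)
}

#' @export
setMethod("show", "InteractionResult", function(object) {
  cat(sprintf("InteractionResult [%s%s]: beta = %.4g, se = %.4g, wald = %.4g, p = %.4g\n",
              object@strategy, if (object@rkt) "+rkt" else "",
              object@beta, object@se, object@wald, object@p))
  if (length(object@droppedColumns))
    cat("  dropped columns:", paste(object@droppedColumns, collapse = ", "), "\n")
})

#' @describeIn InteractionResult the interaction p-value
#' @param object an InteractionResult
#' @export
pValue <- function(object) object@p

#' Marginal (single-predictor) association test
#'
#' Simple regression slope test of \code{y} on \code{x}; used by the
#' screening pipeline both for step-1 cis-eQTL mapping and for the
#' TF-marginal filter.
#'
#' @param y outcome vector.
#' @param x predictor vector (non-constant).
#' @return list with \code{beta} (slope), \code{r2} (squared sample
#'   correlation) and \code{p} (F-test p-value, 1 and n-2 df).
#' @export
marginalTest <- function(y, x) {
  n <- length(y)
  if (length(x) != n) stop("'y' and 'x' must share the same length")
  if (n < 3L) stop("need at least 3 observations")
  if (var(x) == 0) stop("degenerate predictor: 'x' is constant")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  r2 <- if (syy == 0) 0 else (sxy * sxy) / (sxx * syy)
  p <- if (r2 >= 1) {
    0
  } else {
    pf(r2 * (n - 2) / (1 - r2), 1, n - 2, lower.tail = FALSE)
  }
  list(beta = beta, r2 = r2, p = p)
}

## Lean batch path: std/hc0/hc3 p-values for the 4-column interaction design,
## used by the replicate-heavy simulation drivers. Same algebra as
## fitOls + hcCovariance, kept allocation-light.
.interactionStats3 <- function(y, g, z) {
  X <- cbind(1, g, z, g * z)
  XtX <- crossprod(X)
  R <- chol(XtX)
  xtxInv <- chol2inv(R)
  cf <- xtxInv %*% crossprod(X, y)
  res <- y - as.numeric(X %*% cf)
  XA <- X %*% xtxInv
  h <- rowSums(XA * X)
  df <- length(y) - 4L
  sigma2 <- sum(res^2) / df
  seStd2 <- sigma2 * xtxInv[4L, 4L]
  w0 <- res^2
  w3 <- w0 / (1 - h)^2
  a4 <- XA[, 4L]
  seH02 <- sum(a4 * a4 * w0)
  seH32 <- sum(a4 * a4 * w3)
  b <- cf[4L]
  stat <- b * b / c(std = seStd2, hc0 = seH02, hc3 = seH32)
  list(beta = b, stat = stat,
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       residuals = res)
}
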