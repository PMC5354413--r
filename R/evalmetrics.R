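#' Empirical type I error
#'
#' Fraction of a batch of null p-values falling at or below the rejection
#' level.
#'
#' @param pvals numeric vector of p-values.
#' @param alpha rejection level in (0, 1) (default 0.05).
#' @return Proportion in [0, 1].
#' @export
type1Error <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value batch")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  mean(pvals <= alpha)
}

.CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' Genomic inflation factor
#'
#' Converts each p-value to its 1-df chi-square statistic (upper-tail
#' inverse) and divides the median statistic by the chi-square-1 median
#' (0.4549...). Equals 1 for a calibrated uniform batch; values above 1
#' indicate test-statistic inflation.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return lambda_GC (positive scalar).
#' @export
lambdaGC <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value batch")
  if (any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::median(qchisq(pvals, df = 1, lower.tail = FALSE)) / .CHISQ1_MEDIAN
}

#' Expected vs observed -log10(p) for a QQ plot
#'
#' @param pvals numeric p-values.
#' @param envelope if TRUE, add pointwise 95% confidence bounds from the
#'   Beta order-statistic distribution of uniform quantiles.
#' @return data.frame with columns \code{expected}, \code{observed} (most
#'   significant first) and optionally \code{lower}, \code{upper}.
#' @export
qqPoints <- function(pvals, envelope = FALSE) {
  if (length(pvals) == 0L) stop("empty p-value batch")
  n <- length(pvals)
  i <- seq_len(n)
  out <- data.frame(expected = -log10((i - 0.5) / n),
                    observed = -log10(sort(pvals)))
  if (envelope) {
    out$lower <- -log10(qbeta(0.975, i, n - i + 1))
    out$upper <- -log10(qbeta(0.025, i, n - i + 1))
  }
  out
}

#' Residual-variance profile by genotype class
#'
#' Quantifies interaction-induced heteroscedasticity: within each observed
#' genotype class, the sample variance of the fitted-model residual delta,
#' the sample variance of the true generative residual epsilon, and their
#' difference (subtracting epsilon makes models with different residual
#' scales comparable). Under no interaction the difference is ~0 in every
#' class; a G-by-E interaction with an unmeasured E makes it grow
#' quadratically in the standardized dosage.
#'
#' @param delta residuals from the fitted (misspecified) model.
#' @param gRaw raw genotype dosages (0/1/2).
#' @param eps true generative residuals.
#' @return data.frame with one row per genotype class present (>= 2
#'   observations): \code{class}, \code{n}, \code{varDelta}, \code{varEps},
#'   \code{diff}. Classes with fewer than 2 observations are dropped with a
#'   warning.
#' @export
varianceByGenotype <- function(delta, gRaw, eps) {
  n <- length(delta)
  if (length(gRaw) != n || length(eps) != n)
    stop("'delta', 'gRaw' and 'eps' must align")
  classes <- sort(unique(gRaw))
  rows <- lapply(classes, function(cl) {
    idx <- gRaw == cl
    if (sum(idx) < 2L) return(NULL)
    data.frame(class = cl, n = sum(idx),
               varDelta = var(delta[idx]), varEps = var(eps[idx]),
               diff = var(delta[idx]) - var(eps[idx]))
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped))
    warning(sum(skipped), " genotype class(es) with < 2 observations excluded")
  do.call(rbind, rows[!skipped])
}

#' Interaction-effect sweep: type I error and variance heterogeneity
#'
#' Simulates series of replicates in which the G-by-E interaction fraction
#' tau sweeps over a grid, the interacting exposure E is withheld from the
#' fitted model, and the standard OLS Wald test for the G-by-Z interaction
#' is applied (Z does not interact, so every rejection is a false positive).
#' Optionally each main-effect regime sets the corresponding main-effect
#' fraction equal to the interaction fraction.
#'
#' @param tauGrid interaction variance fractions (default 0 to 0.3).
#' @param regime which main effect accompanies the interaction:
#'   \code{"none"}, \code{"G"}, \code{"E"} or \code{"Z"}; the active main
#'   effect explains the same variance fraction as the interaction.
#' @param n individuals per replicate (default 400).
#' @param reps replicates per tau value (default 10000).
#' @param caf coded-allele frequency (default 0.1, the SNP frequency used
#'   throughout the single-SNP generative simulations; rarer alleles give
#'   stronger leverage to the interaction-induced heteroscedasticity).
#' @param alpha rejection level for the type I error (default 0.05).
#' @param seed root seed; each tau value gets an independent substream.
#' @param profile if TRUE (default), also average the per-genotype
#'   (delta - epsilon) variance differences over replicates.
#' @return list with \code{summary} (data.frame: tau, regime, type1Error,
#'   lambdaGC, reps) and, when profiled, \code{profiles} (data.frame: tau,
#'   class, meanDiff).
#' @export
runTauSweep <- function(tauGrid = seq(0, 0.3, by = 0.05),
                        regime = c("none", "G", "E", "Z"),
                        n = 400L, reps = 10000L, caf = 0.1, alpha = 0.05,
                        seed = 1L, profile = TRUE) {
  regime <- match.arg(regime)
  if (any(tauGrid < 0) || any(2 * tauGrid >= 1))
    stop("inadmissible tau grid: fractions must be >= 0 and regime totals < 1")
  summaries <- vector("list", length(tauGrid))
  profiles <- vector("list", length(tauGrid))
  for (k in seq_along(tauGrid)) {
    tau <- tauGrid[k]
    useSubstream(seed, k - 1L)
    pvals <- numeric(reps)
    diffSums <- c(`0` = 0, `1` = 0, `2` = 0)
    diffCnts <- c(`0` = 0L, `1` = 0L, `2` = 0L)
    for (r in seq_len(reps)) {
      cfg <- scenarioConfig(
        n = n, caf = caf,
        tauG = if (regime == "G") tau else 0,
        tauE = if (regime == "E") tau else 0,
        tauZ = if (regime == "Z") tau else 0,
        tauGE = tau)
      coh <- buildCohort(cfg)
      st <- .interactionStats3(coh@y, coh@gStd, coh@z)
      pvals[r] <- st$p[["std"]]
      if (profile) {
        vp <- suppressWarnings(
          varianceByGenotype(st$residuals, coh@gRaw, coh@eps))
        key <- as.character(vp$class)
        diffSums[key] <- diffSums[key] + vp$diff
        diffCnts[key] <- diffCnts[key] + 1L
      }
    }
    summaries[[k]] <- data.frame(tau = tau, regime = regime,
                                 type1Error = type1Error(pvals, alpha),
                                 lambdaGC = lambdaGC(pvals), reps = reps)
    if (profile) {
      keep <- diffCnts > 0L
      profiles[[k]] <- data.frame(tau = tau,
                                  class = as.integer(names(diffSums)[keep]),
                                  meanDiff = diffSums[keep] / diffCnts[keep],
                                  row.names = NULL)
    }
  }
  out <- list(summary = do.call(rbind, summaries))
  if (profile) out$profiles <- do.call(rbind, profiles)
  out
}

.ALL_STRATEGIES <- c("std", "hc0", "hc3", "bin", "sat")

#' Run one robustness-grid cell
#'
#' Simulates \code{reps} randomized-effects replicates (see
#' [drawGridReplicate()]) and returns the genomic inflation factor and
#' empirical type I error of the requested interaction-test strategies for
#' the null G-by-Z test.
#'
#' \code{dist = "mixture"} draws the all-normal or all-right-skewed regime
#' per replicate with equal probability; \code{regime = "mixture"} keeps the
#' unmeasured-exposure main effect always active and draws the measured
#' covariate's main effect in half the replicates (the pooled regime used
#' when summarizing a sample-size-by-frequency panel).
#'
#' @param n,caf sample size and coded-allele frequency.
#' @param reps number of replicates.
#' @param dist \code{"normal"}, \code{"right_skew"} or \code{"mixture"}.
#' @param regime \code{"E_only"}, \code{"Z_only"}, \code{"both"},
#'   \code{"neither"} or \code{"mixture"}.
#' @param strategies subset of std/hc0/hc3/bin/sat.
#' @param r2Range,epsRule residual-scaling rule (see [drawGridReplicate()]).
#' @param alpha type I error level.
#' @param seed optional seed (plain \code{set.seed}); callers running many
#'   cells should instead seed substreams via [useSubstream()].
#' @param collectP if TRUE, attach the reps x strategies p-value matrix.
#' @return data.frame with one row per strategy (n, caf, dist, regime,
#'   strategy, lambdaGC, type1Error, reps); with \code{collectP}, the matrix
#'   is in \code{attr(, "pvals")}.
#' @export
runGridCell <- function(n, caf, reps = 20000L, dist = "mixture",
                        regime = "mixture",
                        strategies = c("std", "hc0", "hc3"),
                        r2Range = c(0, 0.8),
                        epsRule = c("uniform_r2", "unit"),
                        alpha = 0.05, seed = NULL, collectP = FALSE) {
  epsRule <- match.arg(epsRule)
  strategies <- match.arg(strategies, .ALL_STRATEGIES, several.ok = TRUE)
  if (reps < 100L) stop("lambda_GC is undefined below a minimum batch of 100 replicates")
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(NA_real_, nrow = reps, ncol = length(strategies),
              dimnames = list(NULL, strategies))
  lean <- intersect(strategies, c("std", "hc0", "hc3"))
  heavy <- setdiff(strategies, lean)
  for (r in seq_len(reps)) {
    d <- if (dist == "mixture") {
      if (runif(1) < 0.5) "normal" else "right_skew"
    } else dist
    rg <- if (regime == "mixture") {
      if (runif(1) < 0.5) "E_only" else "both"
    } else regime
    rep <- drawGridReplicate(n, caf, dist = d, regime = rg,
                             r2Range = r2Range, epsRule = epsRule)
    if (length(lean)) {
      st <- .interactionStats3(rep$y, rep$g, rep$z)
      P[r, lean] <- st$p[lean]
    }
    for (s in heavy)
      P[r, s] <- testInteraction(rep$y, rep$gRaw, rep$z, strategy = s)@p
  }
  out <- do.call(rbind, lapply(strategies, function(s) {
    data.frame(n = n, caf = caf, dist = dist, regime = regime, strategy = s,
               lambdaGC = lambdaGC(P[, s]),
               type1Error = type1Error(P[, s], alpha), reps = reps)
  }))
  if (collectP) attr(out, "pvals") <- P
  out
}

#' Run the full robustness grid
#'
#' Iterates [runGridCell()] over every cell of a [gridConfig()], seeding an
#' independent substream per cell so any cell can be recomputed in
#' isolation.
#'
#' @param grid a \code{GridConfig}.
#' @param strategies strategies to evaluate per cell.
#' @param alpha type I error level.
#' @return data.frame, one row per cell x strategy.
#' @export
runGrid <- function(grid, strategies = c("std", "hc0", "hc3"), alpha = 0.05) {
  stopifnot(inherits(grid, "GridConfig"))
  cells <- grid$cells
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    useSubstream(grid$seed, i - 1L)
    res[[i]] <- runGridCell(cells$n[i], cells$caf[i],
                            reps = grid$replicatesPerCell,
                            dist = cells$dist[i], regime = cells$regime[i],
                            strategies = strategies,
                            r2Range = grid$r2Range, epsRule = grid$epsRule,
                            alpha = alpha)
  }
  do.call(rbind, res)
}

#' Expected effect sizes among null tests passing a selection threshold
#'
#' Reconstructs, under a global null, the distribution of the
#' variance-explained (r-squared) values one would report after selecting
#' single-predictor association tests at an FDR threshold: the per-test
#' p-value cutoff is the Benjamini-Hochberg boundary \code{q * k / m}, the
#' null r-squared of a simple regression with \code{n} samples follows
#' Beta(1/2, (n-2)/2), and the p cutoff maps to an r-squared cutoff through
#' the F(1, n-2) relation. Reported are the mean of the truncated Beta above
#' the cutoff (analytic by default) and the expected maximum over \code{m}
#' null draws.
#'
#' @param mTests total number of tests m.
#' @param nSamples sample size n (>= 4).
#' @param qLevel FDR level q.
#' @param kDiscoveries number of discoveries k (<= m).
#' @param method \code{"analytic"} (truncated-beta integrals) or
#'   \code{"simulate"} (m Monte Carlo draws).
#' @return list with \code{pThreshold}, \code{r2Threshold}, \code{meanR2},
#'   \code{maxR2}.
#' @examples
#' nullSelectedR2(1e6, 121, qLevel = 1, kDiscoveries = 1e6)$meanR2  # 1/60
#' @export
nullSelectedR2 <- function(mTests, nSamples, qLevel, kDiscoveries,
                           method = c("analytic", "simulate")) {
  method <- match.arg(method)
  if (kDiscoveries > mTests) stop("'kDiscoveries' cannot exceed 'mTests'")
  if (nSamples < 4) stop("'nSamples' must be >= 4")
  pThr <- min(1, qLevel * kDiscoveries / mTests)
  a <- 0.5
  b <- (nSamples - 2) / 2
  r2Thr <- if (pThr >= 1) {
    0
  } else {
    Fq <- qf(pThr, 1, nSamples - 2, lower.tail = FALSE)
    Fq / (Fq + nSamples - 2)
  }
  if (method == "analytic") {
    surv <- pbeta(r2Thr, a, b, lower.tail = FALSE)
    meanR2 <- (a / (a + b)) * pbeta(r2Thr, a + 1, b, lower.tail = FALSE) / surv
    maxR2 <- stats::integrate(function(x)
      1 - exp(mTests * pbeta(x, a, b, log.p = TRUE)),
      0, 1, rel.tol = 1e-9)$value
  } else {
    chunk <- 2e6
    left <- mTests
    s <- 0; cnt <- 0; mx <- 0
    while (left > 0) {
      k <- min(chunk, left)
      r2 <- stats::rbeta(k, a, b)
      sel <- r2 > r2Thr
      s <- s + sum(r2[sel]); cnt <- cnt + sum(sel)
      mx <- max(mx, max(r2))
      left <- left - k
    }
    meanR2 <- if (cnt > 0) s / cnt else NA_real_
    maxR2 <- mx
  }
  list(pThreshold = pThr, r2Threshold = r2Thr, meanR2 = meanR2, maxR2 = maxR2)
}

#' Transformation paradox demonstration
#'
#' Generates one cohort in either of two regimes with a right-skewed
#' residual and an exposure centred at 5, and tests the SNP-by-exposure
#' interaction on the raw and on the rank-inverse-normal-transformed
#' outcome:
#' \describe{
#'   \item{main_effects}{SNP and exposure each explain 20% of the outcome
#'     variance with no interaction; the transform tends to induce a
#'     spurious interaction.}
#'   \item{interaction}{main effects explain 10% each plus a true
#'     interaction explaining 20%; the transform tends to remove it.}
#' }
#'
#' @param scenario \code{"main_effects"} or \code{"interaction"}.
#' @param n cohort size (default 10000).
#' @param caf coded-allele frequency (default 0.1).
#' @param seed optional seed.
#' @return list with \code{pRaw}, \code{pRkt} (standard-test interaction
#'   p-values), \code{log10pRaw}, \code{log10pRkt} (computed on the log
#'   scale, so extreme significance does not underflow) and the
#'   [Cohort-class].
#' @export
transformationDemo <- function(scenario = c("main_effects", "interaction"),
                               n = 10000L, caf = 0.1, seed = NULL) {
  scenario <- match.arg(scenario)
  cfg <- if (scenario == "main_effects") {
    scenarioConfig(n = n, caf = caf, tauG = 0.2, tauE = 0.2, tauGE = 0,
                   distEps = "right_skew", meanE = 5, seed = seed)
  } else {
    scenarioConfig(n = n, caf = caf, tauG = 0.1, tauE = 0.1, tauGE = 0.2,
                   distEps = "right_skew", meanE = 5, seed = seed)
  }
  coh <- buildCohort(cfg)
  log10p <- function(y) {
    st <- .interactionStats3(y, coh@gStd, coh@e)
    pchisq(st$stat[["std"]], df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  l10Raw <- log10p(coh@y)
  l10Rkt <- log10p(rankInverseNormal(coh@y))
  list(pRaw = 10^l10Raw, pRkt = 10^l10Rkt,
       log10pRaw = l10Raw, log10pRkt = l10Rkt, cohort = coh)
}
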