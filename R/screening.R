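#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols "mcols<-"
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData "rowData<-" rowRanges colData
NULL

#' Generate a synthetic genotype + expression screening dataset
#'
#' Builds a [ScreeningDataset-class] emulating a cis-eQTL SNP-by-TF
#' screening design: Hardy-Weinberg genotypes with per-SNP coded-allele
#' frequencies from Uniform(0.05, 0.5); target-probe expression assembled
#' from planted effects on the variance-fraction scale (residual scaled so
#' each target has unit variance); transcription-factor probe expression
#' standard normal; genomic coordinates placed so both cis-proximal and
#' distal SNP-probe pairs exist. Every planted effect is recorded in the
#' truth ledger.
#'
#' Planted layers (each applied to a random subset of target probes):
#' \describe{
#'   \item{cis}{a SNP within 100 kb of the probe with a main effect
#'     explaining a Uniform draw from \code{cisTauRange} of the target
#'     variance (emulating the large marginal effects typical of
#'     cis-eQTLs).}
#'   \item{tf_main}{a main effect of one measured TF probe.}
#'   \item{interaction}{an interaction between the cis SNP and a measured
#'     TF (the TF also receives a main effect).}
#'   \item{hidden_interaction}{an interaction between the cis SNP and an
#'     \emph{unmeasured} standard-normal factor with its own main effect;
#'     such targets also receive a measured-TF main effect, so the spurious
#'     heteroscedasticity-driven signal concentrates among
#'     strongly-associated TFs.}
#' }
#'
#' @param nSamples,nSnps,nProbes,nTfs dimensions (TF probes are additional
#'   to the \code{nProbes} target probes).
#' @param nChrom,chromLength genome layout for coordinate sampling.
#' @param cisFraction fraction of target probes receiving a planted cis
#'   effect (default 1).
#' @param cisTauRange variance-fraction range of cis effects.
#' @param tfMainFraction fraction of cis-planted targets receiving a
#'   measured-TF main effect.
#' @param tfMainTauRange variance-fraction range of TF main effects.
#' @param interactionFraction fraction of cis-planted targets receiving a
#'   measured SNP-by-TF interaction.
#' @param interactionTauRange variance-fraction range of planted
#'   interactions.
#' @param hiddenFraction fraction of cis-planted targets receiving a
#'   SNP-by-unmeasured-factor interaction.
#' @param hiddenTauRange variance-fraction range (main effect and
#'   interaction each get one draw) for the hidden factor.
#' @param seed optional integer seed.
#' @return A [ScreeningDataset-class].
#' @export
generateScreeningDataset <- function(nSamples, nSnps, nProbes, nTfs,
                                     nChrom = 5L, chromLength = 2e8,
                                     cisFraction = 1,
                                     cisTauRange = c(0.3, 0.6),
                                     tfMainFraction = 0.5,
                                     tfMainTauRange = c(0.1, 0.3),
                                     interactionFraction = 0,
                                     interactionTauRange = c(0.1, 0.3),
                                     hiddenFraction = 0,
                                     hiddenTauRange = c(0.15, 0.3),
                                     seed = NULL) {
  stopifnot(nSamples >= 10, nSnps >= nProbes, nProbes >= 1, nTfs >= 1)
  for (f in c(cisFraction, tfMainFraction, interactionFraction, hiddenFraction))
    if (f < 0 || f > 1) stop("planted fractions must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  sampleIds <- sprintf("S%04d", seq_len(nSamples))
  snpIds <- sprintf("snp%05d", seq_len(nSnps))
  targetIds <- sprintf("probe%05d", seq_len(nProbes))
  tfIds <- sprintf("tf%05d", seq_len(nTfs))

  probeChrom <- sample(nChrom, nProbes, replace = TRUE)
  probePos <- as.integer(runif(nProbes, 1, chromLength))
  # first nProbes SNPs are placed near probe i; the rest anywhere
  snpChrom <- c(probeChrom,
                sample(nChrom, nSnps - nProbes, replace = TRUE))
  snpPos <- c(pmax(1L, probePos + as.integer(runif(nProbes, -1e5, 1e5))),
              as.integer(runif(nSnps - nProbes, 1, chromLength)))
  tfChrom <- sample(nChrom, nTfs, replace = TRUE)
  tfPos <- as.integer(runif(nTfs, 1, chromLength))

  caf <- runif(nSnps, 0.05, 0.5)
  dosage <- vapply(seq_len(nSnps), function(j) sampleGenotypes(nSamples, caf[j]),
                   integer(nSamples))
  dimnames(dosage) <- list(sampleIds, snpIds)

  tfExpr <- matrix(rnorm(nSamples * nTfs), nSamples, nTfs,
                   dimnames = list(sampleIds, tfIds))

  nCis <- round(cisFraction * nProbes)
  cisTargets <- if (nCis > 0) sort(sample(nProbes, nCis)) else integer()
  truth <- list()
  targetExpr <- matrix(0, nSamples, nProbes,
                       dimnames = list(sampleIds, targetIds))
  for (i in seq_len(nProbes)) {
    # collect the planted components first; if their variance fractions sum
    # beyond 0.9 they are scaled down proportionally so the residual
    # variance stays positive (realized taus go into the ledger)
    comps <- list()   # each: list(vec, tau, truthRow or NULL)
    addComp <- function(vec, tau, type, snp, partner, record = TRUE) {
      comps[[length(comps) + 1L]] <<- list(
        vec = vec, tau = tau,
        row = if (record) data.frame(type = type, snp = snp,
                                     probe = targetIds[i], partner = partner,
                                     tau = tau) else NULL)
    }
    if (i %in% cisTargets) {
      snpIdx <- i  # the co-located SNP
      gStd <- standardizeDosage(dosage[, snpIdx], caf[snpIdx])
      addComp(gStd, runif(1, cisTauRange[1], cisTauRange[2]),
              "cis", snpIds[snpIdx], NA_character_)
      if (runif(1) < tfMainFraction) {
        tfIdx <- sample(nTfs, 1L)
        addComp(tfExpr[, tfIdx], runif(1, tfMainTauRange[1], tfMainTauRange[2]),
                "tf_main", NA_character_, tfIds[tfIdx])
      }
      if (runif(1) < interactionFraction) {
        tfIdx <- sample(nTfs, 1L)
        addComp(tfExpr[, tfIdx], runif(1, tfMainTauRange[1], tfMainTauRange[2]),
                "tf_main", NA_character_, tfIds[tfIdx])
        addComp(gStd * tfExpr[, tfIdx],
                runif(1, interactionTauRange[1], interactionTauRange[2]),
                "interaction", snpIds[snpIdx], tfIds[tfIdx])
      }
      if (runif(1) < hiddenFraction) {
        u <- rnorm(nSamples)
        tfIdx <- sample(nTfs, 1L)
        addComp(tfExpr[, tfIdx], runif(1, tfMainTauRange[1], tfMainTauRange[2]),
                "tf_main", NA_character_, tfIds[tfIdx])
        addComp(u, runif(1, hiddenTauRange[1], hiddenTauRange[2]),
                "hidden_main", snpIds[snpIdx], "<hidden>", record = FALSE)
        addComp(gStd * u, runif(1, hiddenTauRange[1], hiddenTauRange[2]),
                "hidden_interaction", snpIds[snpIdx], "<hidden>")
      }
    }
    taus <- vapply(comps, `[[`, numeric(1), "tau")
    total <- sum(taus)
    if (total > 0.9) taus <- taus * 0.9 / total
    yi <- numeric(nSamples)
    for (k in seq_along(comps)) {
      yi <- yi + sqrt(taus[k]) * comps[[k]]$vec
      if (!is.null(comps[[k]]$row)) {
        comps[[k]]$row$tau <- taus[k]
        truth[[length(truth) + 1L]] <- comps[[k]]$row
      }
    }
    targetExpr[, i] <- yi + rnorm(nSamples, sd = sqrt(1 - sum(taus)))
  }

  snpGR <- GRanges(paste0("chr", snpChrom), IRanges(snpPos, width = 1L))
  names(snpGR) <- snpIds
  mcols(snpGR)$caf <- caf
  probeGR <- GRanges(paste0("chr", c(probeChrom, tfChrom)),
                     IRanges(c(probePos, tfPos), width = 1L))
  names(probeGR) <- c(targetIds, tfIds)

  snpSE <- SummarizedExperiment(
    assays = list(dosage = t(dosage)), rowRanges = snpGR)
  exprSE <- SummarizedExperiment(
    assays = list(expr = t(cbind(targetExpr, tfExpr))), rowRanges = probeGR)
  rowData(exprSE)$is_tf <- c(rep(FALSE, nProbes), rep(TRUE, nTfs))

  truthDF <- if (length(truth)) {
    DataFrame(do.call(rbind, truth))
  } else {
    DataFrame(type = character(), snp = character(), probe = character(),
              partner = character(), tau = numeric())
  }
  new("ScreeningDataset", snpData = snpSE, exprData = exprSE, truth = truthDF)
}

#' @export
setMethod("show", "ScreeningDataset", function(object) {
  isTf <- rowData(object@exprData)$is_tf
  cat("ScreeningDataset:", ncol(object@snpData), "samples,",
      nrow(object@snpData), "SNPs,", sum(!isTf), "target probes,",
      sum(isTf), "TF probes\n")
  if (nrow(object@truth))
    cat("  planted truth:", paste(sprintf("%s x%d", names(table(object@truth$type)),
                                          as.integer(table(object@truth$type))),
                                  collapse = ", "), "\n")
})

#' @describeIn ScreeningDataset samples x SNPs dosage matrix
#' @param x a ScreeningDataset
#' @export
genotypeMatrix <- function(x) t(assay(x@snpData, "dosage"))

#' @describeIn ScreeningDataset samples x probes expression matrix (targets
#'   and TFs)
#' @export
expressionMatrix <- function(x) t(assay(x@exprData, "expr"))

#' @describeIn ScreeningDataset SNP coordinates as GRanges
#' @export
snpRanges <- function(x) rowRanges(x@snpData)

#' @describeIn ScreeningDataset probe coordinates as GRanges (with is_tf in
#'   the dataset's rowData)
#' @export
probeRanges <- function(x) rowRanges(x@exprData)

#' @describeIn ScreeningDataset logical TF flag per probe
#' @export
isTF <- function(x) {
  setNames(rowData(x@exprData)$is_tf, rownames(x@exprData))
}

#' @describeIn ScreeningDataset the planted-truth ledger
#' @export
plantedTruth <- function(x) x@truth

.featureCoords <- function(gr) {
  data.frame(id = names(gr),
             chrom = as.character(seqnames(gr)),
             pos = start(gr), stringsAsFactors = FALSE)
}

#' Step 1: map cis-eQTLs and keep the top SNP per probe
#'
#' Tests every SNP-target pair on the same chromosome within \code{window}
#' bases (inclusive) with [marginalTest()], adjusts all tested pairs with
#' Benjamini-Hochberg, keeps pairs with adjusted p (q) at or below
#' \code{qMax}, and retains the single most significant SNP per target
#' probe (ties broken by SNP id).
#'
#' @param ds a [ScreeningDataset-class].
#' @param window cis window in bases (default 250000).
#' @param qMax FDR threshold (default 0.01).
#' @return data.frame of eQTL hits: \code{probe}, \code{snp}, \code{p},
#'   \code{q}, \code{r2} (empty, with a warning, when no cis pair exists).
#' @export
selectCisEqtls <- function(ds, window = 250000, qMax = 0.01) {
  snps <- .featureCoords(snpRanges(ds))
  probes <- .featureCoords(probeRanges(ds))
  probes <- probes[!isTF(ds), , drop = FALSE]
  geno <- genotypeMatrix(ds)
  expr <- expressionMatrix(ds)

  pairs <- list()
  for (i in seq_len(nrow(probes))) {
    sel <- snps$chrom == probes$chrom[i] &
      abs(snps$pos - probes$pos[i]) <= window
    if (any(sel))
      pairs[[length(pairs) + 1L]] <- data.frame(
        probe = probes$id[i], snp = snps$id[sel], stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    warning("no SNP-probe pair within the cis window")
    return(data.frame(probe = character(), snp = character(),
                      p = numeric(), q = numeric(), r2 = numeric()))
  }
  pairs <- do.call(rbind, pairs)
  stats <- mapply(function(pr, sn) {
    g <- geno[, sn]
    if (length(unique(g)) < 2L) return(c(NA_real_, NA_real_))
    mt <- marginalTest(expr[, pr], g)
    c(mt$p, mt$r2)
  }, pairs$probe, pairs$snp)
  pairs$p <- stats[1L, ]
  pairs$r2 <- stats[2L, ]
  pairs <- pairs[!is.na(pairs$p), , drop = FALSE]
  pairs$q <- p.adjust(pairs$p, method = "BH")
  hits <- pairs[pairs$q <= qMax, , drop = FALSE]
  if (!nrow(hits)) {
    warning("no cis-eQTL passes q <= ", qMax)
    return(hits[, c("probe", "snp", "p", "q", "r2")])
  }
  hits <- hits[order(hits$probe, hits$p, hits$snp), , drop = FALSE]
  hits <- hits[!duplicated(hits$probe), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("probe", "snp", "p", "q", "r2")]
}

#' Step 2 trio construction: TF-marginal and distance filters
#'
#' Pairs every eQTL hit with every transcription-factor probe whose marginal
#' association with the target is nominally significant
#' (\code{p < tfPMax}) and which lies farther than \code{exclusion} bases
#' from the hit SNP (or on another chromosome; the exclusion avoids
#' confounding by a shared cis effect on two nearby genes).
#'
#' @param ds a [ScreeningDataset-class].
#' @param hits data.frame from [selectCisEqtls()].
#' @param tfPMax TF marginal p-value filter (default 0.05, strict
#'   inequality).
#' @param exclusion exclusion distance in bases (default 1e7; TFs at a
#'   distance <= exclusion on the SNP's chromosome are removed).
#' @return data.frame of trios: \code{snp}, \code{target}, \code{tf},
#'   \code{tfMarginalP} (possibly empty).
#' @export
buildTrios <- function(ds, hits, tfPMax = 0.05, exclusion = 1e7) {
  if (!nrow(hits)) stop("'hits' is empty")
  snps <- .featureCoords(snpRanges(ds))
  probes <- .featureCoords(probeRanges(ds))
  tf <- isTF(ds)
  tfs <- probes[tf, , drop = FALSE]
  expr <- expressionMatrix(ds)

  out <- list()
  for (i in seq_len(nrow(hits))) {
    snpRow <- snps[match(hits$snp[i], snps$id), ]
    y <- expr[, hits$probe[i]]
    for (j in seq_len(nrow(tfs))) {
      if (tfs$chrom[j] == snpRow$chrom &&
          abs(tfs$pos[j] - snpRow$pos) <= exclusion) next
      mp <- marginalTest(y, expr[, tfs$id[j]])$p
      if (mp < tfPMax)
        out[[length(out) + 1L]] <- data.frame(
          snp = hits$snp[i], target = hits$probe[i], tf = tfs$id[j],
          tfMarginalP = mp, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(snp = character(), target = character(),
                      tf = character(), tfMarginalP = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.denseRank <- function(p) {
  # ascending p, ties broken by position for determinism
  ord <- order(p, seq_along(p))
  r <- integer(length(p))
  r[ord] <- seq_along(p)
  r
}

#' Step 2 interaction screening over trios
#'
#' For every trio tests the SNP-by-TF interaction on the target expression
#' under the four analysis strategies of the screening design: standard OLS
#' Wald on the raw outcome (\code{std}), HC3 sandwich Wald on the raw
#' outcome (\code{h3}), and both repeated on the rank-inverse-normal
#' transformed outcome (\code{rkt}, \code{rkt.h3}). Per-strategy ranks
#' (ascending p, ties broken by trio order) and significance flags at
#' \code{sig} are attached. Trios whose SNP is monomorphic are skipped and
#' flagged. P-values that underflow double precision are floored at 1e-300
#' so downstream inflation summaries stay defined.
#'
#' @param ds a [ScreeningDataset-class].
#' @param trios data.frame from [buildTrios()].
#' @param sig genome-wide significance threshold (default 1e-8).
#' @return data.frame with one row per testable trio: identifiers,
#'   \code{tfMarginalP}, \code{pStd}, \code{pH3}, \code{pRkt},
#'   \code{pRktH3}, matching \code{rank*} and \code{sig*} columns.
#'   Skipped trios are reported in \code{attr(, "skipped")}.
#' @export
screenTrios <- function(ds, trios, sig = 1e-8) {
  if (!nrow(trios)) stop("'trios' is empty")
  geno <- genotypeMatrix(ds)
  expr <- expressionMatrix(ds)
  n <- nrow(trios)
  P <- matrix(NA_real_, n, 4L,
              dimnames = list(NULL, c("pStd", "pH3", "pRkt", "pRktH3")))
  rktCache <- new.env(parent = emptyenv())
  skipped <- logical(n)
  for (i in seq_len(n)) {
    g <- geno[, trios$snp[i]]
    if (length(unique(g)) < 2L) { skipped[i] <- TRUE; next }
    y <- expr[, trios$target[i]]
    z <- expr[, trios$tf[i]]
    key <- trios$target[i]
    if (is.null(rktCache[[key]])) rktCache[[key]] <- rankInverseNormal(y)
    raw <- .interactionStats3(y, g, z)
    trn <- .interactionStats3(rktCache[[key]], g, z)
    P[i, ] <- pmax(c(raw$p[["std"]], raw$p[["hc3"]],
                     trn$p[["std"]], trn$p[["hc3"]]), 1e-300)
  }
  res <- cbind(trios[!skipped, , drop = FALSE],
               as.data.frame(P[!skipped, , drop = FALSE]))
  for (s in c("Std", "H3", "Rkt", "RktH3")) {
    res[[paste0("rank", s)]] <- .denseRank(res[[paste0("p", s)]])
    res[[paste0("sig", s)]] <- res[[paste0("p", s)]] < sig
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- trios[skipped, , drop = FALSE]
  res
}

#' Genomic inflation stratified by TF-marginal association strength
#'
#' Splits the screened trios into strata of the TF-target marginal p-value
#' and reports each strategy's genomic inflation factor within each
#' stratum. Strata covering fewer than 100 tests are flagged unreliable.
#'
#' @param results data.frame from [screenTrios()].
#' @param breaks increasing bin edges over (0, 1] for \code{tfMarginalP}
#'   (lower bound excluded, upper included).
#' @param minTests reliability floor per stratum (default 100).
#' @return data.frame: stratum bounds, \code{n}, \code{strategy},
#'   \code{lambdaGC}, \code{reliable}.
#' @export
stratifiedLambda <- function(results,
                             breaks = c(0, 1e-4, 1e-3, 1e-2, 0.05),
                             minTests = 100L) {
  if (!nrow(results)) stop("'results' is empty")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("'breaks' must be strictly increasing")
  cols <- c(std = "pStd", h3 = "pH3", rkt = "pRkt", rkt.h3 = "pRktH3")
  bin <- cut(results$tfMarginalP, breaks = breaks, include.lowest = FALSE)
  out <- list()
  for (b in seq_len(length(breaks) - 1L)) {
    idx <- which(as.integer(bin) == b)
    for (s in names(cols)) {
      lam <- if (length(idx) > 0L) lambdaGC(results[[cols[s]]][idx]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        lower = breaks[b], upper = breaks[b + 1L], n = length(idx),
        strategy = s, lambdaGC = lam,
        reliable = length(idx) >= minTests)
    }
  }
  do.call(rbind, out)
}
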