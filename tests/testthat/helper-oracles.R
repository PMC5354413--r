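# Independent oracles used to cross-check the package implementation.
# These deliberately use naive, brute-force formulations (explicit matrix
# products, exhaustive loops) rather than the package's own code paths.

# sandwich covariance by explicit triple matrix product
bruteSandwich <- function(X, residuals, flavor = c("HC0", "HC3")) {
  flavor <- match.arg(flavor)
  X <- as.matrix(X)
  bread <- solve(t(X) %*% X)
  H <- X %*% bread %*% t(X)
  w <- residuals^2
  if (flavor == "HC3") w <- w / (1 - diag(H))^2
  bread %*% (t(X) %*% diag(w) %*% X) %*% bread
}

# exhaustive trio-filter oracle over raw matrices and coordinates: applies
# the cis window, BH selection, top-SNP rule, TF marginal filter and the
# exclusion distance with plain loops and cor.test
bruteTrioOracle <- function(ds, window = 250000, qMax = 0.01,
                            tfPMax = 0.05, exclusion = 1e7) {
  geno <- genotypeMatrix(ds)
  expr <- expressionMatrix(ds)
  sgr <- snpRanges(ds); pgr <- probeRanges(ds)
  snp <- data.frame(id = names(sgr), chrom = as.character(GenomicRanges::seqnames(sgr)),
                    pos = GenomicRanges::start(sgr))
  prb <- data.frame(id = names(pgr), chrom = as.character(GenomicRanges::seqnames(pgr)),
                    pos = GenomicRanges::start(pgr), tf = unname(isTF(ds)))
  targets <- prb[!prb$tf, ]
  tfs <- prb[prb$tf, ]

  pairs <- NULL
  for (i in seq_len(nrow(targets))) for (j in seq_len(nrow(snp))) {
    if (targets$chrom[i] == snp$chrom[j] &&
        abs(targets$pos[i] - snp$pos[j]) <= window) {
      g <- geno[, snp$id[j]]
      if (length(unique(g)) < 2) next
      ct <- stats::cor.test(expr[, targets$id[i]], g)
      pairs <- rbind(pairs, data.frame(probe = targets$id[i], snp = snp$id[j],
                                       p = ct$p.value))
    }
  }
  if (is.null(pairs)) return(list(hits = NULL, trios = NULL))
  pairs$q <- p.adjust(pairs$p, "BH")
  keep <- pairs[pairs$q <= qMax, ]
  hits <- NULL
  for (pr in unique(keep$probe)) {
    sub <- keep[keep$probe == pr, ]
    sub <- sub[order(sub$p, sub$snp), ]
    hits <- rbind(hits, sub[1, ])
  }
  trios <- NULL
  if (!is.null(hits)) for (i in seq_len(nrow(hits))) {
    srow <- snp[snp$id == hits$snp[i], ]
    for (j in seq_len(nrow(tfs))) {
      sameChromClose <- tfs$chrom[j] == srow$chrom &&
        abs(tfs$pos[j] - srow$pos) <= exclusion
      if (sameChromClose) next
      mp <- stats::cor.test(expr[, hits$probe[i]], expr[, tfs$id[j]])$p.value
      if (mp < tfPMax)
        trios <- rbind(trios, data.frame(snp = hits$snp[i],
                                         target = hits$probe[i],
                                         tf = tfs$id[j]))
    }
  }
  list(hits = hits, trios = trios)
}

trioKey <- function(df) {
  if (is.null(df) || !nrow(df)) return(character())
  sort(paste(df$snp, df$target, df$tf, sep = "|"))
}
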