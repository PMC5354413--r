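test_that("the generator replays and records its planted truth", {
  ds1 <- generateScreeningDataset(100, 20, 10, 8, seed = 61)
  ds2 <- generateScreeningDataset(100, 20, 10, 8, seed = 61)
  expect_identical(genotypeMatrix(ds1), genotypeMatrix(ds2))
  expect_identical(expressionMatrix(ds1), expressionMatrix(ds2))
  expect_identical(as.data.frame(plantedTruth(ds1)),
                   as.data.frame(plantedTruth(ds2)))
  expect_equal(sum(isTF(ds1)), 8)
  expect_equal(dim(genotypeMatrix(ds1)), c(100, 20))
  # every planted cis target has unit-variance expression by construction
  expr <- expressionMatrix(ds1)[, !isTF(ds1)]
  expect_true(all(abs(apply(expr, 2, var) - 1) < 0.6))
  expect_error(generateScreeningDataset(100, 20, 10, 8, cisFraction = 2),
               "fractions")
})

test_that("strong planted cis effects are recovered at q <= 0.01", {
  ds <- generateScreeningDataset(500, 40, 20, 10,
                                 cisTauRange = c(0.5, 0.5),
                                 tfMainFraction = 0, seed = 62)
  hits <- selectCisEqtls(ds)
  truth <- as.data.frame(plantedTruth(ds))
  planted <- truth[truth$type == "cis", ]
  found <- merge(planted, hits, by = c("probe", "snp"))
  expect_gte(nrow(found), nrow(planted) - 1)
  expect_true(all(hits$q >= hits$p))
  expect_false(any(duplicated(hits$probe)))
})

test_that("top-SNP selection keeps the causal SNP among cis competitors", {
  ds <- generateScreeningDataset(400, 60, 20, 10,
                                 cisTauRange = c(0.5, 0.5),
                                 tfMainFraction = 0, seed = 63)
  hits <- selectCisEqtls(ds)
  truth <- as.data.frame(plantedTruth(ds))
  planted <- truth[truth$type == "cis", ]
  m <- merge(hits, planted, by = "probe", suffixes = c(".hit", ".true"))
  expect_gt(mean(m$snp.hit == m$snp.true), 0.9)
})

test_that("trio filters agree exhaustively with the brute-force oracle", {
  ds <- generateScreeningDataset(150, 30, 12, 15, nChrom = 2,
                                 tfMainFraction = 1, seed = 64)
  hits <- selectCisEqtls(ds)
  trios <- buildTrios(ds, hits)
  oracle <- bruteTrioOracle(ds)
  expect_identical(trioKey(trios), trioKey(oracle$trios))
  expect_setequal(hits$snp, oracle$hits$snp)
  # explicit filter rules on the package output
  sgr <- snpRanges(ds); pgr <- probeRanges(ds)
  for (i in seq_len(nrow(trios))) {
    s <- sgr[trios$snp[i]]; tf <- pgr[trios$tf[i]]
    sameChrom <- as.character(GenomicRanges::seqnames(s)) ==
      as.character(GenomicRanges::seqnames(tf))
    if (sameChrom)
      expect_gt(abs(GenomicRanges::start(s) - GenomicRanges::start(tf)), 1e7)
    expect_lt(trios$tfMarginalP[i], 0.05)
  }
})

test_that("distance and marginal filters apply their stated bounds", {
  # hand-placed geometry: one target + cis SNP, three TFs
  dir <- withr::local_tempdir()
  set.seed(65)
  n <- 120
  g <- sampleGenotypes(n, 0.4)
  tfNear <- rnorm(n)            # 5 Mb away: excluded by distance
  tfWeak <- rnorm(n)            # far but marginally unassociated
  yTarget <- 0.8 * standardizeDosage(g, 0.4) + rnorm(n, sd = 0.6)
  tfGood <- yTarget + rnorm(n)  # far and strongly associated
  ids <- sprintf("S%03d", 1:n)
  writeTsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  writeTsv(data.frame(sample_id = ids, snp1 = g), "geno.tsv")
  writeTsv(data.frame(sample_id = ids, target1 = yTarget, tfNear = tfNear,
                      tfWeak = tfWeak, tfGood = tfGood), "expr.tsv")
  writeTsv(data.frame(
    id = c("snp1", "target1", "tfNear", "tfWeak", "tfGood"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(1e6, 1.1e6, 6e6, 5e5, 8e7),
    is_tf = c(FALSE, FALSE, TRUE, TRUE, TRUE)), "annot.tsv")
  ds <- screeningDatasetFromFiles(file.path(dir, "geno.tsv"),
                                  file.path(dir, "expr.tsv"),
                                  file.path(dir, "annot.tsv"))
  hits <- selectCisEqtls(ds)
  expect_equal(hits$snp, "snp1")
  trios <- buildTrios(ds, hits)
  expect_identical(trios$tf, "tfGood")
})

test_that("screening ranks are permutations and planted trios surface", {
  ds <- generateScreeningDataset(1000, 60, 30, 40,
                                 interactionFraction = 0.3,
                                 interactionTauRange = c(0.2, 0.2),
                                 tfMainFraction = 0.3, seed = 66)
  hits <- selectCisEqtls(ds)
  trios <- buildTrios(ds, hits)
  res <- screenTrios(ds, trios)
  for (cl in c("rankStd", "rankH3", "rankRkt", "rankRktH3"))
    expect_identical(sort(res[[cl]]), seq_len(nrow(res)))
  truth <- as.data.frame(plantedTruth(ds))
  planted <- truth[truth$type == "interaction", ]
  planted <- merge(planted, res,
                   by.x = c("snp", "probe", "partner"),
                   by.y = c("snp", "target", "tf"))
  # planted interactions that survive the filters are detected by HC3
  expect_gt(nrow(planted), 0)
  expect_gt(mean(planted$pH3 < 1e-8), 0.8)
  expect_true(all(planted$rankH3 <= max(1, 0.1 * nrow(res))))
})

test_that("stratified lambda reduces to the pooled value on one stratum", {
  ds <- generateScreeningDataset(400, 40, 20, 30, tfMainFraction = 1,
                                 seed = 67)
  res <- screenTrios(ds, buildTrios(ds, selectCisEqtls(ds)))
  sl <- stratifiedLambda(res, breaks = c(0, 1), minTests = 10)
  pooled <- sl[sl$strategy == "h3", ]
  expect_equal(pooled$lambdaGC, lambdaGC(res$pH3), tolerance = 1e-12)
  expect_equal(pooled$n, nrow(res))
  expect_error(stratifiedLambda(res, breaks = c(0.5, 0.1)), "increasing")
})
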