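test_that("genotype sampling follows Hardy-Weinberg proportions", {
  set.seed(11)
  g <- sampleGenotypes(1e6, 0.5)
  freq <- tabulate(g + 1L, 3L) / 1e6
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.01)
  expect_equal(mean(sampleGenotypes(1e6, 0.1)), 0.2, tolerance = 0.01)
  expect_true(all(sampleGenotypes(100, 1e-9) == 0))
  expect_error(sampleGenotypes(100, 0.6), "caf")
  expect_error(sampleGenotypes(100, 0), "caf")
  expect_error(sampleGenotypes(0, 0.3), "positive")
})

test_that("skewed sampler is standardized with the expected skewness", {
  set.seed(12)
  x <- sampleSkewed(1e6)
  expect_equal(mean(x), 0, tolerance = 0.005)
  expect_equal(var(x), 1, tolerance = 0.01)
  skew <- mean((x - mean(x))^3) / stats::sd(x)^3
  # closed-form skew-normal skewness at slant 5
  expect_equal(skew, 0.850965, tolerance = 0.02)
  # zero slant reduces to the standard normal
  set.seed(13)
  ks <- stats::ks.test(sampleSkewed(1e4, alpha = 0), "pnorm")
  expect_gt(ks$p.value, 0.01)
  # skewness sign is stably positive at moderate n
  for (s in 1:20) {
    set.seed(100 + s)
    xs <- sampleSkewed(1e4)
    expect_gt(mean((xs - mean(xs))^3), 0)
  }
})

test_that("coefficient calibration realizes the requested variance fraction", {
  expect_equal(coefFromTau(0), 0)
  expect_equal(coefFromTau(0.3), 0.5477226, tolerance = 1e-6)
  expect_equal(coefFromTau(0.2), 0.4472136, tolerance = 1e-6)
  expect_error(coefFromTau(1), "tau")
  expect_error(coefFromTau(-0.1), "tau")
  # Monte-Carlo round trip over a tau grid
  set.seed(14)
  n <- 1e6
  g <- standardizeDosage(sampleGenotypes(n, 0.3), 0.3)
  e <- rnorm(n)
  for (tau in seq(0.05, 0.3, by = 0.05)) {
    y <- coefFromTau(tau) * g * e + rnorm(n, sd = sqrt(1 - tau))
    expect_equal(var(coefFromTau(tau) * g * e) / var(y), tau,
                 tolerance = 0.005)
  }
})

test_that("cohort variance decomposes into the configured fractions", {
  cfg <- scenarioConfig(n = 1e6, caf = 0.2, tauG = 0.1, tauE = 0.1,
                        tauZ = 0.1, tauGE = 0.1, seed = 15)
  coh <- buildCohort(cfg)
  g <- dosagesStd(coh); e <- exposure(coh); z <- covariateZ(coh)
  comps <- cbind(sqrt(0.1) * g, sqrt(0.1) * e, sqrt(0.1) * z,
                 sqrt(0.1) * g * e, trueResidual(coh))
  compVars <- apply(comps, 2, var)
  expect_equal(compVars, c(0.1, 0.1, 0.1, 0.1, 0.6), tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(var(outcome(coh)), 1, tolerance = 0.01)
  # orthogonality: component variances add up to the outcome variance
  expect_lt(abs(sum(compVars) - var(outcome(coh))), 0.01)
})

test_that("the complete null cohort carries no detectable effects", {
  for (s in 1:3) {
    coh <- buildCohort(scenarioConfig(n = 1e4, caf = 0.3, seed = 20 + s))
    fit <- summary(lm(outcome(coh) ~ dosagesStd(coh) * covariateZ(coh)))
    expect_true(all(fit$coefficients[-1, "Pr(>|t|)"] > 1e-4))
  }
})

test_that("main-effects-only regime yields the expected joint R2", {
  # SNP and exposure each explain 20% of the outcome variance
  cfg <- scenarioConfig(n = 1e4, caf = 0.1, tauG = 0.2, tauE = 0.2,
                        distEps = "right_skew", meanE = 5, seed = 16)
  coh <- buildCohort(cfg)
  r2 <- summary(lm(outcome(coh) ~ dosagesStd(coh) + exposure(coh)))$r.squared
  expect_equal(r2, 0.40, tolerance = 0.03)
})

test_that("cohorts replay bit-identically from their config", {
  cfg <- scenarioConfig(n = 500, caf = 0.1, tauGE = 0.2, seed = 42,
                        distE = "right_skew")
  c1 <- buildCohort(cfg); c2 <- buildCohort(cfg)
  expect_identical(outcome(c1), outcome(c2))
  expect_identical(dosages(c1), dosages(c2))
  expect_identical(trueResidual(c1), trueResidual(c2))
})

test_that("scenario validation rejects inadmissible configurations", {
  expect_error(scenarioConfig(n = 5, caf = 0.3), "n")
  expect_error(scenarioConfig(n = 100, caf = 0.7), "caf")
  expect_error(scenarioConfig(n = 100, caf = 0.3, tauG = 0.5, tauE = 0.5),
               "sum")
  expect_error(scenarioConfig(n = 100, caf = 0.3, distE = "cauchy"), "distE")
})

test_that("randomized-effects replicates honor regime and R2 targets", {
  useSubstream(17, 0)
  r <- drawGridReplicate(1000, 0.3, regime = "neither")
  expect_identical(unname(r$gamma[c("E", "Z")]), c(0, 0))
  expect_true(all(r$gamma[c("G", "GE")] > 0))
  # realized explained fraction matches the drawn target
  useSubstream(17, 1)
  r <- drawGridReplicate(1e5, 0.3, regime = "both")
  sys <- r$y - r$eps
  expect_equal(var(sys) / var(r$y), r$targetR2, tolerance = 0.01)
  # degenerate range pins the explained fraction
  useSubstream(17, 2)
  r <- drawGridReplicate(1e5, 0.3, regime = "both", r2Range = c(0.8, 0.8))
  expect_equal(var(r$y - r$eps) / var(r$y), 0.8, tolerance = 0.01)
})

test_that("substreams are reproducible and order-independent", {
  useSubstream(7, 3); a <- rnorm(5)
  useSubstream(7, 0); invisible(rnorm(2))
  useSubstream(7, 3); b <- rnorm(5)
  expect_identical(a, b)
  useSubstream(7, 4); expect_false(identical(rnorm(5), a))
})

test_that("grid configuration enumerates the full scenario set", {
  gc <- gridConfig()
  expect_equal(nrow(gc$cells), 96)
  expect_error(gridConfig(r2Range = c(0.5, 0.2)))
})

test_that("cohorts export as tidy tables", {
  coh <- buildCohort(scenarioConfig(n = 50, caf = 0.3, seed = 1))
  df <- as.data.frame(coh)
  expect_equal(colnames(df), c("sample_id", "G", "E", "Z", "Y"))
  expect_equal(nrow(df), 50)
})
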