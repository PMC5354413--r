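test_that("least squares recovers exact and hand-computed fits", {
  # noiseless data: interpolation
  x <- c(1, 2, 3, 4, 5)
  fit <- fitOls(cbind(1, x = x), 2 + 3 * x)
  expect_equal(max(abs(fit@residuals)), 0, tolerance = 1e-12)
  expect_equal(unname(fit@coefficients), c(2, 3), tolerance = 1e-12)
  # worked 5-point example, cross-checked against lm
  X <- cbind(1, x = 0:4)
  y <- c(1, 3, 2, 5, 4)
  fit <- fitOls(X, y)
  ref <- lm(y ~ I(0:4))
  expect_equal(unname(fit@coefficients), unname(coef(ref)), tolerance = 1e-12)
  expect_equal(unname(fit@coefficients), c(1.4, 0.8), tolerance = 1e-12)
})

test_that("fit invariants hold: hat trace, orthogonality, rank errors", {
  set.seed(41)
  for (p in 2:4) {
    X <- cbind(1, matrix(rnorm(60 * (p - 1)), 60))
    y <- rnorm(60)
    fit <- fitOls(X, y)
    expect_equal(sum(fit@hat), p, tolerance = 1e-10)
    expect_lt(max(abs(crossprod(X, fit@residuals))), 1e-9)
  }
  Xbad <- cbind(a = rep(1, 10), b = rnorm(10), c = rep(2, 10))
  expect_error(fitOls(Xbad, rnorm(10)), "collinear")
})

test_that("sandwich covariances match brute-force and sandwich-package oracles", {
  set.seed(42)
  # small designs, exact agreement to 12 significant digits; designs with a
  # leverage-one point (where HC3 is undefined) are redrawn
  for (rep in 1:5) {
    repeat {
      n <- sample(6:10, 1)
      X <- cbind(1, g = sample(0:2, n, TRUE), z = rnorm(n))
      X <- cbind(X, gz = X[, 2] * X[, 3])
      y <- rnorm(n)
      if (qr(X)$rank == 4L) {
        fit <- fitOls(X, y)
        if (max(fit@hat) < 0.99) break
      }
    }
    for (fl in c("HC0", "HC3")) {
      expect_equal(hcCovariance(fit, fl),
                   bruteSandwich(X, fit@residuals, fl),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    lmfit <- lm(y ~ X - 1)
    expect_equal(unname(hcCovariance(fit, "HC0")),
                 unname(sandwich::vcovHC(lmfit, type = "HC0")),
                 tolerance = 1e-10)
    expect_equal(unname(hcCovariance(fit, "HC3")),
                 unname(sandwich::vcovHC(lmfit, type = "HC3")),
                 tolerance = 1e-10)
    expect_true(all(diag(hcCovariance(fit, "HC3")) >=
                      diag(hcCovariance(fit, "HC0"))))
  }
})

test_that("HC3 refuses leverage-one observations", {
  X <- cbind(1, d = c(1, 0, 0, 0, 0), x = c(0, 1, 2, 3, 4))
  fit <- fitOls(X, rnorm(5))
  expect_error(hcCovariance(fit, "HC3"), "leverage")
})

test_that("sandwich converges to the naive covariance under homoscedasticity", {
  set.seed(43)
  n <- 1e5
  g <- standardizeDosage(sampleGenotypes(n, 0.3), 0.3)
  z <- rnorm(n)
  y <- 0.3 * g + 0.2 * z + rnorm(n)
  fit <- fitOls(cbind(1, g = g, z = z, gz = g * z), y)
  seNaive <- sqrt(diag(fit@naiveCov))
  seHC0 <- sqrt(diag(hcCovariance(fit, "HC0")))
  seHC3 <- sqrt(diag(hcCovariance(fit, "HC3")))
  expect_equal(seHC0 / seNaive, rep(1, 4), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(seHC3 / seHC0, rep(1, 4), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("interaction strategies share contracts and handle edge designs", {
  set.seed(44)
  n <- 401
  g <- sampleGenotypes(n, 0.3)
  z <- rnorm(n)
  y <- rnorm(n)
  # wald = (beta/se)^2 for the covariance-based strategies
  for (s in c("std", "hc0", "hc3")) {
    r <- testInteraction(y, g, z, s)
    expect_equal(r@wald, (r@beta / r@se)^2, tolerance = 1e-12)
    expect_true(r@p > 0 && r@p <= 1)
  }
  # median split: odd n gives floor/ceiling group sizes, median goes to 1
  zb <- as.numeric(z >= median(z))
  expect_equal(as.integer(sort(table(zb))), c(200L, 201L))
  rbin <- testInteraction(y, g, z, "bin")
  expect_s4_class(rbin, "InteractionResult")
  # saturated model drops the dummy of an absent genotype class
  g2 <- c(rep(0, 200), rep(1, 201))
  rsat <- testInteraction(y, g2, z, "sat")
  expect_identical(rsat@droppedColumns, character(0))
  gRare <- sampleGenotypes(n, 0.05)
  gRare[gRare == 2] <- 1  # remove homozygote carriers
  rsat2 <- testInteraction(y, gRare, z, "sat")
  expect_s4_class(rsat2, "InteractionResult")
  # degenerate inputs
  expect_error(testInteraction(y, rep(1, n), z, "std"), "monomorphic")
  expect_error(testInteraction(y, g, rep(0, n), "std"), "constant")
})

test_that("the saturated model absorbs quadratic exposure effects", {
  set.seed(45)
  reps <- 1000
  pSat <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 2000
    g <- sampleGenotypes(n, 0.3)
    z <- rnorm(n)
    y <- 0.3 * z^2 + rnorm(n)  # curvature only, no interaction
    pSat[r] <- testInteraction(y, g, z, "sat")@p
  }
  expect_gt(stats::ks.test(pSat, "punif")$p.value, 0.01)
  expect_true(lambdaGC(pSat) > 0.9 && lambdaGC(pSat) < 1.1)
})

test_that("rank transformation makes the test invariant to monotone maps", {
  set.seed(46)
  n <- 500
  g <- sampleGenotypes(n, 0.3)
  z <- rnorm(n)
  y <- 0.2 * g * z + rnorm(n)
  p1 <- testInteraction(y, g, z, "std", rkt = TRUE)@p
  p2 <- testInteraction(exp(y), g, z, "std", rkt = TRUE)@p
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    testInteraction(y, g, z, "std")@p,
    testInteraction(exp(y), g, z, "std")@p)))
})

test_that("all five strategies are calibrated under the complete null", {
  useSubstream(47, 0)
  reps <- 20000
  P <- matrix(NA_real_, reps, 5,
              dimnames = list(NULL, c("std", "hc0", "hc3", "bin", "sat")))
  for (r in seq_len(reps)) {
    n <- 1000
    g <- sampleGenotypes(n, 0.3)
    z <- rnorm(n)
    y <- rnorm(n)
    st <- interscreen:::.interactionStats3(y, standardizeDosage(g, 0.3), z)
    P[r, 1:3] <- st$p
    P[r, 4] <- testInteraction(y, g, z, "bin")@p
    P[r, 5] <- testInteraction(y, g, z, "sat")@p
  }
  for (s in colnames(P)) {
    lam <- lambdaGC(P[, s])
    expect_true(lam > 0.95 && lam < 1.05,
                label = sprintf("lambda[%s] = %.3f in [0.95, 1.05]", s, lam))
  }
})

test_that("marginal test matches its exact null distribution", {
  x <- 1:10
  m <- marginalTest(2 * x, x)
  expect_equal(m$r2, 1)
  expect_lt(m$p, 1e-12)
  expect_equal(m$beta, 2, tolerance = 1e-12)
  expect_error(marginalTest(rnorm(10), rep(3, 10)), "constant")
  # null r2 at n = 121 follows Beta(1/2, 59.5)
  set.seed(48)
  r2 <- replicate(2000, marginalTest(rnorm(121), rnorm(121))$r2)
  ks <- stats::ks.test(r2, function(q) pbeta(q, 0.5, 59.5))
  expect_gt(ks$p.value, 0.01)
  # and agrees with cor.test
  set.seed(49)
  y <- rnorm(50); x <- rnorm(50)
  expect_equal(marginalTest(y, x)$p, stats::cor.test(y, x)$p.value,
               tolerance = 1e-10)
})
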