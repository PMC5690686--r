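# Bootstrap, likelihood, permutation, heterogeneity, and pooling.

test_that("bootstrap is seed-reproducible and degenerates to width 0", {
  rd <- dyadReads(readFrame(sprintf("r%d", 1:10), rep("FTUU", 10)))
  est1 <- bootstrapRcp(rd, nBoot = 200, seed = 42)
  est2 <- bootstrapRcp(rd, nBoot = 200, seed = 42)
  expect_identical(est1, est2)

  # all reads identical: every resample equals the data
  expect_equal(ciLimits(est1),
               c(low = point(est1), high = point(est1)))
  expect_equal(pointBc(est1), point(est1))

  # widening nBoot never changes the plug-in point
  est3 <- bootstrapRcp(rd, nBoot = 800, seed = 42)
  expect_identical(point(est3), point(est1))
})

test_that("bootstrap BCa endpoints match a naive reimplementation on the same resample stream", {
  nBoot <- 2000
  seed <- 101
  rd <- singleDyadReads(200, 100, 200)
  est <- bootstrapRcp(rd, nBoot = nBoot, level = 0.95, seed = seed)
  expect_equal(point(est), 4)
  expect_lt(est@ciLow, 4)
  expect_gt(est@ciHigh, 4)

  # oracle: reproduce the resample stream, then do percentile-BCa by
  # hand (loop over resamples, manual rcp, manual z0/a/alpha mapping)
  C <- cbind(
    F = as.integer(as.data.frame(rd)$dyads == "F"),
    H = as.integer(as.data.frame(rd)$dyads %in% c("T", "B")),
    U = as.integer(as.data.frame(rd)$dyads == "U")
  )
  n <- nrow(C)
  set.seed(seed)
  idx <- sample.int(n, n * nBoot, replace = TRUE)
  rcpOf <- function(cnt) {
    p <- cnt / sum(cnt)
    2 * sqrt(p[1] * p[3]) / p[2]
  }
  boot <- vapply(seq_len(nBoot), function(b) {
    rows <- idx[((b - 1) * n + 1):(b * n)]
    rcpOf(colSums(C[rows, , drop = FALSE]))
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  thetaHat <- rcpOf(colSums(C))
  jack <- vapply(seq_len(n), function(i) {
    log(rcpOf(colSums(C) - C[i, ]))
  }, numeric(1))
  B <- length(boot)
  pl <- (sum(boot < thetaHat) + 0.5 * sum(boot == thetaHat)) / B
  z0 <- qnorm(min(max(pl, 1 / (B + 1)), B / (B + 1)))
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  adj <- pnorm(z0 + (z0 + qnorm(c(0.025, 0.975))) /
                 (1 - a * (z0 + qnorm(c(0.025, 0.975)))))
  ciOracle <- as.numeric(quantile(boot, adj, type = 7))
  expect_equal(est@ciLow, ciOracle[1], tolerance = 5e-4)
  expect_equal(est@ciHigh, ciOracle[2], tolerance = 5e-4)
})

test_that("degenerate resamples are dropped, with warning and error rules", {
  # tiny all-but-degenerate data: many resamples all-F (m = 1)
  rd <- dyadReads(readFrame(c("r1", "r2", "r3"), c("F", "F", "TU")))
  expect_warning(
    est <- bootstrapRcp(rd, nBoot = 300, seed = 5),
    "dropped"
  )
  expect_gt(est@nDropped, 0)

  rdAllF <- dyadReads(readFrame(c("r1", "r2"), c("F", "FF")))
  expect_error(bootstrapRcp(rdAllF, nBoot = 50, seed = 5), "undefined")
})

test_that("bootstrap null test centers correctly and detects strong preference", {
  rd <- singleDyadReads(200, 100, 200)
  tst <- testRcpVsNull(rd, r0 = 1, tails = "one", nBoot = 2000,
                       seed = 17)
  expect_lt(pValue(tst), 1e-3)
  expect_gt(statistic(tst), 3)

  # centering at the estimate itself gives a two-tailed p near 1
  est <- bootstrapRcp(rd, nBoot = 2000, seed = 17)
  tst0 <- testRcpVsNull(rd, r0 = pointBc(est), tails = "two",
                        nBoot = 2000, seed = 17)
  expect_gt(pValue(tst0), 0.95)
  expect_identical(testRcpVsNull(rd, r0 = 2, nBoot = 500, seed = 3),
                   testRcpVsNull(rd, r0 = 2, nBoot = 500, seed = 3))
})

test_that("null-calibrated bootstrap test keeps its size under the null", {
  set.seed(808)
  seeds <- sample.int(1e6, 40)
  ps <- vapply(seq_along(seeds), function(i) {
    sim <- simulateReads(nReads = 200, dyadsPerRead = 4, m = 0.4,
                         r = 1, seed = seeds[i])
    pValue(testRcpVsNull(sim$reads, r0 = 1, tails = "one",
                         nBoot = 400, seed = seeds[i] + 1))
  }, numeric(1))
  # approximate calibration: reject far less often than half the time
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("likelihood CI covers known configurations", {
  est <- likelihoodCi(dyadCounts(25, 50, 25))
  expect_equal(point(est), 1)
  expect_lt(est@ciLow, 1)
  expect_gt(est@ciHigh, 1)

  est4 <- likelihoodCi(dyadCounts(40, 20, 40))
  expect_equal(point(est4), 4)
  expect_gt(est4@ciLow, 1) # excludes the random expectation

  estB <- likelihoodCi(dyadCounts(0, 10, 10))
  expect_equal(point(estB), 0)
  expect_equal(estB@ciLow, 0)
  expect_lt(estB@ciHigh, Inf)
  expect_true("one_sided_upper" %in% flags(estB))

  estInf <- likelihoodCi(dyadCounts(10, 0, 10))
  expect_identical(point(estInf), Inf)
  expect_identical(estInf@ciHigh, Inf)
  expect_gt(estInf@ciLow, 1)
  expect_true("one_sided_lower" %in% flags(estInf))
})

test_that("likelihood CI matches a dense (m,U)-grid oracle to 2 decimals", {
  est <- likelihoodCi(dyadCounts(40, 20, 40), level = 0.95)

  # oracle: evaluate the multinomial log-likelihood over a dense grid
  # of (m, U) points, keep the chi-square(1) highest-likelihood region,
  # and read off the range of RCP values it contains
  n <- c(40, 20, 40)
  m <- seq(0.35, 0.65, by = 2.5e-4)
  U <- seq(0.20, 0.60, by = 2.5e-4)
  g <- expand.grid(m = m, U = U)
  M <- g$U + 2 * g$m - 1
  H <- 2 * (1 - g$U - g$m)
  ok <- M > 0 & H > 0 & g$U > 0
  g <- g[ok, ]
  M <- M[ok]
  H <- H[ok]
  ll <- n[1] * log(M) + n[2] * log(H) + n[3] * log(g$U)
  rr <- 2 * sqrt(M * g$U) / H
  inside <- 2 * (max(ll) - ll) <= qchisq(0.95, 1)
  expect_equal(est@ciLow, min(rr[inside]), tolerance = 0.005)
  expect_equal(est@ciHigh, max(rr[inside]), tolerance = 0.005)
})

test_that("likelihood CI respects conversion-error correction", {
  # simulate through the error model; the corrected point estimate
  # equals the corrected plug-in
  rts <- conversionRates(0.011, 0.031)
  obs <- applyErrors(targetFreqs(0.4, 5), rts)
  cnt <- dyadCounts(round(4000 * obs@M), round(4000 * obs@H),
                    round(4000 * obs@U))
  est <- likelihoodCi(cnt, rts)
  expect_equal(point(est), 5, tolerance = 0.05)
  expect_lt(est@ciLow, 5)
  expect_gt(est@ciHigh, 5)
})

test_that("one-sample MLCT reproduces the closed-form null evaluation", {
  res <- mlct(dyadCounts(40, 20, 40), r0 = 1)
  # oracle: under H0 (r = 1) the null MLE is binomial with
  # mHat = (2 nFull + nHemi) / (2 n); evaluate 2 * delta ll by hand
  mHat <- (2 * 40 + 20) / (2 * 100)
  p0 <- c(mHat^2, 2 * mHat * (1 - mHat), (1 - mHat)^2)
  statOracle <- 2 * (multinomLL(c(40, 20, 40), c(0.4, 0.2, 0.4)) -
                       multinomLL(c(40, 20, 40), p0))
  expect_equal(statistic(res), statOracle, tolerance = 1e-6)
  expect_equal(statistic(res), 38.55, tolerance = 0.005)
  expect_equal(pValue(res),
               pchisq(statOracle, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res@df, 1)

  # perfect null fit
  res0 <- mlct(dyadCounts(25, 50, 25), r0 = 1)
  expect_equal(statistic(res0), 0, tolerance = 1e-6)
  expect_equal(pValue(res0), 1, tolerance = 1e-4)
})

test_that("two-sample MLCT is zero on identical samples and detects shifts", {
  a <- dyadCounts(40, 20, 40)
  same <- mlct(a, a)
  expect_equal(statistic(same), 0, tolerance = 1e-6)
  expect_equal(pValue(same), 1, tolerance = 1e-4)

  b <- dyadCounts(25, 50, 25)
  diffR <- mlct(a, b)
  expect_gt(statistic(diffR), 10)
  expect_lt(pValue(diffR), 0.01)

  # a shared-r null with different m should NOT reject: same r = 1 at
  # different methylation levels
  c1 <- dyadCounts(9, 42, 49)   # binomial m = 0.3, n = 100
  c2 <- dyadCounts(36, 48, 16)  # binomial m = 0.6, n = 100
  sameR <- mlct(c1, c2)
  expect_lt(statistic(sameR), qchisq(0.95, 1))
  expect_gt(pValue(sameR), 0.05)
})

test_that("MLCT zero-cell boundary falls back to a parametric bootstrap", {
  expect_error(mlct(dyadCounts(0, 10, 10), r0 = 1), "seed")
  res <- mlct(dyadCounts(0, 30, 30), r0 = 1, nBootFallback = 400,
              seed = 9)
  expect_true("parametric_bootstrap" %in% flags(res))
  expect_lt(pValue(res), 0.05) # zero concordant cells at n=60: not r=1
  expect_identical(
    res,
    mlct(dyadCounts(0, 30, 30), r0 = 1, nBootFallback = 400, seed = 9)
  )
})

test_that("permutation test is exact on copies, seeded, and powerful", {
  a <- singleDyadReads(30, 20, 30)
  same <- permutationTest(a, a, nPerm = 99, seed = 1)
  expect_equal(statistic(same), 0)
  expect_equal(pValue(same), 1)

  b <- simulateReads(nReads = 300, dyadsPerRead = 4, m = 0.4, r = 1,
                     seed = 21)$reads
  c1 <- simulateReads(nReads = 300, dyadsPerRead = 4, m = 0.4, r = 8,
                      seed = 22)$reads
  p1 <- permutationTest(b, c1, nPerm = 499, seed = 23)
  expect_lt(pValue(p1), 0.01)
  expect_identical(p1, permutationTest(b, c1, nPerm = 499, seed = 23))
})

test_that("permutation power holds across replicate simulations", {
  set.seed(31)
  hits <- 0L
  nRuns <- 40L
  for (i in seq_len(nRuns)) {
    a <- simulateReads(nReads = 300, dyadsPerRead = 4, m = 0.4, r = 1,
                       seed = 1000 + i)$reads
    b <- simulateReads(nReads = 300, dyadsPerRead = 4, m = 0.4, r = 8,
                       seed = 2000 + i)$reads
    p <- pValue(permutationTest(a, b, nPerm = 299, seed = 3000 + i))
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / nRuns, 0.9)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(37)
  ps <- vapply(1:120, function(i) {
    a <- simulateReads(nReads = 60, dyadsPerRead = 4, m = 0.4, r = 2,
                       seed = 5000 + i)$reads
    b <- simulateReads(nReads = 60, dyadsPerRead = 4, m = 0.4, r = 2,
                       seed = 6000 + i)$reads
    pValue(permutationTest(a, b, nPerm = 99, seed = 7000 + i))
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("heterogeneity test equals the G-test and gates pooling", {
  reps <- list(dyadCounts(40, 20, 40), dyadCounts(25, 50, 25))
  het <- heterogeneityTest(reps)
  # oracle: G-test of independence on the 2 x 3 table
  O <- rbind(c(40, 20, 40), c(25, 50, 25))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  G <- 2 * sum(O * log(O / E))
  expect_equal(statistic(het), G, tolerance = 1e-9)
  expect_equal(het@df, 2)
  expect_equal(pValue(het), pchisq(G, 2, lower.tail = FALSE))

  # identical replicates: statistic 0, p 1
  het0 <- heterogeneityTest(list(dyadCounts(10, 5, 10),
                                 dyadCounts(10, 5, 10),
                                 dyadCounts(10, 5, 10)))
  expect_equal(statistic(het0), 0, tolerance = 1e-12)
  expect_equal(pValue(het0), 1)
  expect_equal(het0@df, 4)

  # proportional replicates pool to the same RCP
  pooled <- poolReplicates(list(dyadCounts(10, 5, 10),
                                dyadCounts(20, 10, 20)))
  expect_equal(c(pooled@nFull, pooled@nHemi, pooled@nUnmeth),
               c(30L, 15L, 30L))
  expect_equal(rcp(pooled), rcp(dyadCounts(10, 5, 10)))

  # heterogeneous replicates refuse without force, pool with force
  expect_error(poolReplicates(reps), "heterogeneous")
  err <- tryCatch(poolReplicates(reps), error = function(e) e)
  expect_s4_class(err$test, "TestResult")
  forced <- poolReplicates(reps, force = TRUE)
  expect_equal(c(forced@nFull, forced@nHemi, forced@nUnmeth),
               c(65L, 70L, 65L))

  # zero-total replicates are excluded with a warning
  expect_warning(
    hetZ <- heterogeneityTest(list(dyadCounts(10, 5, 10),
                                   dyadCounts(0, 0, 0),
                                   dyadCounts(20, 10, 20))),
    "zero total"
  )
  expect_equal(hetZ@df, 2)
})

test_that("likelihood and bootstrap CIs agree for independent dyads", {
  sim <- simulateReads(nReads = 500, dyadsPerRead = 4, m = 0.4, r = 5,
                       seed = 61)
  bEst <- bootstrapRcp(sim$reads, nBoot = 4000, seed = 62)
  lEst <- likelihoodCi(countDyads(sim$reads))
  expect_equal(point(bEst), point(lEst), tolerance = 1e-9)
  expect_lt(abs(bEst@ciLow - lEst@ciLow) / lEst@ciLow, 0.1)
  expect_lt(abs(bEst@ciHigh - lEst@ciHigh) / lEst@ciHigh, 0.1)
})

test_that("within-read correlation widens bootstrap CIs relative to likelihood", {
  sim <- simulateReads(nReads = 400, dyadsPerRead = 10, m = 0.4, r = 5,
                       rho = 0.7, seed = 71)
  bEst <- bootstrapRcp(sim$reads, nBoot = 3000, seed = 72)
  lEst <- likelihoodCi(countDyads(sim$reads))
  widthB <- log(bEst@ciHigh) - log(bEst@ciLow)
  widthL <- log(lEst@ciHigh) - log(lEst@ciLow)
  expect_gt(widthB, 1.3 * widthL)
})
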