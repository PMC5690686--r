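# The RCP statistic and the (m, U) configuration-space geometry.

test_that("rcp matches hand values, limits, and degenerate rules", {
  expect_equal(rcp(dyadFreqs(0.25, 0.5, 0.25)), 1)
  expect_equal(rcp(dyadFreqs(0.4, 0.2, 0.4)), 4)
  expect_identical(rcp(dyadFreqs(0.3, 0, 0.7)), Inf)
  expect_equal(rcp(c(1, 1, 1) / 3), 2)
  expect_equal(rcp(dyadFreqs(0, 0.4, 0.6)), 0)
  expect_error(rcp(dyadFreqs(1, 0, 0)), "completely methylated")
  expect_error(rcp(dyadFreqs(0, 0, 1)), "completely methylated")
  expect_equal(rcp(dyadCounts(40, 20, 40)), 4)
})

test_that("the squared statistic equals 4MU/H^2", {
  set.seed(7)
  for (i in 1:50) {
    v <- as.numeric(stats::rmultinom(1, 1000, c(0.3, 0.4, 0.3))) / 1000
    if (any(v == 0)) next
    f <- dyadFreqs(v)
    expect_equal(rcp(f)^2, 4 * v[1] * v[3] / v[2]^2, tolerance = 1e-12)
  }
})

test_that("summary and frequency maps are mutual inverses", {
  s <- summaryFromFreqs(dyadFreqs(0.4, 0.2, 0.4))
  expect_equal(s, c(m = 0.5, U = 0.4))
  expect_equal(summaryFromFreqs(dyadFreqs(0, 0, 1)), c(m = 0, U = 1))
  expect_equal(summaryFromFreqs(dyadFreqs(0.25, 0.5, 0.25)),
               c(m = 0.5, U = 0.25))

  f <- freqsFromSummary(0.5, 0.4)
  expect_equal(c(f@M, f@H, f@U), c(0.4, 0.2, 0.4))
  f2 <- freqsFromSummary(0.3, 0.49)
  expect_equal(c(f2@M, f2@H, f2@U), c(0.09, 0.42, 0.49))
  expect_error(freqsFromSummary(0.2, 0.9), "conservative boundary")
  expect_error(freqsFromSummary(0.4, 0.1), "dispersive boundary")

  set.seed(11)
  for (i in 1:50) {
    v <- as.numeric(stats::rmultinom(1, 500, c(1, 1, 1) / 3)) / 500
    f <- dyadFreqs(v)
    s <- summaryFromFreqs(f)
    back <- freqsFromSummary(s[["m"]], s[["U"]])
    expect_equal(c(back@M, back@H, back@U), c(f@M, f@H, f@U),
                 tolerance = 1e-12)
  }
})

test_that("rcp is invariant under the (M,H,U) <-> (m,U) reparameterization", {
  set.seed(3)
  for (i in 1:30) {
    v <- as.numeric(stats::rmultinom(1, 400, c(0.35, 0.3, 0.35))) / 400
    if (any(v == 0)) next
    f <- dyadFreqs(v)
    s <- summaryFromFreqs(f)
    expect_equal(rcp(f), rcp(freqsFromSummary(s[["m"]], s[["U"]])),
                 tolerance = 1e-12)
  }
})

test_that("rcp is symmetric under swapping M and U", {
  set.seed(5)
  for (i in 1:30) {
    v <- as.numeric(stats::rmultinom(1, 300, c(0.5, 0.2, 0.3))) / 300
    if (v[2] == 0) next
    expect_equal(rcp(dyadFreqs(v)), rcp(dyadFreqs(v[c(3, 2, 1)])),
                 tolerance = 1e-12)
  }
})

test_that("region boundaries follow the three reference curves", {
  expect_equal(regionBoundaries(0.5),
               c(dispersive = 0, random = 0.25, conservative = 0.5))
  expect_equal(regionBoundaries(0.75),
               c(dispersive = 0, random = 0.0625, conservative = 0.25))
  expect_equal(regionBoundaries(0),
               c(dispersive = 1, random = 1, conservative = 1))
  grid <- regionBoundaries(seq(0.01, 0.99, by = 0.01))
  expect_true(all(grid$dispersive <= grid$random + 1e-12))
  expect_true(all(grid$random <= grid$conservative + 1e-12))
})

test_that("binomial frequencies have RCP 1 for all m", {
  for (m in seq(0.05, 0.95, by = 0.05)) {
    f <- dyadFreqs(m^2, 2 * m * (1 - m), (1 - m)^2)
    expect_equal(rcp(f), 1, tolerance = 1e-12)
  }
})

test_that("uFromMRcp solves the contour equation and round-trips", {
  expect_equal(uFromMRcp(0.3, 1), 0.49)
  expect_equal(uFromMRcp(0.5, 2), 1 / 3, tolerance = 1e-9)
  expect_equal(uFromMRcp(0.5, 1e9), 0.5, tolerance = 1e-6)
  expect_equal(uFromMRcp(0.5, Inf), 0.5)

  set.seed(13)
  for (i in 1:100) {
    m <- runif(1, 0.05, 0.95)
    r <- exp(runif(1, log(0.05), log(50)))
    U <- uFromMRcp(m, r)
    lo <- max(1 - 2 * m, 0)
    expect_gte(U, lo - 1e-12)
    expect_lte(U, 1 - m + 1e-12)
    expect_equal(rcp(freqsFromSummary(m, U)), r, tolerance = 1e-9)
  }
})

test_that("contours map the grid, are feasible, and increase with r", {
  c1 <- rcpContour(1, c(0.2, 0.5, 0.8))
  expect_equal(c1$U, c(0.64, 0.25, 0.04))
  c2 <- rcpContour(2, c(0.2, 0.5, 0.8))
  expect_equal(c2$U[2], 1 / 3, tolerance = 1e-9)
  expect_true(all(c2$U > c1$U))
  mGrid <- seq(0.05, 0.95, by = 0.05)
  for (r in c(0.5, 1, 2, 5, 20)) {
    cc <- rcpContour(r, mGrid)
    expect_true(all(cc$U >= pmax(1 - 2 * mGrid, 0) - 1e-12))
    expect_true(all(cc$U <= 1 - mGrid + 1e-12))
  }
})

test_that("mixtures average frequencies and bound pooled RCP", {
  f <- dyadFreqs(0.2, 0.3, 0.5)
  expect_equal(mixtureFreqs(list(f), 1), f)

  high <- dyadFreqs(0.8, 0, 0.2)
  low <- dyadFreqs(0.64, 0.32, 0.04)
  mix <- mixtureFreqs(list(high, low), c(0.5, 0.5))
  expect_equal(c(mix@M, mix@H, mix@U), c(0.72, 0.16, 0.12))
  expect_equal(rcp(mix), 2 * sqrt(0.72 * 0.12) / 0.16)
  expect_equal(rcp(mix), 3.674, tolerance = 1e-3)
  # pooled RCP strictly between the components' (rcp(low) = 1, Inf)
  expect_gt(rcp(mix), rcp(low))
  expect_lt(rcp(mix), Inf)

  expect_error(mixtureFreqs(list(high, low), c(0.6, 0.5)), "sum to 1")
})

test_that("minimum subpopulation fraction inverts the pooled RCP", {
  high <- dyadFreqs(0.8, 0, 0.2)
  low <- dyadFreqs(0.64, 0.32, 0.04)
  target <- rcp(mixtureFreqs(list(high, low), c(0.5, 0.5)))
  w <- minFractionForRcp(target, high, low)
  expect_equal(w, 0.5, tolerance = 1e-5)
  expect_equal(minFractionForRcp(rcp(low), high, low), 0)
  expect_equal(minFractionForRcp(rcp(high), high, low), 1)
  expect_error(minFractionForRcp(2, low, high), "exceed")
})
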