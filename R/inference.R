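# Confidence intervals and hypothesis tests for RCP.
#
# Two inference routes mirror the two sampling models for hairpin data:
#  * read-level resampling (bootstrap, permutation), which honors the
#    correlation of dyads within a sequenced molecule; and
#  * multinomial likelihood on dyad counts (profile-likelihood CIs and
#    maximum-likelihood comparison tests, MLCTs), which assumes
#    independently sampled dyads.
# Conversion-error correction is applied inside every resample and
# inside the likelihood via the forward error model, with the rates
# held fixed.

# Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Corrected plug-in RCP for each row of an n x 3 count (or frequency)
# matrix; NA where undefined.
.correctedRcpFromCounts <- function(countMat, f, c0) {
  tot <- rowSums(countMat)
  P <- countMat / tot
  X <- .correctFreqsMat(P, f, c0)
  out <- .rcpVec(X[, 1L], X[, 2L], X[, 3L])
  out[tot == 0] <- NA_real_
  unname(out)
}

# Read-level bootstrap of the corrected RCP. Returns the plug-in
# estimate, the bootstrap draws (NA already removed), the number of
# dropped degenerate resamples, and read-level jackknife values.
.bootRcpSamples <- function(reads, rates, nBoot, seed) {
  C <- .perReadCounts(reads)
  n <- nrow(C)
  if (n < 2L) stop("bootstrap requires at least 2 reads")
  f <- rates@failed
  c0 <- rates@inappropriate
  total <- colSums(C)
  thetaHat <- .correctedRcpFromCounts(rbind(total), f, c0)
  if (is.na(thetaHat)) {
    stop("RCP is undefined for these reads (m = 0 or m = 1)")
  }

  boot <- .withSeed(seed, {
    idx <- sample.int(n, n * nBoot, replace = TRUE)
    G <- rep(seq_len(nBoot), each = n)
    bc <- rowsum(C[idx, , drop = FALSE], G, reorder = FALSE)
    .correctedRcpFromCounts(bc, f, c0)
  })
  nDropped <- sum(is.na(boot))
  if (nDropped == nBoot) {
    stop("all bootstrap resamples had undefined RCP")
  }
  if (nDropped > 0.1 * nBoot) {
    warning(sprintf(
      "%d of %d bootstrap resamples had undefined RCP and were dropped",
      nDropped, nBoot
    ))
  }
  jackCounts <- matrix(rep(total, each = n), n, 3L) - C
  jack <- .correctedRcpFromCounts(jackCounts, f, c0)
  list(
    thetaHat = as.numeric(thetaHat), boot = boot[!is.na(boot)],
    nDropped = nDropped, jack = jack
  )
}

# BCa ingredients computed on the log-RCP scale (the natural scale for
# a ratio statistic whose bootstrap distribution may include 0 or Inf;
# the percentile mapping itself is monotone-transform invariant).
.bcaAdjust <- function(thetaHat, boot, jack, probs) {
  B <- length(boot)
  pl <- (sum(boot < thetaHat) + 0.5 * sum(boot == thetaHat)) / B
  pl <- min(max(pl, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(pl)
  lj <- log(jack)
  lj <- lj[is.finite(lj)]
  a <- 0
  if (length(lj) >= 3L) {
    d <- mean(lj) - lj
    denom <- sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / (6 * denom)
  }
  zA <- stats::qnorm(probs)
  stats::pnorm(z0 + (z0 + zA) / (1 - a * (z0 + zA)))
}

#' Bootstrap (BCa) confidence interval for RCP
#'
#' Resamples whole reads (not dyads) with replacement, so that the
#' interval does not assume independent sampling of dyads: dyads on one
#' hairpin molecule stay together in every resample. Each resample is
#' tallied, corrected for conversion error, and its RCP computed; the
#' interval applies the bias-corrected and accelerated (BCa)
#' adjustment, with the bias constant taken from the bootstrap
#' distribution and the acceleration from a leave-one-read-out
#' jackknife on log RCP. The bias-corrected point estimate is the
#' BCa-adjusted bootstrap median.
#'
#' Resamples with undefined RCP (completely methylated or unmethylated)
#' are dropped and counted; more than 10% dropped raises a warning, all
#' dropped an error.
#'
#' @param reads a [DyadReads-class] object with at least 2 reads.
#' @param rates [ConversionRates-class]; default no error.
#' @param nBoot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer RNG seed (required; results are bit-reproducible
#'   given the seed).
#' @return An [RcpEstimate-class] with `method = "bootstrap_bca"`.
#' @examples
#' sim <- simulateReads(nReads = 80, dyadsPerRead = 4, m = 0.4, r = 5,
#'                      seed = 1)
#' bootstrapRcp(sim$reads, nBoot = 500, seed = 7)
#' @seealso [likelihoodCi()] for the independent-dyad alternative.
#' @export
bootstrapRcp <- function(reads, rates = conversionRates(), nBoot = 10000,
                         level = 0.95, seed) {
  stopifnot(is(reads, "DyadReads"), is(rates, "ConversionRates"),
            nBoot >= 2, level > 0, level < 1)
  bs <- .bootRcpSamples(reads, rates, nBoot, seed)
  alpha <- (1 - level) / 2
  adj <- .bcaAdjust(bs$thetaHat, bs$boot, bs$jack,
                    c(alpha, 0.5, 1 - alpha))
  qs <- as.numeric(stats::quantile(bs$boot, adj, names = FALSE,
                                   type = 7))
  new("RcpEstimate",
    point = bs$thetaHat, pointBc = qs[[2L]],
    ciLow = qs[[1L]], ciHigh = qs[[3L]],
    level = level, method = "bootstrap_bca",
    nBoot = as.integer(nBoot), seed = as.integer(seed),
    nDropped = as.integer(bs$nDropped), flags = character()
  )
}

#' Bootstrap test of RCP against a null value
#'
#' Tests H0: RCP = `r0` (default 1, the random-placement expectation)
#' using the normal approximation on log RCP calibrated by the
#' bootstrap spread: the statistic is
#' `log(pointBc / r0) / se(log RCP)` with the standard error taken from
#' the read-level bootstrap distribution. This parameterization makes
#' p-values far below the resampling resolution (e.g. p < 1e-16)
#' representable. The one-tailed test has alternative RCP > `r0`.
#'
#' @inheritParams bootstrapRcp
#' @param r0 null RCP value.
#' @param tails `"one"` (alternative RCP > r0) or `"two"`.
#' @return A [TestResult-class] with `method = "bootstrap"`.
#' @examples
#' sim <- simulateReads(nReads = 100, dyadsPerRead = 4, m = 0.4, r = 5,
#'                      seed = 1)
#' testRcpVsNull(sim$reads, r0 = 1, nBoot = 500, seed = 7)
#' @export
testRcpVsNull <- function(reads, rates = conversionRates(), r0 = 1,
                          tails = c("one", "two"), nBoot = 10000, seed) {
  tails <- match.arg(tails)
  stopifnot(r0 > 0, is.finite(r0))
  bs <- .bootRcpSamples(reads, rates, nBoot, seed)
  adj <- .bcaAdjust(bs$thetaHat, bs$boot, bs$jack, 0.5)
  pointBc <- as.numeric(stats::quantile(bs$boot, adj, names = FALSE,
                                        type = 7))
  lb <- log(bs$boot)
  lb <- lb[is.finite(lb)]
  if (length(lb) < 2L) stop("too few finite bootstrap log-RCP values")
  seLog <- stats::sd(lb)
  stat <- (log(pointBc) - log(r0)) / seLog
  p <- if (tails == "one") {
    stats::pnorm(stat, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  }
  new("TestResult",
    statistic = stat, pValue = min(p, 1), tails = tails,
    method = "bootstrap", df = NA_real_, flags = character()
  )
}

# --- multinomial likelihood machinery (independent-dyad model) --------

# Log-likelihood of observed counts n (length 3) under true-scale
# parameters (m, r), pushed through the conversion-error model.
.llMR <- function(m, r, n, E) {
  U <- .uFromMRcpVec(m, r)
  pTrue <- cbind(U + 2 * m - 1, 2 * (1 - U - m), U)
  pTrue[pTrue < 0] <- 0
  pObs <- pTrue %*% E
  ll <- rep(-Inf, length(m))
  ok <- apply(pObs, 1L, function(p) all(p[n > 0] > 0))
  if (any(ok)) {
    lp <- log(pObs[ok, , drop = FALSE])
    lp[, n == 0] <- 0 # 0 * log(0) convention
    lp[!is.finite(lp)] <- 0
    ll[ok] <- lp %*% ifelse(n > 0, n, 0)
  }
  ll
}

# Profile log-likelihood over m for fixed r.
.profileLL <- function(r, n, E) {
  stats::optimize(function(m) .llMR(m, r, n, E),
                  interval = c(1e-7, 1 - 1e-7),
                  maximum = TRUE, tol = 1e-10)$objective
}

# Saturated-model fit of (m, r) to counts n under the error model.
# Returns list(rHat, llMax, boundary): boundary is "zero" / "inf" / ""
# for RCP pinned at 0, Inf, or interior.
.mleMR <- function(n, E, f, c0) {
  N <- sum(n)
  props <- n / N
  x <- solve(t(E), props) # algebraic inverse, may leave simplex
  attainable <- all(x >= -SIMPLEX_TOL)
  x[x < 0] <- 0
  x <- x / sum(x)
  m <- x[[1L]] + x[[2L]] / 2
  if (m <= 0 || m >= 1) {
    stop("RCP is undefined after correction (m = 0 or m = 1)")
  }
  rHat <- .rcpVec(x[[1L]], x[[2L]], x[[3L]])
  if (attainable) {
    lp <- log(props[n > 0])
    llMax <- sum(n[n > 0] * lp)
  } else {
    # corrected frequencies were clipped: refine numerically
    start <- c(stats::qlogis(min(max(m, 1e-6), 1 - 1e-6)),
               log(min(max(rHat, 1e-6), 1e6)))
    fit <- stats::optim(start, function(p) {
      -.llMR(stats::plogis(p[[1L]]), exp(p[[2L]]), n, E)
    }, method = "Nelder-Mead", control = list(maxit = 2000))
    llMax <- -fit$value
    rHat <- exp(fit$par[[2L]])
  }
  boundary <- if (rHat == 0) "zero" else if (is.infinite(rHat)) "inf" else ""
  list(rHat = as.numeric(rHat), llMax = llMax, boundary = boundary)
}

#' Profile-likelihood confidence interval for RCP
#'
#' Treats the dyad counts as a multinomial sample (dyads sampled
#' independently), reparameterizes the dyad-state probabilities to
#' methylation frequency m and RCP r, pushes them through the
#' conversion-error model, and profiles the log-likelihood over r. The
#' interval is the set of r whose profile deviance
#' `2 * (llMax - llProfile(r))` does not exceed the chi-square(1)
#' quantile at `level`. The point estimate is the maximum-likelihood
#' estimate, i.e. the error-corrected plug-in frequencies.
#'
#' A zero count cell pins the estimate to a boundary (0 when a
#' concordant class is absent, Inf when hemimethylation is absent) and
#' yields a one-sided interval, flagged in the result.
#'
#' @param counts a [DyadCounts-class] with total at least 3.
#' @param rates [ConversionRates-class].
#' @param level confidence level.
#' @return An [RcpEstimate-class] with `method = "likelihood"`.
#' @examples
#' likelihoodCi(dyadCounts(40, 20, 40))
#' @export
likelihoodCi <- function(counts, rates = conversionRates(),
                         level = 0.95) {
  stopifnot(is(counts, "DyadCounts"), is(rates, "ConversionRates"),
            level > 0, level < 1)
  n <- c(counts@nFull, counts@nHemi, counts@nUnmeth)
  if (sum(n) < 3L) stop("need a total of at least 3 dyads")
  E <- .errorMatrix(rates@failed, rates@inappropriate)
  fit <- .mleMR(n, E, rates@failed, rates@inappropriate)
  cutoff <- stats::qchisq(level, df = 1L)
  dev <- function(r) 2 * (fit$llMax - .profileLL(r, n, E))
  flagsOut <- character()

  rAnchor <- fit$rHat
  if (fit$boundary == "zero") rAnchor <- 1e-4
  if (fit$boundary == "inf") rAnchor <- 1e4

  # lower endpoint
  if (fit$boundary == "zero") {
    lowEnd <- 0
    flagsOut <- c(flagsOut, "one_sided_upper")
  } else {
    lowEnd <- 0
    rl <- rAnchor
    found <- FALSE
    for (k in seq_len(60L)) {
      rl <- rl / 2
      if (dev(rl) > cutoff) {
        found <- TRUE
        break
      }
    }
    if (found) {
      lowEnd <- stats::uniroot(function(lr) dev(exp(lr)) - cutoff,
                               lower = log(rl), upper = log(rAnchor),
                               tol = 1e-9)$root
      lowEnd <- exp(lowEnd)
    } else {
      flagsOut <- c(flagsOut, "lower_at_boundary")
    }
  }

  # upper endpoint
  if (fit$boundary == "inf") {
    highEnd <- Inf
    flagsOut <- c(flagsOut, "one_sided_lower")
  } else {
    highEnd <- Inf
    rh <- rAnchor
    found <- FALSE
    for (k in seq_len(60L)) {
      rh <- rh * 2
      if (dev(rh) > cutoff) {
        found <- TRUE
        break
      }
    }
    if (found) {
      highEnd <- stats::uniroot(function(lr) dev(exp(lr)) - cutoff,
                                lower = log(rAnchor), upper = log(rh),
                                tol = 1e-9)$root
      highEnd <- exp(highEnd)
    } else {
      flagsOut <- c(flagsOut, "upper_at_boundary")
    }
  }

  new("RcpEstimate",
    point = fit$rHat, pointBc = fit$rHat,
    ciLow = lowEnd, ciHigh = highEnd,
    level = level, method = "likelihood",
    nBoot = 0L, seed = NA_integer_, nDropped = 0L, flags = flagsOut
  )
}

#' Maximum-likelihood comparison test (MLCT)
#'
#' Likelihood-ratio test under the independent-dyad multinomial model.
#' One-sample form (`countsB = NULL`): H0 fixes RCP at `r0` with m
#' free, against (m, r) both free; df = 1. Two-sample form: H0 shares
#' one RCP across the two samples with each sample's m free, against a
#' free RCP per sample; df = 1. P-values come from the chi-square
#' distribution; when a zero count cell puts a maximum-likelihood
#' estimate on the boundary, the chi-square approximation is replaced
#' by a parametric bootstrap under the fitted null (flagged
#' `"parametric_bootstrap"`).
#'
#' @param countsA,countsB [DyadCounts-class] objects; `countsB = NULL`
#'   selects the one-sample test against `r0`.
#' @param r0 null RCP for the one-sample form.
#' @param ratesA,ratesB [ConversionRates-class] per sample.
#' @param nBootFallback parametric-bootstrap replicates for boundary
#'   cases.
#' @param seed RNG seed, required only when the parametric-bootstrap
#'   fallback triggers.
#' @return A [TestResult-class] with `method = "mlct"`.
#' @examples
#' mlct(dyadCounts(40, 20, 40), r0 = 1)
#' @export
mlct <- function(countsA, countsB = NULL, r0 = 1,
                 ratesA = conversionRates(), ratesB = ratesA,
                 nBootFallback = 10000, seed = NULL) {
  stopifnot(is(countsA, "DyadCounts"))
  nA <- c(countsA@nFull, countsA@nHemi, countsA@nUnmeth)
  EA <- .errorMatrix(ratesA@failed, ratesA@inappropriate)
  boundary <- any(nA == 0L)

  if (is.null(countsB)) {
    stopifnot(r0 > 0, is.finite(r0))
    statFun <- function(n) {
      fit <- .mleMR(n, EA, ratesA@failed, ratesA@inappropriate)
      max(0, 2 * (fit$llMax - .profileLL(r0, n, EA)))
    }
    stat <- statFun(nA)
    nullProbs <- list(.nullProbsOneSample(nA, r0, EA))
    sizes <- sum(nA)
    simStat <- function(cnts) statFun(cnts[[1L]])
  } else {
    stopifnot(is(countsB, "DyadCounts"))
    nB <- c(countsB@nFull, countsB@nHemi, countsB@nUnmeth)
    EB <- .errorMatrix(ratesB@failed, ratesB@inappropriate)
    boundary <- boundary || any(nB == 0L)
    statFun <- function(na, nb) {
      fa <- .mleMR(na, EA, ratesA@failed, ratesA@inappropriate)
      fb <- .mleMR(nb, EB, ratesB@failed, ratesB@inappropriate)
      shared <- .sharedRFit(na, nb, EA, EB, fa$rHat, fb$rHat)
      max(0, 2 * (fa$llMax + fb$llMax - shared$ll))
    }
    stat <- statFun(nA, nB)
    fa <- .mleMR(nA, EA, ratesA@failed, ratesA@inappropriate)
    fb <- .mleMR(nB, EB, ratesB@failed, ratesB@inappropriate)
    shared <- .sharedRFit(nA, nB, EA, EB, fa$rHat, fb$rHat)
    nullProbs <- list(
      .probsAtR(shared$r, nA, EA),
      .probsAtR(shared$r, nB, EB)
    )
    sizes <- c(sum(nA), sum(nB))
    simStat <- function(cnts) statFun(cnts[[1L]], cnts[[2L]])
  }

  if (!boundary) {
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    flagsOut <- character()
  } else {
    if (is.null(seed)) {
      stop("a zero count cell requires the parametric-bootstrap ",
           "fallback; supply a seed")
    }
    p <- .withSeed(seed, {
      hits <- 0L
      for (b in seq_len(nBootFallback)) {
        cnts <- lapply(seq_along(nullProbs), function(i) {
          as.integer(stats::rmultinom(1L, sizes[[i]], nullProbs[[i]]))
        })
        sb <- tryCatch(simStat(cnts), error = function(e) NA_real_)
        if (!is.na(sb) && sb >= stat) hits <- hits + 1L
      }
      (1 + hits) / (1 + nBootFallback)
    })
    flagsOut <- "parametric_bootstrap"
  }
  new("TestResult",
    statistic = stat, pValue = p, tails = "one", method = "mlct",
    df = 1, flags = flagsOut
  )
}

# Observed-scale probabilities under H0 for the one-sample MLCT:
# r fixed at r0, m at its profile maximum.
.nullProbsOneSample <- function(n, r0, E) {
  mHat <- stats::optimize(function(m) .llMR(m, r0, n, E),
                          interval = c(1e-7, 1 - 1e-7),
                          maximum = TRUE, tol = 1e-10)$maximum
  .probsAtMR(mHat, r0, E)
}

.probsAtMR <- function(m, r, E) {
  U <- .uFromMRcpVec(m, r)
  pTrue <- pmax(c(U + 2 * m - 1, 2 * (1 - U - m), U), 0)
  as.numeric(pTrue %*% E)
}

# Observed-scale probabilities for one sample at the shared-r null fit
# (sample-specific profile m).
.probsAtR <- function(r, n, E) {
  mHat <- stats::optimize(function(m) .llMR(m, r, n, E),
                          interval = c(1e-7, 1 - 1e-7),
                          maximum = TRUE, tol = 1e-10)$maximum
  .probsAtMR(mHat, r, E)
}

# Maximize profileA(r) + profileB(r) over a shared r (H0 of the
# two-sample MLCT; each sample keeps its own m).
.sharedRFit <- function(na, nb, EA, EB, rHatA, rHatB) {
  anchors <- c(rHatA, rHatB)
  anchors <- anchors[is.finite(anchors) & anchors > 0]
  if (length(anchors) == 0L) anchors <- 1
  lo <- log(min(anchors)) - 8
  hi <- log(max(anchors)) + 8
  obj <- function(lr) {
    .profileLL(exp(lr), na, EA) + .profileLL(exp(lr), nb, EB)
  }
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-9)
  list(r = exp(opt$maximum), ll = opt$objective)
}

#' Two-sample permutation test on RCP
#'
#' Compares the RCP of two read sets with the statistic
#' `|log rcp_A - log rcp_B|` on conversion-error-corrected frequencies.
#' The null distribution reshuffles whole reads between the two groups,
#' preserving group sizes, so that within-molecule dyad correlation is
#' kept intact; the p-value is `(1 + #(null >= observed)) /
#' (1 + n_kept)`. Permutations with undefined RCP in either group are
#' dropped and counted.
#'
#' @param readsA,readsB [DyadReads-class] objects with >= 2 reads each.
#' @param rates [ConversionRates-class] shared by both groups.
#' @param nPerm number of permutations.
#' @param seed integer RNG seed (required).
#' @return A [TestResult-class] with `method = "permutation"`,
#'   two-tailed.
#' @examples
#' a <- simulateReads(nReads = 50, dyadsPerRead = 4, m = 0.4, r = 1,
#'                    seed = 1)$reads
#' b <- simulateReads(nReads = 50, dyadsPerRead = 4, m = 0.4, r = 8,
#'                    seed = 2)$reads
#' permutationTest(a, b, nPerm = 199, seed = 7)
#' @export
permutationTest <- function(readsA, readsB, rates = conversionRates(),
                            nPerm = 10000, seed) {
  stopifnot(is(readsA, "DyadReads"), is(readsB, "DyadReads"),
            length(readsA) >= 2L, length(readsB) >= 2L)
  CA <- .perReadCounts(readsA)
  CB <- .perReadCounts(readsB)
  f <- rates@failed
  c0 <- rates@inappropriate
  rA <- .correctedRcpFromCounts(rbind(colSums(CA)), f, c0)
  rB <- .correctedRcpFromCounts(rbind(colSums(CB)), f, c0)
  if (is.na(rA) || is.na(rB)) {
    stop("RCP is undefined for one of the groups")
  }
  obs <- abs(log(rA) - log(rB))
  C <- rbind(CA, CB)
  n <- nrow(C)
  nA <- nrow(CA)
  tot <- colSums(C)
  nullStats <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      ia <- sample.int(n, nA)
      ca <- colSums(C[ia, , drop = FALSE])
      ra <- .correctedRcpFromCounts(rbind(ca), f, c0)
      rb <- .correctedRcpFromCounts(rbind(tot - ca), f, c0)
      abs(log(ra) - log(rb))
    }, numeric(1L))
  })
  kept <- nullStats[!is.na(nullStats)]
  nDropped <- nPerm - length(kept)
  if (length(kept) == 0L) stop("all permutations had undefined RCP")
  # NaN from log(Inf)-log(Inf) etc. counts as undefined and is dropped
  p <- (1 + sum(kept >= obs)) / (1 + length(kept))
  new("TestResult",
    statistic = obs, pValue = min(p, 1), tails = "two",
    method = "permutation", df = NA_real_,
    flags = if (nDropped > 0L) sprintf("dropped_%d", nDropped)
            else character()
  )
}

#' Heterogeneity test across replicate samples
#'
#' Multinomial likelihood-ratio test of H0: all replicates share one
#' dyad-state distribution (M, H, U) against each replicate free — a
#' G-test of independence on the k x 3 count table, with
#' `df = 2(k - 1)`. Equality of full dyad distributions is stricter
#' than equality of RCP, making this a conservative gate for pooling.
#' Replicates with zero total are excluded with a warning.
#'
#' @param replicates list of [DyadCounts-class] objects, length >= 2.
#' @return A [TestResult-class] with `method = "heterogeneity"`.
#' @examples
#' heterogeneityTest(list(dyadCounts(40, 20, 40), dyadCounts(25, 50, 25)))
#' @export
heterogeneityTest <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  N <- t(vapply(replicates, function(x) {
    stopifnot(is(x, "DyadCounts"))
    c(x@nFull, x@nHemi, x@nUnmeth)
  }, numeric(3L)))
  tot <- rowSums(N)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d replicate(s) with zero total",
                    sum(tot == 0)))
    N <- N[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  k <- nrow(N)
  if (k < 2L) stop("need at least 2 non-empty replicates")
  pPool <- colSums(N) / sum(N)
  term <- function(n, p) {
    pos <- n > 0
    sum(n[pos] * log(n[pos] / p[pos]))
  }
  stat <- 2 * sum(vapply(seq_len(k), function(i) {
    term(N[i, ], tot[[i]] * pPool)
  }, numeric(1L)))
  df <- 2 * (k - 1)
  new("TestResult",
    statistic = stat,
    pValue = stats::pchisq(stat, df = df, lower.tail = FALSE),
    tails = "one", method = "heterogeneity", df = df,
    flags = character()
  )
}

#' Pool dyad counts across replicates
#'
#' Element-wise sum of replicate counts. Pooling is refused (with the
#' heterogeneity test attached to the error condition) when
#' [heterogeneityTest()] rejects homogeneity at p < 0.05, unless
#' `force = TRUE`. The pooled RCP always lies between the smallest and
#' largest replicate RCP; this is asserted on the result.
#'
#' @param replicates list of [DyadCounts-class] objects, length >= 2.
#' @param force pool even when the replicates are heterogeneous.
#' @return A [DyadCounts-class] with summed counts.
#' @examples
#' poolReplicates(list(dyadCounts(10, 5, 10), dyadCounts(20, 10, 20)))
#' @export
poolReplicates <- function(replicates, force = FALSE) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  het <- heterogeneityTest(replicates)
  if (!force && pValue(het) < 0.05) {
    cond <- structure(
      class = c("rcpmeth_heterogeneity_error", "error", "condition"),
      list(
        message = sprintf(
          "replicates are heterogeneous (G = %.4g, df = %g, p = %.4g); use force = TRUE to pool anyway",
          statistic(het), het@df, pValue(het)
        ),
        call = sys.call(-1L), test = het
      )
    )
    stop(cond)
  }
  N <- t(vapply(replicates, function(x) {
    c(x@nFull, x@nHemi, x@nUnmeth, x@nReads)
  }, numeric(4L)))
  s <- colSums(N)
  pooled <- dyadCounts(s[[1L]], s[[2L]], s[[3L]], s[[4L]],
                       sampleId = "pooled",
                       locus = replicates[[1L]]@locus)
  reps <- vapply(replicates, function(x) {
    tryCatch(rcp(x), error = function(e) NA_real_)
  }, numeric(1L))
  reps <- reps[!is.na(reps)]
  if (length(reps) > 0L) {
    rPool <- tryCatch(rcp(pooled), error = function(e) NA_real_)
    if (!is.na(rPool)) {
      stopifnot(rPool >= min(reps) - 1e-9, rPool <= max(reps) + 1e-9)
    }
  }
  pooled
}
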