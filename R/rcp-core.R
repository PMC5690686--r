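# The RCP statistic and the (m, U) configuration-space geometry.
#
# All public entry points operate on DyadFreqs / DyadCounts; the
# vectorized internals (.rcpVec, .uFromMRcpVec) are shared with the
# resampling and likelihood machinery, where class construction per
# replicate would dominate the run time.

# Vectorized RCP over parallel (M, H, U) vectors. Returns NA where RCP
# is undefined (m = 0 or m = 1), Inf for H = 0 with both concordant
# classes present, 0 where a concordant class is absent but H > 0.
.rcpVec <- function(M, H, U) {
  r <- 2 * sqrt(M * U) / H
  zeroH <- H == 0
  r[zeroH & M > 0 & U > 0] <- Inf
  r[zeroH & (M == 0 | U == 0)] <- NA_real_ # m is 0 or 1: undefined
  r
}

#' @rdname rcp
#' @export
setMethod("rcp", "DyadFreqs", function(x, ...) {
  M <- x@M
  H <- x@H
  U <- x@U
  if (H == 0 && (M == 0 || U == 0)) {
    stop("RCP cannot be inferred for completely methylated or ",
         "unmethylated regions (m = 0 or m = 1)")
  }
  if (H == 0) return(Inf)
  2 * sqrt(M * U) / H
})

#' @rdname rcp
#' @export
setMethod("rcp", "DyadCounts", function(x, ...) rcp(asFreqs(x)))

#' @rdname rcp
#' @export
setMethod("rcp", "numeric", function(x, ...) {
  if (length(x) != 3L) stop("numeric input must be c(M, H, U)")
  s <- sum(x)
  if (s <= 0) stop("frequencies or counts must have a positive sum")
  rcp(dyadFreqs(x / s))
})

#' Methylation summary (m, U) from dyad frequencies
#'
#' Maps the dyad-state frequencies (M, H, U) to the equivalent pair
#' (m, U): the overall methylation frequency of CpG cytosines
#' \eqn{m = M + H/2} and the unmethylated-dyad frequency U. Because the
#' three frequencies sum to 1, (m, U) carries the full information of
#' (M, H, U); it is the coordinate system of the configuration-space
#' plots.
#'
#' @param freqs a [DyadFreqs-class] object.
#' @return Named numeric vector `c(m = , U = )`.
#' @examples
#' summaryFromFreqs(dyadFreqs(0.4, 0.2, 0.4))
#' @seealso [freqsFromSummary()] for the inverse map.
#' @export
summaryFromFreqs <- function(freqs) {
  stopifnot(is(freqs, "DyadFreqs"))
  c(m = freqs@M + freqs@H / 2, U = freqs@U)
}

#' Dyad frequencies from a methylation summary (m, U)
#'
#' Inverts [summaryFromFreqs()]: `M = U + 2m - 1`, `H = 2(1 - U - m)`.
#' The pair must be feasible, `max(1 - 2m, 0) <= U <= 1 - m`; values
#' within `1e-9` of a boundary are clipped onto it.
#'
#' @param m overall methylation frequency of CpG cytosines.
#' @param U unmethylated-dyad frequency.
#' @return A [DyadFreqs-class] object.
#' @examples
#' freqsFromSummary(0.5, 0.4)
#' @export
freqsFromSummary <- function(m, U) {
  stopifnot(length(m) == 1L, length(U) == 1L, m >= 0, m <= 1)
  lo <- max(1 - 2 * m, 0)
  hi <- 1 - m
  if (U < lo - SIMPLEX_TOL) {
    stop(sprintf(
      "(m = %g, U = %g) infeasible: U below the dispersive boundary %g",
      m, U, lo
    ))
  }
  if (U > hi + SIMPLEX_TOL) {
    stop(sprintf(
      "(m = %g, U = %g) infeasible: U above the conservative boundary %g",
      m, U, hi
    ))
  }
  U <- min(max(U, lo), hi)
  dyadFreqs(U + 2 * m - 1, 2 * (1 - U - m), U)
}

#' Boundaries of the methylation configuration space
#'
#' For a methylation frequency m, the unmethylated-dyad frequencies on
#' the three reference curves of (m, U) space:
#' * dispersive boundary (complete discordance preference):
#'   `U = max(1 - 2m, 0)` — for m > 0.5 no unmethylated dyads remain;
#' * random-placement curve (RCP = 1): `U = (1 - m)^2`, the binomial
#'   expectation;
#' * conservative boundary (complete concordance preference):
#'   `U = 1 - m`.
#'
#' @param m methylation frequency (vectorized), in [0, 1].
#' @return For scalar `m`, a named numeric vector
#'   `c(dispersive = , random = , conservative = )`; for vector `m`, a
#'   data.frame with columns `m`, `dispersive`, `random`,
#'   `conservative`.
#' @examples
#' regionBoundaries(0.5)
#' regionBoundaries(0.75)
#' @export
regionBoundaries <- function(m) {
  stopifnot(all(m >= 0), all(m <= 1))
  disp <- pmax(1 - 2 * m, 0)
  rand <- (1 - m)^2
  cons <- 1 - m
  if (length(m) == 1L) {
    c(dispersive = disp, random = rand, conservative = cons)
  } else {
    data.frame(m = m, dispersive = disp, random = rand,
               conservative = cons)
  }
}

# Vectorized inverse of the contour equation. For each (m, r) solves
#   (r^2 - 1) U^2 - (2 (1 - m) r^2 + 2 m - 1) U + r^2 (1 - m)^2 = 0
# and returns the root inside [max(1 - 2m, 0), 1 - m]. r = 1 is the
# linear (binomial) case; if both roots are feasible the smaller is
# kept, continuous with the r -> 1 limit.
.uFromMRcpVec <- function(m, r) {
  n <- max(length(m), length(r))
  m <- rep_len(m, n)
  r <- rep_len(r, n)
  lo <- pmax(1 - 2 * m, 0)
  hi <- 1 - m
  U <- rep(NA_real_, n)

  inf <- is.infinite(r)
  U[inf] <- hi[inf]
  one <- !inf & abs(r - 1) < 1e-12
  U[one] <- (1 - m[one])^2

  i <- which(!inf & !one)
  if (length(i) > 0L) {
    a <- r[i]^2 - 1
    b <- -(2 * (1 - m[i]) * r[i]^2 + 2 * m[i] - 1)
    cc <- r[i]^2 * (1 - m[i])^2
    disc <- pmax(b^2 - 4 * a * cc, 0)
    sq <- sqrt(disc)
    r1 <- (-b - sq) / (2 * a)
    r2 <- (-b + sq) / (2 * a)
    tol <- 1e-9
    ok1 <- r1 >= lo[i] - tol & r1 <= hi[i] + tol
    ok2 <- r2 >= lo[i] - tol & r2 <= hi[i] + tol
    pick <- ifelse(ok1 & ok2, pmin(r1, r2), ifelse(ok1, r1, r2))
    bad <- !ok1 & !ok2
    if (any(bad)) {
      stop(sprintf("no feasible root for (m = %g, r = %g)",
                   m[i][bad][1L], r[i][bad][1L]))
    }
    U[i] <- pmin(pmax(pick, lo[i]), hi[i])
  }
  U
}

#' Unmethylated-dyad frequency on an RCP contour
#'
#' For a methylation frequency m and a target RCP value r, returns the
#' unique U in the feasible band `[max(1 - 2m, 0), 1 - m]` such that the
#' dyad frequencies implied by (m, U) have RCP equal to r. This is the
#' contour-line construction of the configuration-space plot.
#'
#' @param m methylation frequency in (0, 1).
#' @param r target RCP, >= 0 (`Inf` gives the conservative boundary).
#' @return The unmethylated-dyad frequency U.
#' @examples
#' uFromMRcp(0.3, 1)   # binomial curve: (1 - m)^2
#' uFromMRcp(0.5, 2)   # 1/3: equal dyad-state frequencies
#' @export
uFromMRcp <- function(m, r) {
  stopifnot(length(m) == 1L, length(r) == 1L, m > 0, m < 1, r >= 0)
  .uFromMRcpVec(m, r)
}

#' Points along an RCP contour
#'
#' Evaluates [uFromMRcp()] over a grid of methylation frequencies,
#' giving a polyline for drawing the contour of constant RCP in (m, U)
#' space.
#'
#' @param r RCP value of the contour.
#' @param mGrid numeric vector of methylation frequencies in (0, 1).
#' @return data.frame with columns `m`, `U`, `r`.
#' @examples
#' rcpContour(2, c(0.2, 0.5, 0.8))
#' @export
rcpContour <- function(r, mGrid) {
  stopifnot(length(r) == 1L, r >= 0, all(mGrid > 0), all(mGrid < 1))
  data.frame(m = mGrid, U = .uFromMRcpVec(mGrid, r), r = r)
}

#' Pooled dyad frequencies of a cell-subpopulation mixture
#'
#' The dyad frequencies observed when sequencing a population composed
#' of subpopulations with different methylation systems: the weighted
#' average of the component frequencies, state by state. Used to ask how
#' large a high-RCP subpopulation (e.g. spontaneously differentiated
#' cells in a stem-cell culture) must be to explain an observed pooled
#' RCP.
#'
#' @param freqsList list of [DyadFreqs-class] components.
#' @param weights numeric vector of subpopulation proportions; must sum
#'   to 1 within `1e-9`.
#' @return A [DyadFreqs-class] object.
#' @examples
#' mixtureFreqs(
#'   list(dyadFreqs(0.8, 0, 0.2), dyadFreqs(0.64, 0.32, 0.04)),
#'   c(0.5, 0.5)
#' )
#' @export
mixtureFreqs <- function(freqsList, weights) {
  stopifnot(length(freqsList) == length(weights), length(weights) >= 1L)
  if (any(weights < 0) || any(weights > 1)) {
    stop("mixture weights must lie in [0, 1]")
  }
  if (abs(sum(weights) - 1) > SIMPLEX_TOL) {
    stop(sprintf("mixture weights must sum to 1 (got %.12g)",
                 sum(weights)))
  }
  mat <- vapply(freqsList, function(f) {
    stopifnot(is(f, "DyadFreqs"))
    c(f@M, f@H, f@U)
  }, numeric(3L))
  dyadFreqs(as.numeric(mat %*% weights))
}

#' Minimum subpopulation fraction explaining an observed RCP
#'
#' The smallest proportion w of a high-RCP component such that the
#' pooled frequencies `w * high + (1 - w) * low` reach at least the
#' target RCP. Solved by bisection to `1e-6`; monotonicity of the pooled
#' RCP in w is verified on the instance before solving.
#'
#' @param targetR the observed (pooled) RCP to explain.
#' @param high [DyadFreqs-class] of the concordance-preferring
#'   subpopulation; must have `rcp(high) > targetR`.
#' @param low [DyadFreqs-class] of the background subpopulation; must
#'   have `rcp(low) < targetR`.
#' @return The minimal weight on `high`, in [0, 1].
#' @examples
#' high <- dyadFreqs(0.8, 0, 0.2)              # fully concordant, m = 0.8
#' low <- freqsFromSummary(0.8, (1 - 0.8)^2)   # random placement, m = 0.8
#' minFractionForRcp(3.674, high, low)
#' @export
minFractionForRcp <- function(targetR, high, low) {
  stopifnot(is(high, "DyadFreqs"), is(low, "DyadFreqs"),
            length(targetR) == 1L, targetR >= 0)
  rHigh <- rcp(high)
  rLow <- rcp(low)
  if (!(rHigh > rLow)) stop("rcp(high) must exceed rcp(low)")
  if (targetR <= rLow) return(0)
  if (targetR > rHigh) {
    stop("rcp(high) must be at least the target RCP")
  }
  if (targetR == rHigh) return(1)
  pooledR <- function(w) {
    rcp(mixtureFreqs(list(high, low), c(w, 1 - w)))
  }
  wGrid <- seq(0, 1, by = 0.05)
  rGrid <- vapply(wGrid, pooledR, numeric(1L))
  if (is.unsorted(rGrid, strictly = FALSE)) {
    stop("pooled RCP is not monotone in the mixture weight for these ",
         "components; bisection is not applicable")
  }
  lo <- 0
  hi <- 1
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pooledR(mid) >= targetR) hi <- mid else lo <- mid
  }
  hi
}
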