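# Forward model and inversion for bisulfite conversion errors at the
# dyad level.
#
# Per cytosine, per strand, independently and strand-symmetrically:
#   truly methylated   -> reads methylated with prob 1 - c  (c = inappropriate)
#   truly unmethylated -> reads methylated with prob f      (f = failed)
# The two strands of a dyad combine these Bernoulli misreads into a
# 3x3 kernel over {FULL, HEMI, UNMETH}, with the two hemimethylated
# orientations collapsed.

# 3x3 row-stochastic matrix, rows = true state, cols = observed state.
.errorMatrix <- function(f, c0) {
  mm <- 1 - c0 # methylated strand reads methylated
  um <- f      # unmethylated strand reads methylated
  rbind(
    FULL = c(mm^2, 2 * mm * (1 - mm), (1 - mm)^2),
    HEMI = c(mm * um, mm * (1 - um) + (1 - mm) * um, (1 - mm) * (1 - um)),
    UNMETH = c(um^2, 2 * um * (1 - um), (1 - um)^2)
  )
}

#' Conversion-error transition matrix
#'
#' The 3x3 row-stochastic matrix mapping true dyad states (rows: FULL,
#' HEMI, UNMETH) to observed dyad states (columns, same order) under
#' per-strand, strand-symmetric, independent bisulfite misreads: a
#' truly methylated cytosine reads methylated with probability
#' `1 - inappropriate`, a truly unmethylated cytosine reads methylated
#' with probability `failed`. The two hemimethylated orientations are
#' collapsed.
#'
#' @param rates a [ConversionRates-class] object.
#' @return A 3x3 numeric matrix with dimnames
#'   `FULL`/`HEMI`/`UNMETH`; every row sums to 1.
#' @examples
#' errorMatrix(conversionRates(failed = 0.1, inappropriate = 0))
#' @export
errorMatrix <- function(rates) {
  stopifnot(is(rates, "ConversionRates"))
  E <- .errorMatrix(rates@failed, rates@inappropriate)
  colnames(E) <- rownames(E)
  E
}

#' Push dyad frequencies through the conversion-error model
#'
#' The dyad-state frequencies expected to be observed when the true
#' frequencies are `freqs` and reads suffer conversion errors at
#' `rates`: `observed = true %*% errorMatrix(rates)`. Conversion errors
#' inflate hemimethylation and so pull RCP toward 1.
#'
#' @param freqs true [DyadFreqs-class].
#' @param rates [ConversionRates-class].
#' @return Observed [DyadFreqs-class].
#' @examples
#' applyErrors(dyadFreqs(0, 0, 1), conversionRates(failed = 0.1))
#' @seealso [correctFreqs()] for the inverse.
#' @export
applyErrors <- function(freqs, rates) {
  stopifnot(is(freqs, "DyadFreqs"), is(rates, "ConversionRates"))
  E <- .errorMatrix(rates@failed, rates@inappropriate)
  dyadFreqs(as.numeric(c(freqs@M, freqs@H, freqs@U) %*% E))
}

# Vectorized forward map on an n x 3 matrix of frequency rows.
.applyErrorsMat <- function(P, f, c0) {
  P %*% .errorMatrix(f, c0)
}

# Vectorized inverse map with clip-and-renormalize projection.
# Returns an n x 3 matrix; attribute "clipped" flags rows that left the
# simplex and were projected.
.correctFreqsMat <- function(P, f, c0) {
  Einv <- solve(.errorMatrix(f, c0))
  X <- P %*% Einv
  neg <- X < 0
  clipped <- rowSums(neg) > 0L
  X[neg] <- 0
  X / rowSums(X)
}

#' Correct observed dyad frequencies for conversion error
#'
#' Inverts [applyErrors()]: solves `observed = true %*% E` for the true
#' frequencies. With sampling noise the algebraic solution can leave the
#' simplex; negative entries are then clipped to zero and the vector
#' renormalized, with a warning. The error matrix is invertible whenever
#' `failed + inappropriate < 1`.
#'
#' @param observed observed [DyadFreqs-class].
#' @param rates [ConversionRates-class].
#' @return Corrected (true-scale) [DyadFreqs-class].
#' @examples
#' correctFreqs(dyadFreqs(0.01, 0.18, 0.81), conversionRates(failed = 0.1))
#' @export
correctFreqs <- function(observed, rates) {
  stopifnot(is(observed, "DyadFreqs"), is(rates, "ConversionRates"))
  E <- .errorMatrix(rates@failed, rates@inappropriate)
  x <- solve(t(E), c(observed@M, observed@H, observed@U))
  if (any(x < -SIMPLEX_TOL)) {
    warning("corrected frequencies left the simplex; ",
            "negative entries clipped and renormalized")
  }
  x[x < 0] <- 0
  dyadFreqs(x / sum(x))
}
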