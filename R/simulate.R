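# Synthetic double-stranded methylation reads with known (m, RCP),
# optional within-read correlation, and injected conversion errors.

#' Dyad frequencies with a prescribed (m, RCP)
#'
#' The unique dyad-state frequencies whose methylation frequency is m
#' and whose RCP is r: solves the contour equation for U
#' ([uFromMRcp()]) and maps back through [freqsFromSummary()].
#' `r = Inf` gives the conservative boundary (M = m, H = 0), `r = 0`
#' the dispersive boundary.
#'
#' @param m methylation frequency in (0, 1).
#' @param r RCP value, >= 0 or `Inf`.
#' @return A [DyadFreqs-class] with `rcp(result) == r` (to 1e-9 for
#'   finite r).
#' @examples
#' targetFreqs(0.5, 1) # binomial: (0.25, 0.5, 0.25)
#' targetFreqs(0.5, 2) # equal frequencies (1/3, 1/3, 1/3)
#' @export
targetFreqs <- function(m, r) {
  freqsFromSummary(m, uFromMRcp(m, r))
}

#' Simulation settings for one synthetic sample
#'
#' Bundles the arguments of [simulateReads()] for use with
#' [simulateTrajectory()]. Validates feasibility of (m, r) eagerly.
#'
#' @inheritParams simulateReads
#' @return A named list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nReads, dyadsPerRead, m = NULL, r = NULL,
                             freqs = NULL, rho = 0,
                             rates = conversionRates(), seed,
                             locus = "locus1", sampleId = "sample1") {
  if (is.null(freqs)) {
    freqs <- targetFreqs(m, r)
  }
  stopifnot(is(freqs, "DyadFreqs"), is(rates, "ConversionRates"),
            nReads >= 0, dyadsPerRead >= 1, rho >= 0, rho < 1,
            length(seed) == 1L, is.finite(seed))
  structure(
    list(nReads = as.integer(nReads),
         dyadsPerRead = as.integer(dyadsPerRead), freqs = freqs,
         rho = rho, rates = rates, seed = as.integer(seed),
         locus = locus, sampleId = sampleId),
    class = "SimulationConfig"
  )
}

# Random molecule barcodes: non-cytosine nucleotides only (a cytosine
# in the linker would be altered by bisulfite treatment), unique within
# the sample. Length grows with the sample size so uniqueness is cheap.
.randomBarcodes <- function(n, len = 7L) {
  if (n == 0L) return(character(0))
  len <- max(len, ceiling(log(10 * n) / log(3)))
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(c("A", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1L))
  }
  bc <- draw(n)
  while (anyDuplicated(bc) > 0L) {
    dup <- duplicated(bc)
    bc[dup] <- draw(sum(dup))
  }
  bc
}

#' Simulate double-stranded methylation reads
#'
#' Draws `nReads` hairpin reads of `dyadsPerRead` dyads each. Dyad
#' states follow a stationary first-order chain over
#' `{FULL, HEMI, UNMETH}` whose stationary distribution is the target
#' frequencies and whose one-step kernel is
#' `(1 - rho) * stationary + rho * identity`: `rho = 0` gives
#' independent dyads, larger `rho` makes neighboring dyads on one
#' molecule sticky, emulating the within-read correlation of real
#' patterns. Hemimethylated dyads are assigned top/bottom orientation
#' with probability 1/2 each. Conversion errors are then injected per
#' strand per dyad at the configured rates, so the expected observed
#' frequencies equal `applyErrors(truth, rates)`. Barcodes are unique
#' random non-cytosine strings; the batchstamp is the sample id.
#' Identical seeds give bit-identical output.
#'
#' @param nReads number of reads.
#' @param dyadsPerRead dyads per read.
#' @param m,r methylation frequency and RCP of the generating system
#'   (converted to frequencies via [targetFreqs()]); alternatively give
#'   `freqs` directly.
#' @param freqs optional [DyadFreqs-class] overriding `(m, r)`.
#' @param rho within-read correlation parameter in [0, 1).
#' @param rates [ConversionRates-class] of injected errors.
#' @param seed integer RNG seed (required).
#' @param locus,sampleId labels written on every read.
#' @return List with `reads` ([DyadReads-class]) and `truth`
#'   ([DyadFreqs-class], the error-free generating frequencies).
#' @examples
#' sim <- simulateReads(nReads = 10, dyadsPerRead = 4, m = 0.4, r = 5,
#'                      seed = 1)
#' sim$reads
#' @export
simulateReads <- function(nReads, dyadsPerRead, m = NULL, r = NULL,
                          freqs = NULL, rho = 0,
                          rates = conversionRates(), seed,
                          locus = "locus1", sampleId = "sample1") {
  if (is.null(freqs)) freqs <- targetFreqs(m, r)
  stopifnot(is(freqs, "DyadFreqs"), is(rates, "ConversionRates"),
            nReads >= 0, dyadsPerRead >= 1, rho >= 0, rho < 1)
  nReads <- as.integer(nReads)
  D <- as.integer(dyadsPerRead)
  if (nReads == 0L) {
    return(list(reads = dyadReads(emptyReadFrame()), truth = freqs))
  }
  pi0 <- c(freqs@M, freqs@H, freqs@U)
  f <- rates@failed
  c0 <- rates@inappropriate

  df <- .withSeed(seed, {
    # collapsed true states: 1 = FULL, 2 = HEMI, 3 = UNMETH
    states <- matrix(0L, nReads, D)
    states[, 1L] <- sample.int(3L, nReads, replace = TRUE, prob = pi0)
    if (D > 1L) {
      for (j in 2L:D) {
        stay <- stats::runif(nReads) < rho
        fresh <- sample.int(3L, nReads, replace = TRUE, prob = pi0)
        states[, j] <- ifelse(stay, states[, j - 1L], fresh)
      }
    }
    hemiTop <- matrix(stats::runif(nReads * D) < 0.5, nReads, D)
    topM <- states == 1L | (states == 2L & hemiTop)
    botM <- states == 1L | (states == 2L & !hemiTop)
    # per-strand misreads: methylated survives with 1 - c0,
    # unmethylated escapes conversion with f
    flipTop <- matrix(stats::runif(nReads * D), nReads, D)
    flipBot <- matrix(stats::runif(nReads * D), nReads, D)
    obsTop <- ifelse(topM, flipTop >= c0, flipTop < f)
    obsBot <- ifelse(botM, flipBot >= c0, flipBot < f)
    code <- matrix("U", nReads, D)
    code[obsTop & obsBot] <- "F"
    code[obsTop & !obsBot] <- "T"
    code[!obsTop & obsBot] <- "B"
    dyads <- do.call(paste0, lapply(seq_len(D), function(j) code[, j]))
    data.frame(
      read_id = sprintf("%s_r%06d", sampleId, seq_len(nReads)),
      sample_id = sampleId, locus = locus, batchstamp = sampleId,
      barcode = .randomBarcodes(nReads), dyads = dyads,
      stringsAsFactors = FALSE
    )
  })
  list(reads = dyadReads(df), truth = freqs)
}

#' Concatenate simulated samples into a developmental trajectory
#'
#' Simulates each configuration with [simulateReads()] and concatenates
#' the reads into one multi-sample set, enabling end-to-end tests of
#' abrupt (single-step) and gradual (multi-step) RCP shifts such as
#' those seen across embryonic development. Sample ids must be
#' distinct.
#'
#' @param configs non-empty list of [simulationConfig()] objects with
#'   distinct `sampleId`s.
#' @return List with `reads` (combined [DyadReads-class]) and `truth`
#'   (named list of [DyadFreqs-class] per sample id).
#' @examples
#' cfgs <- list(
#'   simulationConfig(20, 4, m = 0.4, r = 20, seed = 1, sampleId = "early"),
#'   simulationConfig(20, 4, m = 0.4, r = 3, seed = 2, sampleId = "late")
#' )
#' simulateTrajectory(cfgs)$reads
#' @export
simulateTrajectory <- function(configs) {
  if (!is.list(configs) || length(configs) == 0L) {
    stop("configs must be a non-empty list of simulationConfig objects")
  }
  stopifnot(all(vapply(configs, inherits, logical(1L),
                       "SimulationConfig")))
  ids <- vapply(configs, `[[`, character(1L), "sampleId")
  if (anyDuplicated(ids) > 0L) {
    stop("duplicate sample ids in trajectory: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sims <- lapply(configs, function(cfg) {
    simulateReads(
      nReads = cfg$nReads, dyadsPerRead = cfg$dyadsPerRead,
      freqs = cfg$freqs, rho = cfg$rho, rates = cfg$rates,
      seed = cfg$seed, locus = cfg$locus, sampleId = cfg$sampleId
    )
  })
  reads <- dyadReads(do.call(rbind, lapply(sims, function(s) {
    s$reads@reads
  })))
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids
  list(reads = reads, truth = truth)
}
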