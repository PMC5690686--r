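#' @import methods
NULL

DYAD_STATE_CHARS <- c("F", "T", "B", "U", ".")
SIMPLEX_TOL <- 1e-9

#' DyadFreqs: frequencies of the three CpG-dyad methylation states
#'
#' A point on the 2-simplex holding the frequencies of fully methylated
#' (`M`), hemimethylated (`H`, both strand orientations collapsed), and
#' unmethylated (`U`) CpG/CpG dyads. These three frequencies are the
#' sufficient statistics of the RCP framework.
#'
#' @slot M numeric(1), frequency of fully methylated dyads.
#' @slot H numeric(1), frequency of hemimethylated dyads.
#' @slot U numeric(1), frequency of unmethylated dyads.
#'
#' @seealso [dyadFreqs()], [rcp()], [summaryFromFreqs()]
#' @exportClass DyadFreqs
setClass("DyadFreqs",
  representation(M = "numeric", H = "numeric", U = "numeric"),
  prototype(M = NA_real_, H = NA_real_, U = NA_real_)
)

setValidity("DyadFreqs", function(object) {
  v <- c(object@M, object@H, object@U)
  if (length(v) != 3L || anyNA(v)) {
    return("M, H, U must each be a single non-missing number")
  }
  if (any(v < -SIMPLEX_TOL) || any(v > 1 + SIMPLEX_TOL)) {
    return("M, H, U must lie in [0, 1]")
  }
  if (abs(sum(v) - 1) > SIMPLEX_TOL) {
    return(sprintf("M + H + U must equal 1 (got %.12g)", sum(v)))
  }
  TRUE
})

#' Construct dyad-state frequencies
#'
#' Builds a [DyadFreqs-class] object. Frequencies within `1e-9` of the
#' simplex are renormalized exactly onto it (and negatives within
#' tolerance clipped to zero); larger deviations are an error.
#'
#' @param M,H,U frequencies of fully methylated, hemimethylated, and
#'   unmethylated dyads. Alternatively `M` may be a numeric vector of
#'   length 3 `(M, H, U)`.
#' @return A `DyadFreqs` object.
#' @examples
#' dyadFreqs(0.25, 0.5, 0.25)
#' @export
dyadFreqs <- function(M, H = NULL, U = NULL) {
  if (is.null(H) && is.null(U) && length(M) == 3L) {
    v <- as.numeric(M)
  } else {
    v <- c(as.numeric(M), as.numeric(H), as.numeric(U))
  }
  if (length(v) != 3L || anyNA(v)) {
    stop("dyad frequencies must be three non-missing numbers")
  }
  if (any(v < -SIMPLEX_TOL)) {
    stop(sprintf("dyad frequency below 0: %.12g", min(v)))
  }
  if (abs(sum(v) - 1) > SIMPLEX_TOL) {
    stop(sprintf("dyad frequencies must sum to 1 (got %.12g)", sum(v)))
  }
  v <- pmax(v, 0)
  v <- v / sum(v)
  new("DyadFreqs", M = v[[1L]], H = v[[2L]], U = v[[3L]])
}

#' DyadCounts: observed tallies of the three dyad states
#'
#' Integer counts of fully methylated, hemimethylated, and unmethylated
#' dyads observed for one sample at one locus, optionally with the number
#' of sequenced molecules (reads) the dyads came from.
#'
#' @slot sampleId character(1) sample label.
#' @slot locus character(1) opaque locus label (no genomic coordinates).
#' @slot nFull,nHemi,nUnmeth integer(1) dyad-state tallies.
#' @slot nReads integer(1) number of reads tallied; 0 if unknown.
#'
#' @seealso [dyadCounts()], [countDyads()], [asFreqs()]
#' @exportClass DyadCounts
setClass("DyadCounts",
  representation(
    sampleId = "character", locus = "character",
    nFull = "integer", nHemi = "integer", nUnmeth = "integer",
    nReads = "integer"
  ),
  prototype(
    sampleId = NA_character_, locus = NA_character_,
    nFull = 0L, nHemi = 0L, nUnmeth = 0L, nReads = 0L
  )
)

setValidity("DyadCounts", function(object) {
  n <- c(object@nFull, object@nHemi, object@nUnmeth, object@nReads)
  if (anyNA(n)) return("counts must not be missing")
  if (any(n < 0L)) return("counts must be non-negative")
  TRUE
})

#' Construct a dyad-count record
#'
#' @param nFull,nHemi,nUnmeth non-negative integer dyad tallies.
#' @param nReads number of reads the dyads came from (0 if unknown).
#' @param sampleId,locus labels.
#' @return A [DyadCounts-class] object.
#' @examples
#' dyadCounts(40, 20, 40)
#' @export
dyadCounts <- function(nFull, nHemi, nUnmeth, nReads = 0L,
                       sampleId = NA_character_, locus = NA_character_) {
  asCount <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x < 0 || abs(x - round(x)) > 1e-8) {
      stop(sprintf("%s must be a single non-negative integer", what))
    }
    as.integer(round(x))
  }
  new("DyadCounts",
    sampleId = as.character(sampleId), locus = as.character(locus),
    nFull = asCount(nFull, "nFull"), nHemi = asCount(nHemi, "nHemi"),
    nUnmeth = asCount(nUnmeth, "nUnmeth"), nReads = asCount(nReads, "nReads")
  )
}

#' ConversionRates: bisulfite conversion-error probabilities
#'
#' Per-cytosine error rates of the bisulfite reaction: `failed` is the
#' probability that a truly unmethylated cytosine escapes conversion and
#' reads as methylated; `inappropriate` is the probability that a truly
#' methylated cytosine is converted and reads as unmethylated. Rates are
#' strand-symmetric and applied independently per strand.
#'
#' @slot failed numeric(1) failed-conversion probability.
#' @slot inappropriate numeric(1) inappropriate-conversion probability.
#'
#' @seealso [conversionRates()], [errorMatrix()], [correctFreqs()]
#' @exportClass ConversionRates
setClass("ConversionRates",
  representation(failed = "numeric", inappropriate = "numeric"),
  prototype(failed = 0, inappropriate = 0)
)

setValidity("ConversionRates", function(object) {
  f <- object@failed
  c0 <- object@inappropriate
  if (length(f) != 1L || length(c0) != 1L || anyNA(c(f, c0))) {
    return("rates must be single non-missing numbers")
  }
  if (f < 0 || f >= 1 || c0 < 0 || c0 >= 1) {
    return("rates must lie in [0, 1)")
  }
  if (f + c0 >= 1) return("failed + inappropriate must be < 1")
  TRUE
})

#' Construct conversion-error rates
#'
#' @param failed probability an unmethylated cytosine reads methylated.
#' @param inappropriate probability a methylated cytosine reads
#'   unmethylated.
#' @return A [ConversionRates-class] object.
#' @examples
#' conversionRates(failed = 0.011, inappropriate = 0.0109)
#' @export
conversionRates <- function(failed = 0, inappropriate = 0) {
  obj <- new("ConversionRates",
    failed = as.numeric(failed),
    inappropriate = as.numeric(inappropriate)
  )
  validObject(obj)
  obj
}

#' DyadReads: a set of double-stranded methylation pattern reads
#'
#' One row per sequenced hairpin molecule. Each read carries identity
#' metadata (an experiment-level batchstamp and a molecule-level barcode,
#' both encoded in the hairpin linker) and an ordered dyad-state string
#' over the alphabet `F` (fully methylated), `T`/`B` (hemimethylated on
#' the top/bottom strand), `U` (unmethylated), and `.` (missing).
#'
#' @slot reads data.frame with character columns `read_id`, `sample_id`,
#'   `locus`, `batchstamp`, `barcode`, `dyads`.
#'
#' @seealso [dyadReads()], [readPatternFile()], [deduplicateReads()],
#'   [countDyads()]
#' @exportClass DyadReads
setClass("DyadReads", representation(reads = "data.frame"))

READ_COLUMNS <- c("read_id", "sample_id", "locus", "batchstamp", "barcode",
                  "dyads")

setValidity("DyadReads", function(object) {
  df <- object@reads
  if (!identical(names(df), READ_COLUMNS)) {
    return(sprintf("columns must be exactly: %s",
                   paste(READ_COLUMNS, collapse = ", ")))
  }
  if (!all(vapply(df, is.character, logical(1L)))) {
    return("all columns must be character")
  }
  if (nrow(df) > 0L) {
    if (any(is.na(df$dyads)) || any(!nzchar(df$dyads))) {
      return("every read must have a non-empty dyad-state string")
    }
    bad <- grepl(sprintf("[^%s]", paste(DYAD_STATE_CHARS, collapse = "")),
                 df$dyads, fixed = FALSE)
    if (any(bad)) {
      ch <- setdiff(unique(strsplit(paste(df$dyads[bad], collapse = ""),
                                    "")[[1L]]), DYAD_STATE_CHARS)
      return(sprintf("illegal dyad-state character(s): %s",
                     paste(ch, collapse = ", ")))
    }
  }
  TRUE
})

#' Construct a read set from a data frame
#'
#' @param reads data.frame with character columns `read_id`, `sample_id`,
#'   `locus`, `batchstamp`, `barcode`, `dyads`; `dyads` strings use the
#'   alphabet `F`, `T`, `B`, `U`, `.`.
#' @return A [DyadReads-class] object.
#' @examples
#' dyadReads(data.frame(
#'   read_id = "r1", sample_id = "s1", locus = "L1",
#'   batchstamp = "AC12", barcode = "GATTACA", dyads = "FTU."
#' ))
#' @export
dyadReads <- function(reads) {
  df <- as.data.frame(reads, stringsAsFactors = FALSE)
  missing <- setdiff(READ_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("missing read columns: ", paste(missing, collapse = ", "))
  }
  df <- df[READ_COLUMNS]
  df[] <- lapply(df, as.character)
  rownames(df) <- NULL
  obj <- new("DyadReads", reads = df)
  validObject(obj)
  obj
}

#' RcpEstimate: an RCP point estimate with confidence interval
#'
#' @slot point numeric(1) plug-in (error-corrected) RCP estimate.
#' @slot pointBc numeric(1) bias-corrected point estimate (BCa-adjusted
#'   median for the bootstrap method; equal to `point` for the
#'   likelihood method).
#' @slot ciLow,ciHigh numeric(1) confidence-interval endpoints.
#' @slot level numeric(1) confidence level in (0, 1).
#' @slot method character(1), `"bootstrap_bca"` or `"likelihood"`.
#' @slot nBoot integer(1) bootstrap replicates (0 for likelihood).
#' @slot seed integer(1) RNG seed used (NA for likelihood).
#' @slot nDropped integer(1) degenerate bootstrap resamples dropped.
#' @slot flags character vector of warnings attached to the estimate,
#'   e.g. `"one_sided_lower"` when a zero count cell forces a one-sided
#'   interval.
#'
#' @seealso [bootstrapRcp()], [likelihoodCi()]
#' @exportClass RcpEstimate
setClass("RcpEstimate",
  representation(
    point = "numeric", pointBc = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    level = "numeric", method = "character",
    nBoot = "integer", seed = "integer",
    nDropped = "integer", flags = "character"
  ),
  prototype(
    point = NA_real_, pointBc = NA_real_,
    ciLow = NA_real_, ciHigh = NA_real_,
    level = 0.95, method = NA_character_,
    nBoot = 0L, seed = NA_integer_, nDropped = 0L, flags = character()
  )
)

setValidity("RcpEstimate", function(object) {
  if (!(object@level > 0 && object@level < 1)) {
    return("level must lie in (0, 1)")
  }
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh) {
    return("ciLow must not exceed ciHigh")
  }
  TRUE
})

#' TestResult: outcome of an RCP hypothesis test
#'
#' @slot statistic numeric(1) test statistic.
#' @slot pValue numeric(1) p-value in [0, 1].
#' @slot tails character(1), `"one"` or `"two"`.
#' @slot method character(1), one of `"bootstrap"`, `"permutation"`,
#'   `"mlct"`, `"heterogeneity"`.
#' @slot df numeric(1) chi-square degrees of freedom (NA for resampling
#'   tests).
#' @slot flags character vector, e.g. `"parametric_bootstrap"` when a
#'   zero-cell boundary forced the MLCT p-value onto a parametric
#'   bootstrap.
#'
#' @seealso [mlct()], [permutationTest()], [heterogeneityTest()],
#'   [testRcpVsNull()]
#' @exportClass TestResult
setClass("TestResult",
  representation(
    statistic = "numeric", pValue = "numeric", tails = "character",
    method = "character", df = "numeric", flags = "character"
  ),
  prototype(
    statistic = NA_real_, pValue = NA_real_, tails = "two",
    method = NA_character_, df = NA_real_, flags = character()
  )
)

setValidity("TestResult", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1)) {
    return("pValue must lie in [0, 1]")
  }
  if (!object@tails %in% c("one", "two")) {
    return("tails must be 'one' or 'two'")
  }
  if (!is.na(object@df) && object@df < 1) return("df must be >= 1")
  TRUE
})
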