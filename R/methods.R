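# Accessors, coercions and show methods for the value classes.

#' @rdname DyadCounts-class
#' @aliases asFreqs,DyadCounts-method
#' @param ... unused.
#' @export
setMethod("asFreqs", "DyadCounts", function(x, ...) {
  total <- x@nFull + x@nHemi + x@nUnmeth
  if (total < 1L) stop("cannot form frequencies from all-zero counts")
  dyadFreqs(c(x@nFull, x@nHemi, x@nUnmeth) / total)
})

#' @rdname accessors
#' @export
setMethod("point", "RcpEstimate", function(x) x@point)

#' @rdname accessors
#' @export
setMethod("pointBc", "RcpEstimate", function(x) x@pointBc)

#' @rdname accessors
#' @export
setMethod("ciLimits", "RcpEstimate", function(x) {
  c(low = x@ciLow, high = x@ciHigh)
})

#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("statistic", "TestResult", function(x) x@statistic)

#' @rdname accessors
#' @export
setMethod("flags", "RcpEstimate", function(x) x@flags)

#' @rdname accessors
#' @export
setMethod("flags", "TestResult", function(x) x@flags)

#' @describeIn DyadReads-class number of reads.
#' @export
setMethod("length", "DyadReads", function(x) nrow(x@reads))

#' @describeIn DyadReads-class subset reads, preserving order.
#' @param i index vector.
#' @param j,drop,... unused.
#' @export
setMethod("[", "DyadReads", function(x, i, j, ..., drop = FALSE) {
  dyadReads(x@reads[i, , drop = FALSE])
})

#' @describeIn DyadReads-class underlying data frame.
#' @param row.names,optional passed through.
#' @export
setMethod("as.data.frame", "DyadReads",
  function(x, row.names = NULL, optional = FALSE, ...) {
    df <- x@reads
    rownames(df) <- row.names
    df
  }
)

setMethod("show", "DyadReads", function(object) {
  df <- object@reads
  cat(sprintf("DyadReads with %d read(s)\n", nrow(df)))
  if (nrow(df) > 0L) {
    cat(sprintf("  samples: %s\n",
                paste(unique(df$sample_id), collapse = ", ")))
    cat(sprintf("  loci:    %s\n", paste(unique(df$locus), collapse = ", ")))
    nd <- nchar(df$dyads)
    cat(sprintf("  dyads per read: %d-%d\n", min(nd), max(nd)))
  }
  invisible(object)
})

setMethod("show", "DyadFreqs", function(object) {
  cat(sprintf("DyadFreqs  M = %.6g  H = %.6g  U = %.6g\n",
              object@M, object@H, object@U))
  invisible(object)
})

setMethod("show", "DyadCounts", function(object) {
  cat(sprintf(
    "DyadCounts [%s / %s]  full = %d  hemi = %d  unmeth = %d  reads = %d\n",
    object@sampleId, object@locus, object@nFull, object@nHemi,
    object@nUnmeth, object@nReads
  ))
  invisible(object)
})

setMethod("show", "ConversionRates", function(object) {
  cat(sprintf("ConversionRates  failed = %.4g  inappropriate = %.4g\n",
              object@failed, object@inappropriate))
  invisible(object)
})

setMethod("show", "RcpEstimate", function(object) {
  cat(sprintf("RcpEstimate (%s)\n", object@method))
  cat(sprintf("  RCP = %.6g (bias-corrected %.6g)\n",
              object@point, object@pointBc))
  cat(sprintf("  %g%% CI [%.6g, %.6g]\n", 100 * object@level,
              object@ciLow, object@ciHigh))
  if (object@nBoot > 0L) {
    cat(sprintf("  n_boot = %d, seed = %d, dropped = %d\n",
                object@nBoot, object@seed, object@nDropped))
  }
  if (length(object@flags) > 0L) {
    cat(sprintf("  flags: %s\n", paste(object@flags, collapse = ", ")))
  }
  invisible(object)
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult (%s, %s-tailed)\n", object@method, object@tails))
  cat(sprintf("  statistic = %.6g", object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %g", object@df))
  cat(sprintf("\n  p = %.6g\n", object@pValue))
  if (length(object@flags) > 0L) {
    cat(sprintf("  flags: %s\n", paste(object@flags, collapse = ", ")))
  }
  invisible(object)
})
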