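# Run reports: self-describing JSON records of what a pipeline run
# computed, sufficient (parameters + seed) to reproduce it.

#' @importFrom utils packageVersion
.toolVersion <- function() {
  as.character(utils::packageVersion("rcpmeth"))
}

.estimateAsList <- function(est) {
  list(
    type = "RcpEstimate", point = est@point, pointBc = est@pointBc,
    ciLow = est@ciLow, ciHigh = est@ciHigh, level = est@level,
    method = est@method, nBoot = est@nBoot, seed = est@seed,
    nDropped = est@nDropped, flags = as.list(est@flags)
  )
}

.testAsList <- function(tst) {
  list(
    type = "TestResult", statistic = tst@statistic,
    pValue = tst@pValue, tails = tst@tails, method = tst@method,
    df = tst@df, flags = as.list(tst@flags)
  )
}

.resultFromList <- function(x) {
  if (identical(x$type, "RcpEstimate")) {
    new("RcpEstimate",
      point = as.numeric(x$point), pointBc = as.numeric(x$pointBc),
      ciLow = as.numeric(x$ciLow), ciHigh = as.numeric(x$ciHigh),
      level = as.numeric(x$level), method = as.character(x$method),
      nBoot = as.integer(x$nBoot),
      seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
      nDropped = as.integer(x$nDropped),
      flags = as.character(unlist(x$flags))
    )
  } else if (identical(x$type, "TestResult")) {
    new("TestResult",
      statistic = as.numeric(x$statistic),
      pValue = as.numeric(x$pValue), tails = as.character(x$tails),
      method = as.character(x$method), df = as.numeric(x$df),
      flags = as.character(unlist(x$flags))
    )
  } else {
    stop("unknown result type in report")
  }
}

#' Build a run report
#'
#' A run report records the command, inputs, parameters, seed, and
#' results of a pipeline invocation; together with the package version
#' it suffices to reproduce the run. Reports serialize losslessly to
#' JSON via [writeRunReport()] / [readRunReport()].
#'
#' @param command name of the command executed.
#' @param inputs character vector of input file names.
#' @param parameters named list of parameter values.
#' @param results list of [RcpEstimate-class] / [TestResult-class]
#'   objects, optionally named by sample.
#' @param warnings character vector of run warnings.
#' @param seed integer seed governing the run.
#' @return A list of class `RunReport`.
#' @export
runReport <- function(command, inputs = character(),
                      parameters = list(), results = list(),
                      warnings = character(), seed = NA_integer_) {
  structure(
    list(
      command = command, inputs = as.character(inputs),
      parameters = parameters, results = results,
      warnings = as.character(warnings),
      tool_version = .toolVersion(), seed = as.integer(seed)
    ),
    class = "RunReport"
  )
}

#' @rdname runReport
#' @param report a `RunReport`.
#' @param file JSON path.
#' @export
writeRunReport <- function(report, file) {
  stopifnot(inherits(report, "RunReport"))
  ser <- report
  ser$results <- lapply(report$results, function(r) {
    if (is(r, "RcpEstimate")) .estimateAsList(r) else .testAsList(r)
  })
  class(ser) <- NULL
  jsonlite::write_json(ser, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' @rdname runReport
#' @export
readRunReport <- function(file) {
  x <- jsonlite::read_json(file)
  rep <- runReport(
    command = x$command,
    inputs = as.character(unlist(x$inputs)),
    parameters = lapply(x$parameters, function(v) {
      if (is.list(v)) unlist(v) else v
    }),
    results = lapply(x$results, .resultFromList),
    warnings = as.character(unlist(x$warnings)),
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
  names(rep$results) <- names(x$results)
  rep$tool_version <- as.character(x$tool_version)
  rep
}

#' Estimate RCP for every sample of an input file
#'
#' The end-to-end estimation pipeline behind the command-line `estimate`
#' command. Pattern-file inputs are deduplicated
#' ([deduplicateReads()]), tallied ([countDyads()]), corrected and
#' estimated; dyad-count tables skip straight to correction and
#' estimation (count tables carry their own conversion rates; the
#' `rates` argument applies to pattern files). Samples whose RCP is
#' undefined (completely methylated or unmethylated) are reported as
#' warnings and the run continues for the remaining samples.
#'
#' @param file input path (pattern file or count table).
#' @param type `"patterns"` or `"counts"`.
#' @param method `"bootstrap"` or `"likelihood"`. Count-table input
#'   supports only `"likelihood"` (read-level resampling needs reads).
#' @param rates [ConversionRates-class] for pattern-file input.
#' @param nBoot,level,seed estimation settings.
#' @return A `RunReport` whose `results` hold one
#'   [RcpEstimate-class] per estimable sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCountTable(list(list(counts = dyadCounts(40, 20, 40, sampleId = "s1",
#'                                               locus = "L1"),
#'                           rates = conversionRates())), tf)
#' runEstimate(tf, type = "counts", method = "likelihood", seed = 1)
#' @export
runEstimate <- function(file, type = c("patterns", "counts"),
                        method = c("bootstrap", "likelihood"),
                        rates = conversionRates(), nBoot = 10000,
                        level = 0.95, seed) {
  type <- match.arg(type)
  method <- match.arg(method)
  warningsOut <- character()
  results <- list()

  if (type == "counts") {
    if (method == "bootstrap") {
      stop("count-table input supports only method = 'likelihood' ",
           "(read-level bootstrap needs the reads)")
    }
    records <- readCountTable(file)
    for (rec in records) {
      key <- sprintf("%s/%s", rec$counts@sampleId, rec$counts@locus)
      est <- tryCatch(
        likelihoodCi(rec$counts, rec$rates, level = level),
        error = function(e) conditionMessage(e)
      )
      if (is.character(est)) {
        warningsOut <- c(warningsOut, sprintf("%s: %s", key, est))
      } else {
        results[[key]] <- est
      }
    }
  } else {
    reads <- readPatternFile(file)
    dd <- deduplicateReads(reads)
    if (dd$nRemoved > 0L) {
      warningsOut <- c(warningsOut, sprintf(
        "removed %d redundant read(s) by (batchstamp, barcode, locus)",
        dd$nRemoved
      ))
    }
    df <- dd$kept@reads
    for (sid in unique(df$sample_id)) {
      sub <- dyadReads(df[df$sample_id == sid, , drop = FALSE])
      est <- tryCatch(
        if (method == "bootstrap") {
          bootstrapRcp(sub, rates, nBoot = nBoot, level = level,
                       seed = seed)
        } else {
          likelihoodCi(countDyads(sub), rates, level = level)
        },
        error = function(e) conditionMessage(e)
      )
      if (is.character(est)) {
        warningsOut <- c(warningsOut, sprintf("%s: %s", sid, est))
      } else {
        results[[sid]] <- est
      }
    }
  }
  runReport(
    command = "estimate", inputs = file,
    parameters = list(type = type, method = method, nBoot = nBoot,
                      level = level, failed = rates@failed,
                      inappropriate = rates@inappropriate),
    results = results, warnings = warningsOut, seed = seed
  )
}

#' Render the configuration-space figure for estimated samples
#'
#' Takes count records (as from [readCountTable()]), corrects each for
#' its conversion rates, and plots the corrected (m, U) points with
#' [plotConfigurationSpace()].
#'
#' @param records list of `list(counts = , rates = )` records.
#' @param contours RCP contour values.
#' @param file optional output path (PNG or SVG by extension); when
#'   `NULL` the ggplot object is returned unrendered.
#' @return The ggplot object, invisibly when `file` is given.
#' @export
runPlot <- function(records, contours = c(1, 2, 5, 20), file = NULL) {
  if (length(records) == 0L) stop("no samples to plot")
  samples <- do.call(rbind, lapply(records, function(rec) {
    corr <- correctFreqs(asFreqs(rec$counts), rec$rates)
    s <- summaryFromFreqs(corr)
    data.frame(
      m = s[["m"]], U = s[["U"]],
      label = sprintf("%s/%s", rec$counts@sampleId, rec$counts@locus),
      stringsAsFactors = FALSE
    )
  }))
  p <- plotConfigurationSpace(samples, contours = contours)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}
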