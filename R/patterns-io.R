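# Reading, validation, deduplication and tabulation of double-stranded
# methylation pattern files and dyad-count tables.
#
# Pattern file: TSV, UTF-8, header
#   read_id  sample_id  locus  batchstamp  barcode  dyads
# with one row per sequenced hairpin molecule and the dyad string over
# {F, T, B, U, .} (fully methylated, hemimethylated on top/bottom
# strand, unmethylated, missing).
#
# Dyad-count table: TSV, header
#   sample_id locus n_full n_hemi n_unmeth n_reads failed_rate inapprop_rate

#' Read a double-stranded methylation pattern file
#'
#' Parses the tab-separated pattern dialect (header row
#' `read_id sample_id locus batchstamp barcode dyads`) into a
#' [DyadReads-class] object, one record per data line in file order.
#' Dyad-state characters map `F` = fully methylated, `T`/`B` =
#' hemimethylated on the top/bottom strand, `U` = unmethylated, `.` =
#' missing (partial double-stranded pattern). Malformed lines (wrong
#' column count) and illegal state characters raise errors naming the
#' line number or offending character. The fraction of missing dyads is
#' reported via `message()`.
#'
#' @param file path to the pattern file, or a connection.
#' @return A [DyadReads-class] object (possibly empty).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "read_id\tsample_id\tlocus\tbatchstamp\tbarcode\tdyads",
#'   "r1\ts1\tL1\tAC12\tGATTACA\tFTU."
#' ), tf)
#' readPatternFile(tf)
#' @seealso [writePatternFile()], [deduplicateReads()], [countDyads()]
#' @export
readPatternFile <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  if (length(lines) == 0L) stop("pattern file is empty (no header)")
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, READ_COLUMNS)) {
    stop(sprintf("unexpected pattern-file header: '%s'", lines[[1L]]))
  }
  body <- lines[-1L]
  if (length(body) == 0L) {
    return(dyadReads(emptyReadFrame()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[[1L]]
    stop(sprintf("malformed pattern line %d: expected 6 columns, got %d",
                 bad + 1L, nf[[bad]]))
  }
  mat <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- READ_COLUMNS
  allStates <- strsplit(paste(df$dyads, collapse = ""), "")[[1L]]
  illegal <- setdiff(unique(allStates), DYAD_STATE_CHARS)
  if (length(illegal) > 0L) {
    stop(sprintf("illegal dyad-state character '%s' in pattern file",
                 illegal[[1L]]))
  }
  if (any(!nzchar(df$dyads))) {
    stop(sprintf("empty dyad string at pattern line %d",
                 which(!nzchar(df$dyads))[[1L]] + 1L))
  }
  missingFrac <- mean(allStates == ".")
  message(sprintf("read %d pattern(s); missing-dyad fraction %.4f",
                  nrow(df), missingFrac))
  dyadReads(df)
}

emptyReadFrame <- function() {
  df <- as.data.frame(
    setNames(replicate(length(READ_COLUMNS), character(0),
                       simplify = FALSE), READ_COLUMNS),
    stringsAsFactors = FALSE
  )
  df
}

#' Write a pattern file
#'
#' Writes a [DyadReads-class] object in the tab-separated pattern
#' dialect read by [readPatternFile()]. Read -> write -> read is an
#' exact round trip.
#'
#' @param reads a [DyadReads-class] object.
#' @param file output path or connection.
#' @return Invisibly, `file`.
#' @export
writePatternFile <- function(reads, file) {
  stopifnot(is(reads, "DyadReads"))
  df <- reads@reads
  lines <- c(
    paste(READ_COLUMNS, collapse = "\t"),
    if (nrow(df) > 0L) do.call(paste, c(unname(df), sep = "\t"))
  )
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Remove redundant reads by (batchstamp, barcode, locus)
#'
#' The molecule-specific barcode, together with the experiment-specific
#' batchstamp, identifies redundant sequences arising from PCR
#' amplification of the same hairpin molecule. Among reads sharing a
#' (batchstamp, barcode, locus) key, only the first in input order is
#' kept; relative order is preserved. The operation is idempotent.
#'
#' @param reads a [DyadReads-class] object.
#' @return A list with elements `kept` ([DyadReads-class]) and
#'   `nRemoved` (integer).
#' @examples
#' rd <- dyadReads(data.frame(
#'   read_id = c("r1", "r2"), sample_id = "s1", locus = "L1",
#'   batchstamp = "AC12", barcode = "GATTACA", dyads = c("FF", "FU")
#' ))
#' deduplicateReads(rd)$nRemoved
#' @export
deduplicateReads <- function(reads) {
  stopifnot(is(reads, "DyadReads"))
  df <- reads@reads
  if (nrow(df) == 0L) {
    return(list(kept = reads, nRemoved = 0L))
  }
  key <- paste(df$batchstamp, df$barcode, df$locus, sep = "\r")
  keep <- !duplicated(key)
  list(
    kept = dyadReads(df[keep, , drop = FALSE]),
    nRemoved = sum(!keep)
  )
}

#' Tally dyad states across a read set
#'
#' Counts fully methylated (`F`), hemimethylated (`T` and `B`,
#' orientation collapsed), and unmethylated (`U`) dyads over all reads;
#' missing dyads (`.`) contribute to no count.
#'
#' @param reads a [DyadReads-class] object.
#' @return A [DyadCounts-class] with `nReads` set to the number of
#'   reads. Sample and locus labels are taken from the reads when
#'   unique, otherwise the first value is used.
#' @examples
#' rd <- dyadReads(data.frame(
#'   read_id = "r1", sample_id = "s1", locus = "L1",
#'   batchstamp = "b", barcode = "GAT", dyads = "FTU.B"
#' ))
#' countDyads(rd)
#' @export
countDyads <- function(reads) {
  stopifnot(is(reads, "DyadReads"))
  df <- reads@reads
  if (nrow(df) == 0L) {
    return(dyadCounts(0L, 0L, 0L, 0L))
  }
  ch <- strsplit(paste(df$dyads, collapse = ""), "")[[1L]]
  tab <- table(factor(ch, levels = DYAD_STATE_CHARS))
  dyadCounts(
    nFull = tab[["F"]],
    nHemi = tab[["T"]] + tab[["B"]],
    nUnmeth = tab[["U"]],
    nReads = nrow(df),
    sampleId = df$sample_id[[1L]],
    locus = df$locus[[1L]]
  )
}

# Per-read dyad-count matrix (n x 3), the resampling unit of the
# bootstrap and permutation machinery.
.perReadCounts <- function(reads) {
  df <- reads@reads
  n <- nrow(df)
  C <- matrix(0L, n, 3L, dimnames = list(NULL, c("F", "H", "U")))
  if (n == 0L) return(C)
  chars <- strsplit(df$dyads, "")
  lens <- lengths(chars)
  ch <- unlist(chars, use.names = FALSE)
  grp <- rep.int(seq_len(n), lens)
  C[, 1L] <- tabulate2(grp[ch == "F"], n)
  C[, 2L] <- tabulate2(grp[ch == "T" | ch == "B"], n)
  C[, 3L] <- tabulate2(grp[ch == "U"], n)
  C
}

tabulate2 <- function(x, nbins) tabulate(x, nbins = nbins)

COUNT_COLUMNS <- c("sample_id", "locus", "n_full", "n_hemi", "n_unmeth",
                   "n_reads", "failed_rate", "inapprop_rate")

#' Read a dyad-count table
#'
#' Parses a TSV table (header `sample_id locus n_full n_hemi n_unmeth
#' n_reads failed_rate inapprop_rate`) into a list of records, each a
#' list with elements `counts` ([DyadCounts-class]) and `rates`
#' ([ConversionRates-class]). Negative counts or rates outside [0, 1)
#' are validation errors.
#'
#' @param file path to the TSV table, or a connection.
#' @return List of `list(counts = , rates = )` records, in row order.
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!identical(names(df), COUNT_COLUMNS)) {
    stop(sprintf("unexpected count-table header: %s",
                 paste(names(df), collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    num <- suppressWarnings(as.numeric(unlist(row[3:8])))
    if (anyNA(num)) {
      stop(sprintf("non-numeric value in count-table row %d", i))
    }
    if (any(num[1:4] < 0)) {
      stop(sprintf("negative count in count-table row %d", i))
    }
    list(
      counts = dyadCounts(num[[1L]], num[[2L]], num[[3L]], num[[4L]],
                          sampleId = row$sample_id, locus = row$locus),
      rates = conversionRates(failed = num[[5L]],
                              inappropriate = num[[6L]])
    )
  })
}

#' Write a dyad-count table
#'
#' Writes records as read by [readCountTable()]; write -> read
#' reproduces the records exactly (rates are serialized with 17
#' significant digits).
#'
#' @param records list of `list(counts = DyadCounts, rates =
#'   ConversionRates)` records.
#' @param file output path or connection.
#' @return Invisibly, `file`.
#' @export
writeCountTable <- function(records, file) {
  rows <- vapply(records, function(rec) {
    ct <- rec$counts
    rt <- rec$rates
    stopifnot(is(ct, "DyadCounts"), is(rt, "ConversionRates"))
    paste(ct@sampleId, ct@locus, ct@nFull, ct@nHemi, ct@nUnmeth,
          ct@nReads, sprintf("%.17g", rt@failed),
          sprintf("%.17g", rt@inappropriate), sep = "\t")
  }, character(1L))
  writeLines(c(paste(COUNT_COLUMNS, collapse = "\t"), rows), file,
             useBytes = TRUE)
  invisible(file)
}
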