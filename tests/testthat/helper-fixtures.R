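# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A read set of single-dyad reads realizing exact dyad counts, so that
# read-level and dyad-level resampling coincide.
singleDyadReads <- function(nFull, nHemi, nUnmeth, sampleId = "s1",
                            locus = "L1") {
  states <- c(rep("F", nFull), rep("T", nHemi), rep("U", nUnmeth))
  n <- length(states)
  dyadReads(data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    sample_id = sampleId, locus = locus, batchstamp = "bs1",
    barcode = sprintf("GATTACA%04d", seq_len(n)), dyads = states,
    stringsAsFactors = FALSE
  ))
}

# Minimal hand-built read frame.
readFrame <- function(read_id, dyads, sample_id = "s1", locus = "L1",
                      batchstamp = "bs1", barcode = NULL) {
  n <- length(read_id)
  data.frame(
    read_id = read_id, sample_id = rep_len(sample_id, n),
    locus = rep_len(locus, n), batchstamp = rep_len(batchstamp, n),
    barcode = if (is.null(barcode)) sprintf("AGT%05d", seq_len(n))
              else rep_len(barcode, n),
    dyads = dyads, stringsAsFactors = FALSE
  )
}

# Multinomial log-likelihood of counts n at probabilities p, with the
# 0 * log(0) = 0 convention.
multinomLL <- function(n, p) {
  pos <- n > 0
  sum(n[pos] * log(p[pos]))
}
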