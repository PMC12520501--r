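#' Aggregate dyad counts into genomic bins
#'
#' Per-dyad status frequencies are computed only at dyads with resolved
#' coverage `>= minCov` (default 5 reads); bin-level frequencies are, by
#' default, unweighted means of the per-dyad frequencies (methylation
#' frequency is computed at each dyad first, then averaged within the bin).
#' A pooled-count mode is available. Bins whose total methylation falls
#' below `minTotal` (default 2.5%) are flagged `filtered` (retained in the
#' output) because their efficiency estimates are noise-dominated.
#'
#' `p_total = p_full + p_hemi / 2` is the per-cytosine methylation frequency
#' within dyads; since replication hands each daughter duplex one parental
#' strand, it equals the expected hemi-methylation frequency immediately
#' after DNA replication.
#'
#' @param counts Dyad count table ([callDyads()] or
#'   [simulateBinnedDyads()]).
#' @param binSize Bin width in bp (> 0).
#' @param minCov Minimum resolved coverage per dyad.
#' @param minTotal Total-methylation filter threshold.
#' @param pooled If `TRUE`, bin frequencies pool raw counts instead of
#'   averaging per-dyad frequencies.
#' @return `data.table`: `chrom`, `start`, `end`, `context`, `n_dyads`,
#'   `p_full`, `p_hemi`, `p_unme`, `p_total`, `filtered`.
#' @export
aggregateBins <- function(counts, binSize = 1000L, minCov = 5L,
                          minTotal = 0.025, pooled = FALSE) {
  if (binSize <= 0) stop("binSize must be > 0", call. = FALSE)
  ct <- as.data.table(counts)
  ct <- ct[coverage >= minCov]
  if (!nrow(ct)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_dyads = integer(), p_full = numeric(),
                      p_hemi = numeric(), p_unme = numeric(),
                      p_total = numeric(), filtered = logical()))
  }
  ct[, bin := pos %/% as.integer(binSize)]
  if (pooled) {
    out <- ct[, {
      cov <- sum(coverage)
      .(n_dyads = .N,
        p_full = sum(n_full) / cov,
        p_hemi = sum(n_hemi_watson + n_hemi_crick) / cov,
        p_unme = sum(n_unme) / cov)
    }, by = .(chrom, bin, context)]
  } else {
    out <- ct[, .(n_dyads = .N,
                  p_full = mean(n_full / coverage),
                  p_hemi = mean((n_hemi_watson + n_hemi_crick) / coverage),
                  p_unme = mean(n_unme / coverage)),
              by = .(chrom, bin, context)]
  }
  out[, `:=`(start = as.integer(bin * binSize),
             end = as.integer((bin + 1) * binSize))]
  out[, p_total := p_full + p_hemi / 2]
  out[, filtered := p_total < minTotal]
  out[, bin := NULL]
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "n_dyads", "p_full", "p_hemi", "p_unme",
                                 "p_total", "filtered"))
  setorder(out, context, chrom, start)
  out[]
}
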