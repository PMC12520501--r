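#' Simulate chromatin state: H3K9me2 domains and nucleosome positions
#'
#' Splits each chromosome into fixed-width bins and assigns one contiguous
#' heterochromatic block per chromosome (a pericentromere analogue) covering
#' `hetFraction` of its bins; the remaining bins are euchromatic. H3K9me2
#' enrichment is drawn per bin from a low (euchromatic) or high
#' (heterochromatic) log-normal distribution whose defaults straddle the
#' conventional low (<= 0.1) and high (>= 5) classification thresholds.
#' Nucleosome centres are laid down at regular spacing plus uniform jitter.
#'
#' @param genome `DNAStringSet`; the spike-in chromosome (if any) receives no
#'   nucleosomes and is entirely euchromatic with zero enrichment.
#' @param binSize Bin width in bp (> 0).
#' @param hetFraction Fraction of bins per chromosome that are
#'   heterochromatic, in `[0, 1]`.
#' @param spacing Nucleosome repeat length in bp (> 146).
#' @param jitter Maximum absolute uniform jitter (bp) applied to each centre;
#'   `0` gives exactly periodic centres.
#' @param lowMeanlog,lowSdlog Log-normal parameters for euchromatic H3K9me2.
#' @param highMeanlog,highSdlog Log-normal parameters for heterochromatic
#'   H3K9me2.
#' @param seed Integer seed.
#' @return A [ChromatinState-class].
#' @export
simulateChromatin <- function(genome, binSize = 1000L, hetFraction = 0.3,
                              spacing = 180L, jitter = 20L,
                              lowMeanlog = log(0.05), lowSdlog = 0.6,
                              highMeanlog = log(6), highSdlog = 0.4,
                              seed = 1L) {
  if (binSize <= 0) stop("binSize must be > 0", call. = FALSE)
  if (spacing <= 146) stop("nucleosome spacing must exceed 146 bp",
                           call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  .assertProb(hetFraction, "hetFraction")
  spike <- spikeInChrom(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))

  set.seed(derivedSeed(seed, 201L))
  binList <- vector("list", length(lens))
  cenList <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    ch <- names(lens)[i]
    L <- lens[[i]]
    starts <- seq.int(0L, L - 1L, by = binSize)
    ends <- pmin(starts + binSize, L)
    nb <- length(starts)
    region <- rep("euchromatic", nb)
    isSpike <- !is.na(spike) && ch == spike
    if (!isSpike && hetFraction > 0 && nb > 0) {
      nh <- round(hetFraction * nb)
      if (nh > 0) {
        at <- if (nb - nh > 0) sample.int(nb - nh + 1L, 1L) else 1L
        region[seq.int(at, at + nh - 1L)] <- "heterochromatic"
      }
    }
    v <- numeric(nb)
    ne <- sum(region == "euchromatic")
    nh <- nb - ne
    v[region == "euchromatic"] <- stats::rlnorm(ne, lowMeanlog, lowSdlog)
    v[region == "heterochromatic"] <- stats::rlnorm(nh, highMeanlog,
                                                    highSdlog)
    if (isSpike) v[] <- 0
    binList[[i]] <- data.table(chrom = ch, start = starts, end = ends,
                               h3k9me2 = v, region = region)
    if (!isSpike) {
      cen <- seq.int(as.integer(spacing / 2), L - 74L, by = spacing)
      if (jitter > 0 && length(cen)) {
        cen <- cen + sample.int(2L * jitter + 1L, length(cen),
                                replace = TRUE) - jitter - 1L
        cen <- sort(unique(pmax(73L, pmin(cen, L - 74L))))
      }
      cenList[[i]] <- data.table(chrom = ch, center = as.integer(cen))
    }
  }
  new("ChromatinState", bins = rbindlist(binList),
      centers = rbindlist(cenList), binSize = as.integer(binSize))
}
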