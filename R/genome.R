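#' Generate a random genome by weighted base sampling
#'
#' Draws each chromosome as an i.i.d. sequence over A/C/G/T with the given
#' base weights, so expected motif densities follow in closed form from the
#' weights (e.g. the expected number of CG dyads on a chromosome of length L
#' is `(L - 1) * pC * pG`). Optionally appends a fully unmethylated spike-in
#' chromosome (a lambda-phage analogue) used downstream to estimate the
#' bisulfite conversion rate.
#'
#' @param chromLengths Named integer vector of chromosome lengths (bp, each
#'   >= 1000).
#' @param baseWeights Non-negative weights for A, C, G, T (normalised
#'   internally). The default is mildly GC-shifted so that dyad contexts are
#'   reasonably dense.
#' @param spikeIn Either `NULL` (no spike-in) or a length of the spike-in
#'   chromosome, which is named `"spike"`.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @return A [Biostrings::DNAStringSet] with `metadata(x)$spikeIn` holding the
#'   spike-in chromosome name (or `NA`).
#' @examples
#' g <- makeGenome(c(chr1 = 10000), seed = 1)
#' @export
makeGenome <- function(chromLengths, baseWeights = c(A = 0.3, C = 0.22,
                                                     G = 0.22, T = 0.26),
                       spikeIn = NULL, seed = 1L) {
  if (length(chromLengths) == 0L || any(chromLengths < 1000))
    stop("chromosome lengths must be >= 1 kb", call. = FALSE)
  if (length(baseWeights) != 4L || any(!is.finite(baseWeights)) ||
      any(baseWeights < 0) || sum(baseWeights) <= 0)
    stop("baseWeights must be four non-negative weights", call. = FALSE)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  p <- baseWeights / sum(baseWeights)
  set.seed(derivedSeed(seed, 101L))
  seqs <- vapply(chromLengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  spikeName <- NA_character_
  if (!is.null(spikeIn)) {
    stopifnot(spikeIn >= 1000)
    spikeName <- "spike"
    seqs <- c(seqs, spike = paste(
      sample(c("A", "C", "G", "T"), spikeIn, replace = TRUE, prob = p),
      collapse = ""))
  }
  g <- Biostrings::DNAStringSet(seqs)
  S4Vectors::metadata(g)$spikeIn <- spikeName
  g
}

#' Spike-in chromosome name of a genome
#'
#' @param genome A `DNAStringSet` from [makeGenome()] or [readGenomeFasta()].
#' @return The spike-in chromosome name, or `NA` if none.
#' @export
spikeInChrom <- function(genome) {
  s <- S4Vectors::metadata(genome)$spikeIn
  if (is.null(s)) NA_character_ else s
}

#' Read and write genomes as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()]. On reading, a chromosome named `spike` is
#' flagged as the spike-in.
#'
#' @param genome A `DNAStringSet`.
#' @param path File path.
#' @return `readGenomeFasta` returns a `DNAStringSet`; `writeGenomeFasta`
#'   returns `path` invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  S4Vectors::metadata(g)$spikeIn <-
    if ("spike" %in% names(g)) "spike" else NA_character_
  g
}
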