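#' In silico strand annealing: re-pair unlinked strand fragments
#'
#' Watson and Crick fragments sharing identical (chrom, start, end) are
#' paired one-to-one into molecules (before bisulfite conversion the two
#' strands of one duplex align to the same coordinates). Where several
#' same-strand fragments share coordinates, `min(nWatson, nCrick)` pairs are
#' formed and the excess is dropped and tallied. Pairing specificity is
#' assessed by comparing the observed number of same-ends pairs to the
#' number expected under random pairing, estimated by permuting fragment end
#' coordinates within each chromosome.
#'
#' @param fragments `data.table` with `fragment_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param calls Optional per-fragment call table (`fragment_id`, `chrom`,
#'   `pos`, `strand`, `state`); if given, calls of paired fragments are
#'   relabelled with the new `molecule_id` so the result feeds
#'   [callDyads()].
#' @param nPerm Number of end-coordinate permutations for the random-pairing
#'   estimate.
#' @param seed Integer seed for the permutations.
#' @return List with `molecules` (`molecule_id`, `chrom`, `start`, `end`,
#'   `w_fragment`, `c_fragment`), `calls` (relabelled, or `NULL`),
#'   `nPairs`, `nDropped`, `expectedRandom` (mean same-ends pairs across
#'   permutations) and `enrichment` (observed / expected; `Inf` when no
#'   random pair was ever observed).
#' @export
isaPair <- function(fragments, calls = NULL, nPerm = 10L, seed = 1L) {
  fr <- as.data.table(fragments)
  stopifnot(all(c("fragment_id", "chrom", "start", "end", "strand")
                %in% names(fr)))
  w <- fr[strand == "+"][order(chrom, start, end, fragment_id)]
  c_ <- fr[strand == "-"][order(chrom, start, end, fragment_id)]
  w[, keyid := seq_len(.N), by = .(chrom, start, end)]
  c_[, keyid := seq_len(.N), by = .(chrom, start, end)]
  pairs <- w[c_, on = c("chrom", "start", "end", "keyid"), nomatch = NULL,
             .(chrom, start, end, w_fragment = fragment_id,
               c_fragment = i.fragment_id)]
  nPairs <- nrow(pairs)
  nDropped <- nrow(fr) - 2L * nPairs
  if (nPairs == 0L) {
    warning("no pairable fragments")
    mol <- data.table(molecule_id = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      w_fragment = integer(), c_fragment = integer())
  } else {
    mol <- pairs[, .(molecule_id = seq_len(.N), chrom, start, end,
                     w_fragment, c_fragment)]
  }

  # random-pairing expectation: shuffle end coordinates within chromosome
  set.seed(derivedSeed(seed, 601L))
  permCounts <- vapply(seq_len(max(1L, nPerm)), function(i) {
    p <- copy(fr)
    p[, end := sample(end), by = chrom]
    pw <- p[strand == "+", .N, by = .(chrom, start, end)]
    pc <- p[strand == "-", .N, by = .(chrom, start, end)]
    m <- pw[pc, on = c("chrom", "start", "end"), nomatch = NULL]
    sum(pmin(m$N, m$i.N))
  }, numeric(1))
  expectedRandom <- mean(permCounts)
  enrichment <- if (expectedRandom > 0) nPairs / expectedRandom else
    if (nPairs > 0) Inf else NA_real_

  outCalls <- NULL
  if (!is.null(calls) && nPairs > 0L) {
    cl <- as.data.table(calls)
    map <- rbindlist(list(
      mol[, .(fragment_id = w_fragment, molecule_id)],
      mol[, .(fragment_id = c_fragment, molecule_id)]
    ))
    cl[map, molecule_id := i.molecule_id, on = "fragment_id"]
    outCalls <- cl[!is.na(molecule_id),
                   .(molecule_id, chrom, pos, strand, state)]
    setorder(outCalls, molecule_id, chrom, pos)
  }
  list(molecules = mol, calls = outCalls, nPairs = nPairs,
       nDropped = nDropped, expectedRandom = expectedRandom,
       enrichment = enrichment)
}
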