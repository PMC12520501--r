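#' Emit an observed per-molecule cytosine call table
#'
#' Applies the bisulfite observation model to the true states of a simulated
#' population: an unmethylated cytosine reads methylated with probability
#' `1 - conversionRate` (conversion failure), a methylated cytosine reads
#' unmethylated with probability `overconversionRate`, and any call is
#' missing with probability `missRate`. Only in-fragment positions are
#' emitted. Spike-in cytosines are truly unmethylated by construction, so
#' their apparent methylation estimates the conversion failure rate.
#'
#' @param ms A [MoleculeSet-class].
#' @param obs An [ObservationParams-class].
#' @return `data.table` with columns `molecule_id`, `chrom`, `pos` (0-based),
#'   `strand` (`+`/`-`), `state` (`M`, `U` or `.` for missing), sorted by
#'   molecule and position. Byte-identical across reruns for a fixed seed.
#' @export
emitCallTable <- function(ms, obs) {
  st <- copy(ms@states)
  mol <- ms@molecules
  st[mol, `:=`(fs = i.start, fe = i.end), on = "molecule_id"]
  st <- st[pos >= fs & pos < fe]
  set.seed(derivedSeed(obs@seed, 401L))
  n <- nrow(st)
  uMiss <- runif(n); uFlip <- runif(n)
  st[, state := fifelse(meth, fifelse(uFlip < obs@overconversionRate,
                                      "U", "M"),
                        fifelse(uFlip < 1 - obs@conversionRate, "M", "U"))]
  st[uMiss < obs@missRate, state := "."]
  out <- st[, .(molecule_id, chrom, pos, strand, state)]
  setorder(out, molecule_id, chrom, pos, strand)
  out[]
}

#' Emit unlinked single-strand fragments (a WGBS analogue)
#'
#' Splits every molecule of a simulated population into its two strand
#' reads, which share (chrom, start, end) but carry no molecule linkage —
#' the situation in silico strand annealing ([isaPair()]) must undo. Record
#' order is randomised.
#'
#' @param ms A [MoleculeSet-class].
#' @param obs An [ObservationParams-class].
#' @return List with `fragments` (`data.table`: `fragment_id`, `chrom`,
#'   `start`, `end`, `strand`) and `calls` (the call table of
#'   [emitCallTable()] with `molecule_id` replaced by `fragment_id`, each
#'   strand's calls attached to its own fragment).
#' @export
emitUnlinkedFragments <- function(ms, obs) {
  calls <- emitCallTable(ms, obs)
  mol <- ms@molecules
  frags <- rbindlist(list(
    mol[, .(molecule_id, chrom, start, end, strand = "+")],
    mol[, .(molecule_id, chrom, start, end, strand = "-")]
  ))
  set.seed(derivedSeed(obs@seed, 402L))
  frags <- frags[sample.int(.N)]
  frags[, fragment_id := .I]
  calls[frags, fragment_id := i.fragment_id,
        on = c("molecule_id", "chrom", "strand")]
  calls <- calls[!is.na(fragment_id),
                 .(fragment_id, chrom, pos, strand, state)]
  list(fragments = frags[, .(fragment_id, chrom, start, end, strand)],
       calls = calls[])
}
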