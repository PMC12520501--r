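.motifStarts <- function(subject, motif) {
  # fixed-pattern scan; returns 0-based start positions
  Biostrings::start(Biostrings::matchPattern(motif, subject,
                                             fixed = TRUE)) - 1L
}

#' Find symmetric cytosine dyads and CSG sites in a genome
#'
#' Scans the Watson strand of every chromosome for the four dyad-forming
#' contexts. By palindromy of the defining motifs, Watson-strand scanning
#' enumerates each CG (`CG`), CWG (`C[AT]G`) and CWWG (`C[AT][AT]G`) dyad
#' exactly once. CCG is not palindromic as a CHG context (its reverse
#' complement CGG nests a CG, not a CHG), so Watson `CCG` and Watson `CGG`
#' occurrences are reported separately with strand roles swapped; both yield a
#' CCG-context dyad (the C1 cytosine and its strand-symmetric partner) and a
#' CSG record naming the three cytosines C1, C2 and C3.
#'
#' All coordinates are 0-based. Every dyad has exactly one Watson-strand
#' cytosine (`w_pos`) and one Crick-strand cytosine (`c_pos`); `pos` (the
#' binning key) is always `w_pos`.
#'
#' @param genome A `DNAStringSet` over A/C/G/T.
#' @param ctagOnly If `TRUE`, restrict CWWG dyads to the palindromic CTAG
#'   subcontext.
#' @return A list with elements `dyads` (`data.table`: `dyad_id`, `chrom`,
#'   `pos`, `w_pos`, `c_pos`, `context`, `c1_strand` — the strand carrying
#'   the CHG-context C1 cytosine, `NA` outside CCG) and `csg` (`data.table`:
#'   `csg_id`, `chrom`, `orient`, and position/strand of C1, C2, C3).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "ACCGT"))
#' findDyads(g)
#' @export
findDyads <- function(genome, ctagOnly = FALSE) {
  if (any(Biostrings::alphabetFrequency(genome, baseOnly = TRUE)[, "other"]
          > 0))
    stop("genome contains non-ACGT characters", call. = FALSE)
  cwwg <- if (ctagOnly) "CTAG" else c("CAAG", "CATG", "CTAG", "CTTG")
  dyadL <- list(); csgL <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    cg <- .motifStarts(s, "CG")
    cwg <- sort(c(.motifStarts(s, "CAG"), .motifStarts(s, "CTG")))
    cww <- sort(unlist(lapply(cwwg, .motifStarts, subject = s),
                       use.names = FALSE))
    ccg <- .motifStarts(s, "CCG")   # C1 on Watson
    cgg <- .motifStarts(s, "CGG")   # C1 on Crick (mirrored)
    dyadL[[ch]] <- rbindlist(list(
      data.table(chrom = ch, w_pos = cg, c_pos = cg + 1L, context = "CG",
                 c1_strand = NA_character_),
      data.table(chrom = ch, w_pos = cwg, c_pos = cwg + 2L, context = "CWG",
                 c1_strand = NA_character_),
      data.table(chrom = ch, w_pos = cww, c_pos = cww + 3L,
                 context = "CWWG", c1_strand = NA_character_),
      data.table(chrom = ch, w_pos = ccg, c_pos = ccg + 2L, context = "CCG",
                 c1_strand = "+"),
      data.table(chrom = ch, w_pos = cgg, c_pos = cgg + 2L, context = "CCG",
                 c1_strand = "-")
    ))
    csgL[[ch]] <- rbindlist(list(
      data.table(chrom = ch, orient = "+",
                 c1_pos = ccg, c1_strand = "+",
                 c2_pos = ccg + 1L, c2_strand = "+",
                 c3_pos = ccg + 2L, c3_strand = "-"),
      data.table(chrom = ch, orient = "-",
                 c1_pos = cgg + 2L, c1_strand = "-",
                 c2_pos = cgg + 1L, c2_strand = "-",
                 c3_pos = cgg, c3_strand = "+")
    ))
  }
  dyads <- rbindlist(dyadL)
  setorder(dyads, chrom, w_pos, context)
  dyads[, dyad_id := .I]
  dyads[, pos := w_pos]
  data.table::setcolorder(dyads, c("dyad_id", "chrom", "pos", "w_pos",
                                   "c_pos", "context", "c1_strand"))
  csg <- rbindlist(csgL)
  setorder(csg, chrom, c2_pos)
  csg[, csg_id := .I]
  data.table::setcolorder(csg, "csg_id")
  list(dyads = dyads[], csg = csg[])
}

#' Count CSG occurrences within an interval
#'
#' Counts trinucleotide matches to CCG or CGG on the Watson strand within a
#' 0-based half-open interval (equivalently, CCG occurrences on either
#' strand). Overlapping matches count individually.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return Integer count.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "CCGG"))
#' countCsg(g, "chr", 0, 4)  # CCG at 0 and CGG at 1
#' @export
countCsg <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome", call. = FALSE)
  L <- Biostrings::width(genome[chrom])
  if (start < 0 || end > L || start >= end)
    stop("interval out of bounds", call. = FALSE)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  length(.motifStarts(s, "CCG")) + length(.motifStarts(s, "CGG"))
}
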