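#' Strand-concordance spectrum of proximal dyads
#'
#' For every hemi-methylated focal dyad on a molecule, classifies the
#' nearest resolved dyad of the neighbour context on the same molecule
#' (excluding the focal site itself, within `maxDist` bp): `hemi_same` if it
#' is hemi-methylated with 5mC on the same strand as the focal 5mC,
#' `hemi_oppo` if on the opposite strand, otherwise `full` or `unme`. Under
#' replication-generated hemi-methylation, 5mC of maintenance-failure hemi
#' dyads sits on the template strand, so neighbouring hemi dyads are
#' strand-concordant; de novo events break the concordance.
#'
#' @param molCalls Per-molecule dyad calls (`calls` element of
#'   [callDyads()]).
#' @param focalContext Context of the hemi focal dyads.
#' @param neighborContext Context of the classified neighbours.
#' @param maxDist Maximum focal-neighbour distance in bp (default
#'   unlimited; hpBS molecules are short anyway).
#' @param tie Nearest-neighbour ties (equidistant left/right) take the
#'   leftmost (`"left"`, default) or rightmost neighbour.
#' @return List with `spectrum` (named frequencies over `hemi_same`,
#'   `hemi_oppo`, `full`, `unme`, summing to 1) and `nPairs`.
#' @export
proximalStatus <- function(molCalls, focalContext, neighborContext,
                           maxDist = Inf, tie = c("left", "right")) {
  tie <- match.arg(tie)
  mc <- as.data.table(molCalls)[status != "unresolved"]
  foc <- mc[context == focalContext &
              status %in% c("hemi_watson", "hemi_crick")]
  nb <- mc[context == neighborContext]
  cats <- c("hemi_same", "hemi_oppo", "full", "unme")
  if (!nrow(foc) || !nrow(nb)) {
    warning("no qualifying focal/neighbour dyads")
    return(list(spectrum = setNames(rep(NA_real_, 4), cats), nPairs = 0L))
  }
  setkey(nb, molecule_id)
  setorder(nb, molecule_id, pos)
  nbl <- split(nb[, .(dyad_id, pos, status)], nb$molecule_id)
  res <- foc[, {
    v <- nbl[[as.character(molecule_id[1])]]
    fd <- dyad_id; fp <- pos; fst <- status
    if (is.null(v) || !nrow(v)) list(cls = character(0)) else {
      vd <- v$dyad_id; vp <- v$pos; vs <- v$status
      cls <- rep(NA_character_, .N)
      for (k in seq_len(.N)) {
        keep <- which(vd != fd[k] & abs(vp - fp[k]) <= maxDist)
        if (!length(keep)) next
        dist <- abs(vp[keep] - fp[k])
        sel <- keep[dist == min(dist)]
        j <- if (tie == "left") sel[which.min(vp[sel])] else
          sel[which.max(vp[sel])]
        st <- vs[j]
        cls[k] <- if (st %in% c("hemi_watson", "hemi_crick")) {
          if (st == fst[k]) "hemi_same" else "hemi_oppo"
        } else st
      }
      list(cls = cls)
    }
  }, by = molecule_id]$cls
  res <- res[!is.na(res)]
  n <- length(res)
  spec <- setNames(as.numeric(table(factor(res, levels = cats))) /
                     max(n, 1L), cats)
  if (n == 0L) warning("no qualifying proximal pairs")
  list(spectrum = spec, nPairs = n)
}

#' Extract CSG triplets resolved on single molecules
#'
#' A CSG site nests a CG dyad inside a CCG/CGG trinucleotide: two
#' consecutive cytosines on one strand (C1 in CHG context, C2 the
#' same-strand CG cytosine) and a third (C3) on the other strand completing
#' the CG dyad. One triplet is emitted per (molecule, site) with all three
#' states resolved; mirrored (Watson CGG) sites are handled with strand
#' roles swapped so C1 is always the CHG-context cytosine.
#'
#' @param calls Call table (`molecule_id`, `chrom`, `pos`, `strand`,
#'   `state`).
#' @param csgSites `csg` table from [findDyads()].
#' @return `data.table`: `molecule_id`, `csg_id`, `s1`, `s2`, `s3`
#'   (`"M"`/`"U"`).
#' @export
csgTriplets <- function(calls, csgSites) {
  calls <- .checkCallTable(calls)[state %in% c("M", "U")]
  cs <- as.data.table(csgSites)
  grab <- function(pcol, scol, out) {
    x <- cs[, .(csg_id, chrom, pos = get(pcol), strand = get(scol))]
    calls[x, on = c("chrom", "pos", "strand"), nomatch = NULL,
          allow.cartesian = TRUE,
          .(molecule_id, csg_id = i.csg_id, st = state)] |>
      setnames("st", out)
  }
  t1 <- grab("c1_pos", "c1_strand", "s1")
  t2 <- grab("c2_pos", "c2_strand", "s2")
  t3 <- grab("c3_pos", "c3_strand", "s3")
  out <- t1[t2, on = c("molecule_id", "csg_id"), nomatch = NULL][
    t3, on = c("molecule_id", "csg_id"), nomatch = NULL]
  setorder(out, molecule_id, csg_id)
  out[, .(molecule_id, csg_id, s1, s2, s3)]
}

#' Conditional Pearson correlations among CSG cytosines
#'
#' For each conditioning cytosine and state (C1 = U/M, C2 = U/M, C3 = U/M),
#' subsets the triplets accordingly and computes the Pearson correlation of
#' the remaining two binary methylation vectors (M = 1, U = 0). A
#' correlation is undefined (NA) when either vector is constant or the
#' subset is smaller than `minN`.
#'
#' @param triplets Output of [csgTriplets()].
#' @param minN Minimum subset size for a defined correlation.
#' @return `data.table`: `pair`, `cond`, `cond_state`, `r`, `n`.
#' @export
conditionalPearson <- function(triplets, minN = 30L) {
  tr <- as.data.table(triplets)
  stopifnot(nrow(tr) > 0)
  m <- cbind(c1 = as.numeric(tr$s1 == "M"), c2 = as.numeric(tr$s2 == "M"),
             c3 = as.numeric(tr$s3 == "M"))
  combos <- data.table(
    pair = rep(c("C2-C3", "C1-C3", "C1-C2"), each = 2),
    cond = rep(c("C1", "C2", "C3"), each = 2),
    cond_state = rep(c("U", "M"), 3))
  idx <- list(`C1` = 1L, `C2` = 2L, `C3` = 3L)
  out <- combos[, {
    ci <- idx[[cond]]
    keep <- m[, ci] == (cond_state == "M")
    ab <- m[keep, -ci, drop = FALSE]
    n <- nrow(ab)
    r <- if (n >= minN && stats::sd(ab[, 1]) > 0 && stats::sd(ab[, 2]) > 0)
      cor(ab[, 1], ab[, 2]) else NA_real_
    .(r = r, n = n)
  }, by = .(pair, cond, cond_state)]
  out[]
}
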