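#' Pair per-strand cytosine calls into per-molecule dyad statuses
#'
#' For every molecule covering both cytosines of a dyad site, the pair of
#' observed states determines the dyad status: (M,M) full, (M,U)
#' hemi_watson, (U,M) hemi_crick, (U,U) unme (states given as
#' Watson, Crick). A dyad with either member missing (state `.` or not
#' covered) is `unresolved` and excluded from counts. Conflicting duplicate
#' calls at one cytosine of one molecule are treated as missing; calls at
#' positions that are not dyad-member cytosines are ignored and tallied.
#'
#' @param calls Call table (`molecule_id`, `chrom`, `pos`, `strand`,
#'   `state`), as emitted by [emitCallTable()] or read with
#'   [readCallTable()].
#' @param sites Dyad site list from [findDyads()], or its `dyads` table.
#' @return List with `calls` (`data.table` of per-molecule dyad calls:
#'   `molecule_id`, `dyad_id`, `chrom`, `pos`, `context`, `w_state`,
#'   `c_state`, `status`), `counts` (per-site tallies: `chrom`, `pos`,
#'   `c_pos`, `context`, `n_full`, `n_hemi_watson`, `n_hemi_crick`,
#'   `n_unme`, `coverage`) and `nIgnored` (calls at non-dyad positions).
#' @export
callDyads <- function(calls, sites) {
  calls <- .checkCallTable(calls)
  dy <- if (is.list(sites) && !is.data.frame(sites)) sites$dyads else
    as.data.table(sites)

  # collapse duplicate calls per cytosine per molecule; conflicts -> missing
  kc <- c("molecule_id", "chrom", "pos", "strand")
  isdup <- duplicated(calls, by = kc) |
    duplicated(calls, by = kc, fromLast = TRUE)
  if (any(isdup)) {
    dd <- calls[isdup,
      .(state = if (data.table::uniqueN(state) == 1L) state[1L] else "."),
      by = kc]
    calls <- rbindlist(list(calls[!isdup, c(kc, "state"), with = FALSE],
                            dd))
  }

  members <- unique(rbindlist(list(
    dy[, .(chrom, pos = w_pos, strand = "+")],
    dy[, .(chrom, pos = c_pos, strand = "-")]
  )))
  nIgnored <- nrow(calls) -
    nrow(calls[members, on = c("chrom", "pos", "strand"), nomatch = NULL])

  wcalls <- calls[strand == "+"]
  ccalls <- calls[strand == "-"]
  mc <- wcalls[dy, on = c(chrom = "chrom", pos = "w_pos"), nomatch = NULL,
               allow.cartesian = TRUE,
               .(molecule_id, dyad_id = i.dyad_id, chrom, pos,
                 c_pos = i.c_pos, context = i.context, w_state = state)]
  mc[ccalls, c_state := i.state,
     on = c("molecule_id", "chrom", c_pos = "pos")]
  # molecules seen only at the Crick member: count them as unresolved too
  onlyC <- ccalls[dy, on = c(chrom = "chrom", pos = "c_pos"),
                  nomatch = NULL, allow.cartesian = TRUE,
                  .(molecule_id, dyad_id = i.dyad_id, chrom,
                    pos = i.w_pos, c_pos = pos, context = i.context,
                    c_state = state)]
  onlyC <- onlyC[!mc, on = c("molecule_id", "dyad_id")]
  onlyC[, w_state := "."]
  mc <- rbindlist(list(mc, onlyC), use.names = TRUE)
  mc[is.na(w_state), w_state := "."]
  mc[is.na(c_state), c_state := "."]
  mc[, status := fifelse(w_state == "." | c_state == ".", "unresolved",
               fifelse(w_state == "M" & c_state == "M", "full",
               fifelse(w_state == "M", "hemi_watson",
               fifelse(c_state == "M", "hemi_crick", "unme"))))]
  setorder(mc, chrom, pos, molecule_id)

  res <- mc[status != "unresolved"]
  counts <- res[, .(n_full = sum(status == "full"),
                    n_hemi_watson = sum(status == "hemi_watson"),
                    n_hemi_crick = sum(status == "hemi_crick"),
                    n_unme = sum(status == "unme")),
                by = .(dyad_id, chrom, pos, c_pos, context)]
  counts[, coverage := n_full + n_hemi_watson + n_hemi_crick + n_unme]
  counts[, dyad_id := NULL]
  setorder(counts, chrom, pos)
  list(calls = mc[, .(molecule_id, dyad_id, chrom, pos, context,
                      w_state, c_state, status)],
       counts = counts[], nIgnored = nIgnored)
}

#' Estimate the bisulfite conversion rate from spike-in calls
#'
#' The conversion rate is the fraction of converted (unmethylated-reading)
#' calls among all non-missing cytosine calls on the spike-in chromosome,
#' whose cytosines are truly unmethylated.
#'
#' @param calls Call table.
#' @param spikeChrom Spike-in chromosome name.
#' @return Estimated rate in `[0, 1]`.
#' @export
conversionRate <- function(calls, spikeChrom) {
  calls <- .checkCallTable(calls)
  sp <- calls[chrom == spikeChrom & state != "."]
  if (!nrow(sp))
    stop("no spike-in cytosine calls; conversion rate undefined",
         call. = FALSE)
  sp[, mean(state == "U")]
}
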