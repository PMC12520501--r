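#' Bin a bedGraph-style enrichment track, with optional input blacklisting
#'
#' Computes, per fixed-width bin, the coverage-length-weighted mean of the
#' record values (over covered bases only; `covered` records the covered
#' width). When a control (`input`) track is supplied, bins whose input
#' value exceeds twice the genome-wide mean of input bin values are
#' blacklisted; blacklisted bins are excluded from all downstream
#' statistics.
#'
#' @param records bedGraph records as a `data.table`/`data.frame` with
#'   `chrom`, `start`, `end` (0-based half-open), `value`, or a `GRanges`
#'   with a `score` column (as returned by [readBedGraph()]). Records must
#'   not overlap.
#' @param binSize Bin width in bp.
#' @param chromSizes Named vector of chromosome lengths.
#' @param input Optional control track in the same format, used for
#'   blacklisting.
#' @return `data.table`: `chrom`, `start`, `end`, `value`, `covered`,
#'   `blacklisted`.
#' @export
binTrack <- function(records, binSize = 1000L, chromSizes, input = NULL) {
  rec <- .asBedGraphDT(records)
  if (any(rec$start < 0) ||
      any(rec$end > chromSizes[rec$chrom]))
    stop("records outside chromosome bounds", call. = FALSE)
  setorder(rec, chrom, start)
  if (rec[, any(start[-1] < end[-.N]), by = chrom][, any(V1)])
    stop("overlapping bedGraph records", call. = FALSE)
  base <- .binnedMeans(rec, binSize, chromSizes)
  base[, blacklisted := FALSE]
  if (!is.null(input)) {
    inp <- .binnedMeans(.asBedGraphDT(input), binSize, chromSizes)
    thr <- 2 * mean(inp$value[inp$covered > 0])
    bl <- inp[covered > 0 & value > thr, .(chrom, start)]
    base[bl, blacklisted := TRUE, on = c("chrom", "start")]
  }
  base[]
}

.asBedGraphDT <- function(x) {
  if (methods::is(x, "GRanges")) {
    data.table(chrom = as.character(GenomicRanges::seqnames(x)),
               start = GenomicRanges::start(x) - 1L,
               end = GenomicRanges::end(x),
               value = S4Vectors::mcols(x)$score)
  } else {
    dt <- as.data.table(x)
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(dt)))
    dt[, .(chrom, start, end, value)]
  }
}

# split records across bin boundaries and average per bin
.binnedMeans <- function(rec, binSize, chromSizes) {
  binSize <- as.integer(binSize)
  rec <- copy(rec)
  rec[, `:=`(b0 = start %/% binSize, b1 = (end - 1L) %/% binSize)]
  idx <- rep(seq_len(nrow(rec)), rec$b1 - rec$b0 + 1L)
  ex <- rec[idx]
  ex[, bin := data.table::rowid(idx) - 1L + b0]
  ex[, `:=`(os = pmax(start, bin * binSize),
            oe = pmin(end, (bin + 1L) * binSize))]
  agg <- ex[, .(value = sum(value * (oe - os)) / sum(oe - os),
                covered = sum(oe - os)), by = .(chrom, bin)]
  grid <- rbindlist(lapply(names(chromSizes), function(ch) {
    nb <- ceiling(chromSizes[[ch]] / binSize)
    data.table(chrom = ch, bin = seq_len(nb) - 1L)
  }))
  out <- agg[grid, on = c("chrom", "bin")]
  out[is.na(value), `:=`(value = 0, covered = 0L)]
  out[, `:=`(start = as.integer(bin * binSize),
             end = as.integer(pmin((bin + 1) * binSize,
                                   chromSizes[chrom])))]
  out[, bin := NULL]
  data.table::setcolorder(out, c("chrom", "start", "end", "value",
                                 "covered"))
  setorder(out, chrom, start)
  out
}

#' Classify bins by mark enrichment into low/high regions
#'
#' For H3K9me2 the conventional thresholds are low `<= 0.1` and high `>= 5`;
#' for other marks high is `>= 2` and low is its complement (`< 2`).
#' Blacklisted bins are labelled `neither`.
#'
#' @param track Binned track from [binTrack()].
#' @param mark Mark name (`"H3K9me2"` selects the two-threshold rule).
#' @param lowThr,highThr Optional threshold overrides (`lowThr < highThr`).
#' @return The track with an added `label` column
#'   (`"low"`/`"high"`/`"neither"`).
#' @export
classifyRegions <- function(track, mark = "H3K9me2", lowThr = NULL,
                            highThr = NULL) {
  tr <- copy(as.data.table(track))
  if (is.null(highThr)) highThr <- if (identical(mark, "H3K9me2")) 5 else 2
  if (is.null(lowThr))
    lowThr <- if (identical(mark, "H3K9me2")) 0.1 else NA_real_
  if (!is.na(lowThr) && lowThr >= highThr)
    stop("lowThr must be < highThr", call. = FALSE)
  tr[, label := if (is.na(lowThr)) fifelse(value >= highThr, "high", "low")
     else fifelse(value >= highThr, "high",
          fifelse(value <= lowThr, "low", "neither"))]
  if ("blacklisted" %in% names(tr)) tr[blacklisted == TRUE,
                                       label := "neither"]
  tr[]
}

#' Read and write bedGraph / BED files
#'
#' Wrappers over [rtracklayer::import()]/[rtracklayer::export()].
#' `readBedCenters()` reads a BED of nucleosome centres (point or interval
#' features; intervals are collapsed to their midpoints) into the
#' `data.table` layout used by the profile functions.
#'
#' @param path File path.
#' @param x For `writeBedGraph`, a `data.table` with `chrom`, `start`,
#'   `end`, `value`.
#' @return `readBedGraph` returns a `GRanges`; `readBedCenters` a
#'   `data.table` with `chrom`, `center`.
#' @export
readBedGraph <- function(path) rtracklayer::import(path, format = "bedGraph")

#' @rdname readBedGraph
#' @export
writeBedGraph <- function(x, path) {
  dt <- as.data.table(x)
  gr <- GenomicRanges::GRanges(dt$chrom,
          IRanges::IRanges(dt$start + 1L, dt$end), score = dt$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname readBedGraph
#' @export
readBedCenters <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   center = as.integer(floor(
                     (GenomicRanges::start(gr) - 1 +
                        GenomicRanges::end(gr)) / 2)))
  setorder(dt, chrom, center)
  unique(dt)
}
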