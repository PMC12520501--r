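#' Average a positional signal around nucleosome centres
#'
#' For each offset cell in `[-window, +window]` (cells of width `step`,
#' labelled by their centre offset), averages the signal over all
#' (centre, position) combinations with data at that offset. Used for
#' methylation frequencies (per-dyad values at their Watson anchor),
#' occupancy, or any per-position value.
#'
#' @param values `data.table` with `chrom`, `pos`, `value` (one row per
#'   position carrying signal).
#' @param centers `data.table` with `chrom`, `center` (see
#'   [nucleosomeCenters()] / [readBedCenters()]).
#' @param window Half-window in bp (> 0).
#' @param step Offset cell width in bp (<= window).
#' @param normalize If `TRUE`, divide by the maximum so the highest cell
#'   is 1.
#' @return `data.table`: `offset`, `value`, `n` (contributing
#'   observations).
#' @export
centerProfile <- function(values, centers, window = 1000L, step = 10L,
                          normalize = FALSE) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (step <= 0 || step > window)
    stop("step must be in (0, window]", call. = FALSE)
  vals <- as.data.table(values)
  cen <- as.data.table(centers)
  if (!nrow(cen)) {
    warning("no centers")
    return(data.table(offset = integer(), value = numeric(),
                      n = integer()))
  }
  half <- as.integer(step) %/% 2L
  cen2 <- cen[, .(chrom, center, lo = center - as.integer(window) - half,
                  hi = center + as.integer(window) + half)]
  hits <- vals[cen2, on = .(chrom, pos >= lo, pos <= hi),
               allow.cartesian = TRUE, nomatch = NULL,
               .(center = i.center, p = x.pos, value = x.value)]
  if (!nrow(hits)) {
    warning("no signal within window of any center")
    return(data.table(offset = integer(), value = numeric(),
                      n = integer()))
  }
  hits[, offset := as.integer(round((p - center) / step) * step)]
  out <- hits[abs(offset) <= window,
              .(value = mean(value), n = .N), by = offset]
  setorder(out, offset)
  if (normalize && nrow(out) && max(out$value) > 0)
    out[, value := value / max(value)]
  out[]
}

#' Mean nucleosome-occupancy profile around centres
#'
#' Occupancy at a position is the indicator of lying within `halfWidth` bp
#' of any centre (147-bp particle footprint by default); the profile
#' averages this indicator across all centres per offset cell.
#'
#' @inheritParams centerProfile
#' @param halfWidth Half the nucleosome footprint in bp.
#' @return `data.table`: `offset`, `value`, `n`.
#' @export
occupancyProfile <- function(centers, window = 1000L, step = 10L,
                             halfWidth = 73L, normalize = FALSE) {
  cen <- as.data.table(centers)
  offs <- seq.int(-as.integer(window), as.integer(window),
                  by = as.integer(step))
  res <- rbindlist(lapply(split(cen, cen$chrom), function(cc) {
    cc <- cc[order(center)]
    pos <- as.vector(outer(cc$center, offs, `+`))
    j <- findInterval(pos, cc$center)
    dl <- abs(pos - cc$center[pmax(j, 1L)])
    dr <- abs(cc$center[pmin(j + 1L, nrow(cc))] - pos)
    occ <- pmin(dl, dr) <= halfWidth
    data.table(offset = rep(offs, each = nrow(cc)), occ = occ)
  }))
  out <- res[, .(value = mean(occ), n = .N), by = offset]
  setorder(out, offset)
  if (normalize && max(out$value) > 0) out[, value := value / max(value)]
  out[]
}

#' Full/hemi ratio profile and its correlation with occupancy
#'
#' Divides the full-methylation profile by the hemi-methylation profile per
#' offset (undefined where hemi is 0) and computes the Pearson correlation
#' across offsets between the ratio and the occupancy profile. A negative
#' correlation indicates that nucleosomes impede the conversion of hemi- to
#' full-methylation.
#'
#' @param fullProfile,hemiProfile,occupancy Profiles sharing the `offset`
#'   grid (`data.table` with `offset`, `value`).
#' @return List with `ratio` (`data.table`: `offset`, `ratio`) and `r`
#'   (Pearson correlation; NA with fewer than 3 defined offsets or a
#'   constant vector).
#' @export
ratioAndCorrelation <- function(fullProfile, hemiProfile, occupancy) {
  f <- as.data.table(fullProfile); h <- as.data.table(hemiProfile)
  o <- as.data.table(occupancy)
  m <- f[h, on = "offset", nomatch = NULL,
         .(offset, ratio = fifelse(i.value > 0, value / i.value,
                                   NA_real_))]
  m <- m[o, on = "offset", nomatch = NULL,
         .(offset, ratio, occ = i.value)]
  ok <- m[!is.na(ratio)]
  r <- if (nrow(ok) >= 3 && stats::sd(ok$ratio) > 0 &&
           stats::sd(ok$occ) > 0) cor(ok$ratio, ok$occ) else NA_real_
  list(ratio = m[, .(offset, ratio)], r = r)
}

#' Pearson correlation between two profiles across offsets
#'
#' @param p1,p2 Profiles (`data.table` with `offset`, `value`).
#' @return Pearson r, or NA with fewer than 3 shared offsets or a constant
#'   vector.
#' @export
profileCorrelation <- function(p1, p2) {
  m <- as.data.table(p1)[as.data.table(p2), on = "offset",
                         nomatch = NULL, .(a = value, b = i.value)]
  m <- m[!is.na(a) & !is.na(b)]
  if (nrow(m) < 3 || stats::sd(m$a) == 0 || stats::sd(m$b) == 0)
    return(NA_real_)
  cor(m$a, m$b)
}

#' Dyad sequence-context density around nucleosome centres
#'
#' Counts dyad anchors per offset cell across centres, normalised to mean 1
#' over the window, per context.
#'
#' @param genome `DNAStringSet`.
#' @param centers Centres table.
#' @param window,step As in [centerProfile()].
#' @param contexts Contexts to profile.
#' @return `data.table`: `context`, `offset`, `value` (relative density),
#'   `n` (raw anchor count).
#' @export
contextDensity <- function(genome, centers, window = 1000L, step = 10L,
                           contexts = c("CG", "CWG", "CWWG")) {
  if (step > window) stop("step must be <= window", call. = FALSE)
  dy <- findDyads(genome)$dyads
  cen <- as.data.table(centers)
  grid <- data.table(offset = seq.int(-as.integer(window),
                                      as.integer(window),
                                      by = as.integer(step)))
  out <- lapply(contexts, function(ctx) {
    anch <- dy[context == ctx, .(chrom, pos, value = 1)]
    pr <- centerProfile(anch, cen, window = window, step = step)
    # centerProfile reports mean(1) = 1 per covered cell; the density is
    # the anchor count per cell, with zero-anchor cells filled in
    pr <- pr[grid, on = "offset"]
    pr[is.na(n), n := 0L]
    pr[, .(context = ctx, offset, n = n, value = n / mean(n))]
  })
  rbindlist(out)
}

#' Mark-stratified profile correlations
#'
#' Splits nucleosome centres by the low/high label of their containing bin
#' and computes, per stratum, the correlation between the full/hemi ratio
#' profile and the occupancy profile (plus the methylation-occupancy
#' correlations).
#'
#' @param fullValues,hemiValues Per-position value tables (`chrom`, `pos`,
#'   `value`), e.g. per-dyad frequencies at covered dyads.
#' @param centers Centres table.
#' @param labels Labelled bin table (`chrom`, `start`, `end`, `label`),
#'   from [classifyRegions()].
#' @param window,step Profile parameters.
#' @param minCenters Strata with fewer centres give NA.
#' @return `data.table`: `stratum`, `n_centers`, `r_ratio_occ`,
#'   `r_full_occ`, `r_hemi_occ`.
#' @export
stratifiedCorrelation <- function(fullValues, hemiValues, centers, labels,
                                  window = 1000L, step = 10L,
                                  minCenters = 10L) {
  cen <- as.data.table(centers)
  lb <- as.data.table(labels)
  cen2 <- lb[cen, on = .(chrom, start <= center, end > center),
             nomatch = NA, .(chrom, center = i.center, label)]
  strata <- c("low", "high")
  out <- lapply(strata, function(s) {
    cc <- cen2[label == s, .(chrom, center)]
    if (nrow(cc) < minCenters) {
      warning("stratum '", s, "' has fewer than ", minCenters,
              " centers")
      return(data.table(stratum = s, n_centers = nrow(cc),
                        r_ratio_occ = NA_real_, r_full_occ = NA_real_,
                        r_hemi_occ = NA_real_))
    }
    pf <- centerProfile(fullValues, cc, window, step)
    ph <- centerProfile(hemiValues, cc, window, step)
    po <- occupancyProfile(cc, window, step)
    data.table(stratum = s, n_centers = nrow(cc),
               r_ratio_occ = ratioAndCorrelation(pf, ph, po)$r,
               r_full_occ = profileCorrelation(pf, po),
               r_hemi_occ = profileCorrelation(ph, po))
  })
  rbindlist(out)
}
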