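#' Coverage titration QC
#'
#' Subsamples molecules (without replacement) so that the mean resolved dyad
#' coverage hits each target, then compares methylation levels between the
#' subsample and the full-depth data at each resolution. The methylation
#' level of a unit (bin) is the pooled per-cytosine frequency
#' `(n_full + n_hemi/2) / coverage`; the report gives the median and IQR of
#' the per-unit subsample/full-depth ratio, restricted to units covered at
#' both depths with a nonzero full-depth level.
#'
#' @param calls Call table.
#' @param sites Dyad sites from [findDyads()].
#' @param targetCovs Numeric vector of target mean dyad coverages (each
#'   <= the achieved mean coverage).
#' @param resolutions Integer vector of bin sizes (bp); use `Inf`-free
#'   values; `1` approximates dyad resolution.
#' @param seed Integer seed for subsampling.
#' @param context Context whose methylation level is compared.
#' @return `data.table`: `target`, `resolution`, `n_units`, `ratio_median`,
#'   `ratio_q25`, `ratio_q75`, plus the achieved full-depth mean coverage as
#'   attribute `achievedCoverage`.
#' @export
titrateCoverage <- function(calls, sites, targetCovs, resolutions,
                            seed = 1L, context = "CG") {
  calls <- .checkCallTable(calls)
  ctx <- context
  full <- callDyads(calls, sites)$counts[context == ctx]
  if (!nrow(full)) stop("no resolved dyads", call. = FALSE)
  achieved <- mean(full$coverage)
  if (any(targetCovs > achieved))
    stop(sprintf("target coverage exceeds achieved mean (%.2f)", achieved),
         call. = FALSE)
  if (!length(resolutions) || !length(targetCovs)) {
    out <- data.table(target = numeric(), resolution = numeric(),
                      n_units = integer(), ratio_median = numeric(),
                      ratio_q25 = numeric(), ratio_q75 = numeric())
    data.table::setattr(out, "achievedCoverage", achieved)
    return(out)
  }
  mols <- unique(calls$molecule_id)
  set.seed(derivedSeed(seed, 701L))
  res <- list()
  for (tg in targetCovs) {
    frac <- tg / achieved
    keep <- if (frac >= 1) mols else
      sample(mols, size = round(frac * length(mols)))
    sub <- callDyads(calls[molecule_id %in% keep], sites)$counts[
      context == ctx]
    for (rs in resolutions) {
      lv <- function(x) x[, .(
        level = sum(n_full + (n_hemi_watson + n_hemi_crick) / 2) /
          sum(coverage)), by = .(chrom, bin = pos %/% rs)]
      j <- lv(sub)[lv(full), on = c("chrom", "bin"), nomatch = NULL,
                   .(level_sub = level, level_full = i.level)]
      j <- j[level_full > 0]
      r <- j$level_sub / j$level_full
      res[[length(res) + 1L]] <- data.table(
        target = tg, resolution = rs, n_units = length(r),
        ratio_median = median(r), ratio_q25 = quantile(r, 0.25,
        names = FALSE), ratio_q75 = quantile(r, 0.75, names = FALSE))
    }
  }
  out <- rbindlist(res)
  data.table::setattr(out, "achievedCoverage", achieved)
  out[]
}
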