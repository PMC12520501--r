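#' Call differentially methylated 1-kb bins between two samples
#'
#' For each bin, the per-dyad full- (or hemi-) methylation frequencies over
#' dyads shared between the two samples (resolved coverage `>= minCov` in
#' both) are compared with a paired two-sided t-test and a Mann-Whitney U
#' test; p-values are Benjamini-Hochberg adjusted across all tested bins of
#' the run. A bin is a DMR when both adjusted p-values fall below `alpha`
#' (set `combination = "either"` for the disjunctive rule). Bins where
#' sample B has lost methylation completely (mean frequency exactly 0) are
#' additionally called when they contain more than `clMinDyads` shared
#' dyads and the absolute frequency change exceeds `clDelta`
#' (the complete-loss rule). Zero-variance paired differences make the
#' t-test undefined; the decision then falls to the U test (and the
#' complete-loss rule). Called DMRs are classified into Groups 1-4 from the
#' signs of the full- and hemi-methylation changes, and CSG content is
#' counted when a genome is supplied.
#'
#' @param countsA,countsB Dyad count tables (sample A = reference/wildtype,
#'   B = test/mutant); deltas are B - A.
#' @param context Dyad context to test.
#' @param kind `"full"` (fDMR) or `"hemi"` (hDMR).
#' @param binSize Bin width in bp.
#' @param alpha FDR threshold.
#' @param minCov Minimum resolved coverage per dyad per sample.
#' @param minDyads Minimum shared dyads for a bin to be tested (untested
#'   bins are reported with NA p-values).
#' @param combination `"both"` (conjunction, default) or `"either"`.
#' @param clMinDyads,clDelta Complete-loss rule: strict thresholds on the
#'   shared dyad count and absolute frequency change.
#' @param genome Optional `DNAStringSet` for CSG counting.
#' @return `data.table` of all bins with shared dyads: `chrom`, `start`,
#'   `end`, `context`, `kind`, `n_shared_dyads`, `delta` (tested kind),
#'   `delta_full`, `delta_hemi`, `p_ttest`, `p_mwu`, `q_ttest`, `q_mwu`,
#'   `complete_loss`, `is_dmr`, `group` (1-4 or NA), `csg_count`.
#' @export
callDmrs <- function(countsA, countsB, context = "CG",
                     kind = c("full", "hemi"), binSize = 1000L,
                     alpha = 0.05, minCov = 5L, minDyads = 3L,
                     combination = c("both", "either"),
                     clMinDyads = 10L, clDelta = 0.30, genome = NULL) {
  kind <- match.arg(kind)
  combination <- match.arg(combination)
  ctx <- context
  a <- as.data.table(countsA)[context == ctx & coverage >= minCov]
  b <- as.data.table(countsB)[context == ctx & coverage >= minCov]
  fr <- function(x) {
    x <- copy(x)
    x[, `:=`(f_full = n_full / coverage,
             f_hemi = (n_hemi_watson + n_hemi_crick) / coverage)]
    x[, .(chrom, pos, f_full, f_hemi)]
  }
  sh <- fr(a)[fr(b), on = c("chrom", "pos"), nomatch = NULL,
              .(chrom, pos, fA_full = f_full, fA_hemi = f_hemi,
                fB_full = i.f_full, fB_hemi = i.f_hemi)]
  if (!nrow(sh)) stop("no shared dyads between samples", call. = FALSE)
  sh[, bin := pos %/% as.integer(binSize)]
  sh[, `:=`(fA = if (kind == "full") fA_full else fA_hemi,
            fB = if (kind == "full") fB_full else fB_hemi)]

  res <- sh[, {
    n <- .N
    dA <- fA; dB <- fB
    pt <- NA_real_; pm <- NA_real_
    if (n >= minDyads) {
      dif <- dB - dA
      if (stats::sd(dif) > 0)
        pt <- tryCatch(t.test(dB, dA, paired = TRUE)$p.value,
                       error = function(e) NA_real_)
      pm <- tryCatch(suppressWarnings(
        wilcox.test(dB, dA, exact = FALSE)$p.value),
        error = function(e) NA_real_)
    }
    .(n_shared_dyads = n,
      meanA = mean(dA), meanB = mean(dB),
      delta_full = mean(fB_full) - mean(fA_full),
      delta_hemi = mean(fB_hemi) - mean(fA_hemi),
      p_ttest = pt, p_mwu = pm)
  }, by = .(chrom, bin)]
  res[, `:=`(start = as.integer(bin * binSize),
             end = as.integer((bin + 1) * binSize),
             delta = meanB - meanA)]
  res[, `:=`(q_ttest = p.adjust(p_ttest, "BH"),
             q_mwu = p.adjust(p_mwu, "BH"))]
  res[, complete_loss := meanB == 0 & n_shared_dyads > clMinDyads &
        abs(delta) > clDelta]
  sigT <- res$q_ttest < alpha
  sigM <- res$q_mwu < alpha
  sig <- if (combination == "both") {
    # an undefined t-test defers to the U test
    fifelse(is.na(res$p_ttest), sigM,
            fifelse(is.na(res$p_mwu), sigT, sigT & sigM))
  } else {
    fifelse(is.na(res$p_ttest), sigM,
            fifelse(is.na(res$p_mwu), sigT, sigT | sigM))
  }
  res[, is_dmr := (!is.na(sig) & sig) | complete_loss]
  res[, group := NA_integer_]
  res[is_dmr == TRUE, group := classifyGroups(delta_full, delta_hemi)]
  res[, csg_count := NA_integer_]
  if (!is.null(genome)) {
    idx <- which(res$is_dmr & res$chrom %in% names(genome))
    for (i in idx) {
      L <- Biostrings::width(genome[res$chrom[i]])
      res$csg_count[i] <- countCsg(genome, res$chrom[i], res$start[i],
                                   min(res$end[i], L))
    }
  }
  ctxv <- ctx; kv <- kind
  res[, `:=`(context = ctxv, kind = kv, bin = NULL, meanA = NULL,
             meanB = NULL)]
  data.table::setcolorder(res, c("chrom", "start", "end", "context",
    "kind", "n_shared_dyads", "delta", "delta_full", "delta_hemi",
    "p_ttest", "p_mwu", "q_ttest", "q_mwu", "complete_loss", "is_dmr",
    "group", "csg_count"))
  setorder(res, chrom, start)
  res[]
}

#' Classify DMRs into Groups 1-4 from methylation changes
#'
#' Group 1: full and hemi both decreased; Group 2: full decreased, hemi
#' increased; Group 3: full increased, hemi decreased; Group 4: both
#' increased. A zero change in either direction leaves the bin unassigned
#' (`NA`).
#'
#' @param deltaFull,deltaHemi Numeric vectors of frequency changes
#'   (test - reference).
#' @return Integer vector of group labels (1-4 or `NA`).
#' @examples
#' classifyGroups(c(-0.2, -0.2, 0.1, 0.1, 0), c(-0.05, 0.03, -0.1, 0.2, 0.1))
#' @export
classifyGroups <- function(deltaFull, deltaHemi) {
  g <- rep(NA_integer_, length(deltaFull))
  g[deltaFull < 0 & deltaHemi < 0] <- 1L
  g[deltaFull < 0 & deltaHemi > 0] <- 2L
  g[deltaFull > 0 & deltaHemi < 0] <- 3L
  g[deltaFull > 0 & deltaHemi > 0] <- 4L
  g
}
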