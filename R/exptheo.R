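#' Experimental vs theoretical full-methylation (Exp/Theo) curve
#'
#' Under purely stochastic per-cytosine methylation, the full-methylation
#' frequency of a bin with per-cytosine frequency `p_total` is `p_total^2`.
#' Bins are grouped by `p_total` (to minimise interference from uneven
#' methylation across bins); within each group the experimental and
#' theoretical full-methylation frequencies are dyad-count-weighted means,
#' and `log2_ratio = log2(exp/theo)` measures departure from stochasticity
#' (0 = stochastic; > 0 = specific maintenance of symmetric methylation).
#'
#' @param bins Bin table from [aggregateBins()]; filtered bins are dropped.
#' @param context Dyad context to analyse.
#' @param groupEdges Strictly increasing breakpoints partitioning the
#'   `p_total` range; defaults to 10 equal-width groups over `[0.025, 1]`.
#' @return `data.table`: `context`, `group_lo`, `group_hi`, `n_bins`,
#'   `exp_full`, `theo_full`, `log2_ratio`. Groups with no bins or zero
#'   theoretical frequency are omitted.
#' @export
expTheoCurve <- function(bins, context = "CG",
                         groupEdges = seq(0.025, 1, length.out = 11)) {
  if (is.unsorted(groupEdges, strictly = TRUE))
    stop("groupEdges must be strictly increasing", call. = FALSE)
  ctx <- context
  b <- as.data.table(bins)[context == ctx & filtered == FALSE &
                             n_dyads > 0]
  if (!nrow(b)) {
    return(data.table(context = character(), group_lo = numeric(),
                      group_hi = numeric(), n_bins = integer(),
                      exp_full = numeric(), theo_full = numeric(),
                      log2_ratio = numeric()))
  }
  b[, group := findInterval(p_total, groupEdges,
                            rightmost.closed = TRUE)]
  b <- b[group >= 1L & group < length(groupEdges)]
  out <- b[, .(
    group_lo = groupEdges[group[1L]],
    group_hi = groupEdges[group[1L] + 1L],
    n_bins = .N,
    exp_full = stats::weighted.mean(p_full, n_dyads),
    theo_full = stats::weighted.mean(p_total^2, n_dyads)
  ), by = group]
  out <- out[theo_full > 0]
  out[, log2_ratio := log2(exp_full / theo_full)]
  out[, `:=`(context = ctx, group = NULL)]
  data.table::setcolorder(out, c("context", "group_lo", "group_hi",
                                 "n_bins", "exp_full", "theo_full",
                                 "log2_ratio"))
  setorder(out, group_lo)
  out[]
}
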