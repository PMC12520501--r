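#' Draw per-bin methylation and maintenance-efficiency parameters
#'
#' Model-level companion to the molecule simulator: instead of simulating
#' molecules, each bin receives a total methylation frequency `q` (drawn
#' uniformly in `qRange`) and a maintenance efficiency `eff` determined by
#' the chosen model, from which per-dyad status probabilities follow as
#' `p_full = eff * q`, `p_hemi = 2 q (1 - eff)`, `p_unme = 1 - q (2 - eff)`.
#' The `"independent"` model is the stochastic null (`eff = q`, i.e.
#' `p_full = q^2`, `p_hemi = 2 q (1 - q)`).
#'
#' @param nBins Number of bins.
#' @param model `"independent"`, `"saturation"` (`eff = Emax q / (km + q)`),
#'   `"linear"` (`eff = Ebase + kp q`, capped at 1) or `"fixed"`
#'   (`eff = modelParams["eff"]`).
#' @param qRange Range of per-bin total methylation frequencies; the default
#'   keeps `p_unme >= 0` for any efficiency in `[0, 1]` produced by the
#'   supported models at these frequencies.
#' @param modelParams Named numeric vector of model parameters
#'   (`Emax`/`km`, `Ebase`/`kp`, or `eff`).
#' @param seed Integer seed.
#' @param binSize Bin width in bp (bins are laid head-to-tail on one
#'   synthetic chromosome).
#' @return `data.table`: `chrom`, `start`, `end`, `q`, `eff`.
#' @export
makeBinParams <- function(nBins, model = c("independent", "saturation",
                                           "linear", "fixed"),
                          qRange = c(0.05, 0.6), modelParams = NULL,
                          seed = 1L, binSize = 1000L) {
  model <- match.arg(model)
  stopifnot(nBins > 0)
  set.seed(derivedSeed(seed, 501L))
  q <- runif(nBins, qRange[1], qRange[2])
  eff <- switch(model,
    independent = q,
    saturation = {
      stopifnot(all(c("Emax", "km") %in% names(modelParams)))
      modelParams[["Emax"]] * q / (modelParams[["km"]] + q)
    },
    linear = {
      stopifnot(all(c("Ebase", "kp") %in% names(modelParams)))
      pmin(1, modelParams[["Ebase"]] + modelParams[["kp"]] * q)
    },
    fixed = rep(modelParams[["eff"]], nBins))
  if (any(1 - q * (2 - eff) < -1e-9))
    stop("qRange incompatible with model: p_unme would be negative",
         call. = FALSE)
  data.table(chrom = "simChr",
             start = as.integer((seq_len(nBins) - 1L) * binSize),
             end = as.integer(seq_len(nBins) * binSize),
             q = q, eff = eff)
}

#' Simulate per-dyad status counts from per-bin parameters
#'
#' Places `dyadsPerBin` dyads evenly within each bin and draws, for each
#' dyad, multinomial status counts at the given read coverage from the bin's
#' `(p_full, p_hemi, p_unme)`; hemi counts are split between Watson and
#' Crick with equal probability. The output is a dyad-count table directly
#' consumable by [aggregateBins()] and [callDmrs()].
#'
#' @param binParams Output of [makeBinParams()].
#' @param dyadsPerBin Dyads per bin.
#' @param coverage Resolved read coverage per dyad.
#' @param seed Integer seed (vary to obtain replicate noise realisations on
#'   the same bin parameters).
#' @param context Context label to stamp on the counts.
#' @return `data.table` with the [callDyads()] count columns: `chrom`,
#'   `pos`, `c_pos`, `context`, `n_full`, `n_hemi_watson`, `n_hemi_crick`,
#'   `n_unme`, `coverage`.
#' @export
simulateBinnedDyads <- function(binParams, dyadsPerBin = 20L,
                                coverage = 15L, seed = 1L,
                                context = "CG") {
  bp <- as.data.table(binParams)
  nB <- nrow(bp)
  k <- as.integer(dyadsPerBin)
  binSize <- bp$end[1] - bp$start[1]
  off <- as.integer(floor((seq_len(k) - 0.5) / k * binSize))
  dt <- bp[rep(seq_len(nB), each = k)]
  dt[, pos := start + rep(off, nB)]
  dt[, `:=`(p_full = eff * q, p_hemi = 2 * q * (1 - eff))]
  dt[, p_unme := pmax(0, 1 - p_full - p_hemi)]
  set.seed(derivedSeed(seed, 502L))
  n <- nrow(dt)
  dt[, n_full := rbinom(n, coverage, p_full)]
  dt[, n_hemi := rbinom(n, coverage - n_full,
                        fifelse(p_full < 1, pmin(1, p_hemi / (1 - p_full)),
                                0))]
  dt[, n_hemi_watson := rbinom(n, n_hemi, 0.5)]
  dt[, `:=`(n_hemi_crick = n_hemi - n_hemi_watson,
            n_unme = coverage - n_full - n_hemi)]
  ctx <- context
  out <- dt[, .(chrom, pos, c_pos = pos + 1L, context = ctx,
                n_full, n_hemi_watson, n_hemi_crick, n_unme)]
  out[, coverage := n_full + n_hemi_watson + n_hemi_crick + n_unme]
  setorder(out, chrom, pos)
  out[]
}
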