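#' Maintenance-efficiency points from binned methylation
#'
#' The maintenance efficiency of a bin is `y = P_me / P_total`, the fraction
#' of inherited methyl-marked dyads restored to full methylation by the time
#' of observation, plotted against `x = P_total` (the post-replication
#' initial hemi-methylation frequency). Only bins in the requested H3K9me2
#' stratum that pass the per-dyad coverage and total-methylation filters
#' contribute. `y` is deliberately left uncapped: sampling noise can push it
#' above 1 and clipping before fitting would bias the fits.
#'
#' @param bins Bin table from [aggregateBins()].
#' @param labels `data.table` with `chrom`, `start`, `label` assigning each
#'   bin to a stratum (see [classifyRegions()]).
#' @param stratum Stratum to select (usually `"low"` or `"high"`).
#' @param context Dyad context.
#' @return `data.table`: `chrom`, `start`, `x`, `y`, `weight` (dyad count).
#' @export
efficiencyPoints <- function(bins, labels, stratum, context = "CG") {
  ctx <- context
  b <- as.data.table(bins)[context == ctx & filtered == FALSE &
                             n_dyads > 0]
  lb <- as.data.table(labels)
  b[lb, label := i.label, on = c("chrom", "start")]
  b <- b[label == stratum & p_total > 0]
  if (!nrow(b)) {
    warning("no bins in stratum '", stratum, "'")
    return(data.table(chrom = character(), start = integer(),
                      x = numeric(), y = numeric(), weight = numeric()))
  }
  b[, .(chrom, start, x = p_total, y = p_full / p_total,
        weight = as.numeric(n_dyads))]
}

.checkPoints <- function(points, minPts = 10L) {
  p <- as.data.table(points)
  if (nrow(p) < minPts)
    stop("need at least ", minPts, " points", call. = FALSE)
  if (data.table::uniqueN(p$x) < 2L)
    stop("non-identifiable: all x values identical", call. = FALSE)
  p
}

#' Fit the saturation maintenance-efficiency model
#'
#' Fits `y = Emax * x / (km + x)` by minimising the mean squared error.
#' `Emax` is the maximum maintenance efficiency reached when the
#' post-replication hemi-methylation frequency saturates the machinery, and
#' `km` plays the role of an affinity constant between the maintenance
#' methyltransferase and its hemi-methylated substrate. Given `km`, the
#' optimal `Emax` has a closed form, so the fit profiles `Emax` out and
#' minimises over `log(km)` with a multi-start grid followed by
#' golden-section refinement; bounds are `Emax` in `[0, 1.05]` (the slack
#' above 1 keeps boundary estimates diagnosable) and `km` in `(1e-5, 1]`.
#'
#' @param points Points from [efficiencyPoints()] (needs `x`, `y`; `weight`
#'   used when `weighted = TRUE`).
#' @param weighted Use dyad-count weights in the MSE (default unweighted).
#' @return A [MaintenanceFit-class] with parameters `Emax`, `km`.
#' @export
fitSaturation <- function(points, weighted = FALSE) {
  p <- .checkPoints(points)
  x <- p$x; y <- p$y
  w <- if (weighted) p$weight / mean(p$weight) else rep(1, length(x))
  emaxFor <- function(km) {
    g <- x / (km + x)
    e <- sum(w * y * g) / sum(w * g^2)
    min(max(e, 0), 1.05)
  }
  mseFor <- function(logkm) {
    km <- exp(logkm)
    e <- emaxFor(km)
    mean(w * (y - e * x / (km + x))^2)
  }
  grid <- log(10^seq(-5, 0, length.out = 41))
  vals <- vapply(grid, mseFor, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(mseFor, interval = c(lo, hi), tol = 1e-10)
  km <- exp(opt$minimum)
  emax <- emaxFor(km)
  new("MaintenanceFit", model = "saturation",
      params = c(Emax = emax, km = km), mse = opt$objective,
      n = length(x), converged = TRUE)
}

#' Fit the linear maintenance-efficiency model
#'
#' Fits `y = Ebase + kp * x` by closed-form least squares (normal
#' equations). `Ebase` is the basal maintenance efficiency independent of
#' methylation frequency; `kp` the linear coupling between efficiency and
#' `P_total`. In the stochastic limit (two independent de novo events per
#' dyad) the line is the identity, `(Ebase, kp) = (0, 1)`.
#'
#' @inheritParams fitSaturation
#' @return A [MaintenanceFit-class] with parameters `Ebase`, `kp`.
#' @export
fitLinear <- function(points, weighted = FALSE) {
  p <- .checkPoints(points)
  x <- p$x; y <- p$y
  w <- if (weighted) p$weight / mean(p$weight) else rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx == 0) stop("non-identifiable: all x values identical",
                     call. = FALSE)
  kp <- sum(w * (x - mx) * (y - my)) / sxx
  ebase <- my - kp * mx
  mse <- mean(w * (y - ebase - kp * x)^2)
  new("MaintenanceFit", model = "linear",
      params = c(Ebase = ebase, kp = kp), mse = mse,
      n = length(x), converged = TRUE)
}

#' Test proximity of the linear fit to the stochastic limit
#'
#' Fits the free linear model and compares it to the forced identity model
#' `y = x` (the limit where symmetric methylation arises from two
#' independent de novo events). Reports the distance of `(Ebase, kp)` from
#' `(0, 1)` and the two MSEs; an identity MSE close to the free-fit MSE
#' indicates stochastic methylation, while a free fit that substantially
#' beats the identity model indicates specific maintenance.
#'
#' @inheritParams fitSaturation
#' @return List with `fit` (the free [MaintenanceFit-class]),
#'   `ebaseDeviation`, `kpDeviation`, `mseFree`, `mseIdentity`.
#' @export
stochasticLimitCheck <- function(points, weighted = FALSE) {
  fit <- fitLinear(points, weighted = weighted)
  p <- as.data.table(points)
  w <- if (weighted) p$weight / mean(p$weight) else rep(1, nrow(p))
  mseId <- mean(w * (p$y - p$x)^2)
  list(fit = fit,
       ebaseDeviation = unname(fit@params["Ebase"]),
       kpDeviation = unname(fit@params["kp"] - 1),
       mseFree = fit@mse, mseIdentity = mseId)
}
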