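setOldClass("data.table")

#' Chromatin state of a synthetic genome
#'
#' Per-bin H3K9me2 enrichment and euchromatic/heterochromatic labels, plus
#' sorted nucleosome centre positions per chromosome. Produced by
#' [simulateChromatin()].
#'
#' @slot bins `data.table` with columns `chrom`, `start`, `end`, `h3k9me2`,
#'   `region` (`"euchromatic"`/`"heterochromatic"`).
#' @slot centers `data.table` with columns `chrom`, `center` (0-based bp,
#'   strictly increasing within chromosome).
#' @slot binSize Integer bin width in bp.
#' @export
setClass("ChromatinState",
  representation(bins = "data.table", centers = "data.table",
                 binSize = "integer"))

setValidity("ChromatinState", function(object) {
  b <- object@bins
  if (!all(c("chrom", "start", "end", "h3k9me2", "region") %in% names(b)))
    return("bins must have chrom/start/end/h3k9me2/region")
  if (any(b$h3k9me2 < 0)) return("h3k9me2 values must be >= 0")
  cen <- object@centers
  if (nrow(cen)) {
    bad <- cen[, any(diff(center) <= 0), by = chrom][V1 == TRUE]
    if (nrow(bad)) return("nucleosome centers must be strictly increasing")
  }
  TRUE
})

#' Methylation model parameters for the synthetic generator
#'
#' One row per (context, region) combination. Parental-strand methylation
#' probabilities are drawn per bin, uniformly in `[qLo, qHi]` (shared bin-level
#' intensity across contexts), so that neighbouring cytosines covary the way
#' regional methylation does in real methylomes. Set `qLo == qHi` for a
#' constant probability.
#'
#' @slot table `data.table` with columns `context` (CG/CWG/CWWG/CCG), `region`
#'   (euchromatic/heterochromatic), `qLo`, `qHi` (parental methylation
#'   probability range), `E` (maintenance efficiency: probability a hemi dyad
#'   whose template cytosine is methylated is restored to full before
#'   observation) and `d` (per-strand de novo probability).
#' @slot mode `"replication"` (template/nascent structure) or `"independent"`
#'   (every cytosine methylated independently with its site probability,
#'   ignoring `E` and `d`).
#' @slot shield Multiplicative reduction of `E` for dyads under a nucleosome
#'   (1 = no shielding).
#' @export
setClass("MethylationParams",
  representation(table = "data.table", mode = "character",
                 shield = "numeric"))

setValidity("MethylationParams", function(object) {
  tb <- object@table
  if (!all(c("context", "region", "qLo", "qHi", "E", "d") %in% names(tb)))
    return("table must have context/region/qLo/qHi/E/d")
  p <- c(tb$qLo, tb$qHi, tb$E, tb$d, object@shield)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("all probabilities must lie in [0, 1]")
  if (any(tb$qHi < tb$qLo)) return("qHi must be >= qLo")
  if (!object@mode %in% c("replication", "independent"))
    return("mode must be 'replication' or 'independent'")
  TRUE
})

#' Observation (bisulfite read-out) parameters
#'
#' @slot conversionRate Probability an unmethylated cytosine reads converted
#'   (i.e. is correctly observed unmethylated).
#' @slot overconversionRate Probability a methylated cytosine reads converted
#'   (observed unmethylated).
#' @slot missRate Probability a cytosine call is missing.
#' @slot seed Integer seed for the observation stage.
#' @export
setClass("ObservationParams",
  representation(conversionRate = "numeric", overconversionRate = "numeric",
                 missRate = "numeric", seed = "integer"))

setValidity("ObservationParams", function(object) {
  p <- c(object@conversionRate, object@overconversionRate, object@missRate)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("all rates must lie in [0, 1]")
  TRUE
})

#' A simulated population of double-stranded molecules
#'
#' Ground truth for the simulator: fragment coordinates, template strands and
#' true per-cytosine methylation states at all dyad-member cytosines (plus all
#' spike-in cytosines). Produced by [simulatePopulation()].
#'
#' @slot molecules `data.table`: `molecule_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `template` (`"+"`/`"-"`; NA in independent mode).
#' @slot states `data.table`: `molecule_id`, `chrom`, `pos`, `strand`, `meth`
#'   (logical true state) for every simulated cytosine on the molecule.
#' @slot sites `data.table` of dyad sites used (see [findDyads()]).
#' @slot csg `data.table` of CSG sites used (see [findDyads()]).
#' @slot spikeIn Spike-in chromosome name, or `NA`.
#' @export
setClass("MoleculeSet",
  representation(molecules = "data.table", states = "data.table",
                 sites = "data.table", csg = "data.table",
                 spikeIn = "character"))

#' A fitted maintenance-efficiency model
#'
#' @slot model `"saturation"` (E_max * P_total / (k_m + P_total)), `"linear"`
#'   (E_base + k_p * P_total) or `"identity"` (the stochastic limit, y = x).
#' @slot params Named numeric vector of fitted parameters.
#' @slot mse Mean squared error of the fit.
#' @slot n Number of points fitted.
#' @slot converged Logical convergence flag.
#' @export
setClass("MaintenanceFit",
  representation(model = "character", params = "numeric", mse = "numeric",
                 n = "integer", converged = "logical"))

setValidity("MaintenanceFit", function(object) {
  if (object@mse < 0) return("mse must be >= 0")
  TRUE
})

#' @describeIn MaintenanceFit-class Compact display of a fit.
#' @param object A `MaintenanceFit`.
#' @export
setMethod("show", "MaintenanceFit", function(object) {
  cat(sprintf("MaintenanceFit [%s]\n", object@model))
  cat("  params:", paste(sprintf("%s = %.4g", names(object@params),
                                 object@params), collapse = ", "), "\n")
  cat(sprintf("  mse = %.4g, n = %d, converged = %s\n",
              object@mse, object@n, object@converged))
})

setMethod("show", "ChromatinState", function(object) {
  cat(sprintf("ChromatinState: %d bins (%d bp), %d nucleosome centers\n",
              nrow(object@bins), object@binSize, nrow(object@centers)))
  cat(sprintf("  heterochromatic bins: %d\n",
              sum(object@bins$region == "heterochromatic")))
})

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet: %d molecules, %d cytosine states\n",
              nrow(object@molecules), nrow(object@states)))
})

setMethod("show", "MethylationParams", function(object) {
  cat(sprintf("MethylationParams [mode = %s, shield = %.2f]\n",
              object@mode, object@shield))
  print(object@table)
})

#' Accessors for simulator objects
#'
#' `chromatinBins()` and `nucleosomeCenters()` extract the per-bin state and
#' centre positions from a [ChromatinState-class]; `moleculeTable()` and
#' `stateTable()` extract fragment records and true cytosine states from a
#' [MoleculeSet-class]; `fitParams()`, `fitMse()` and `fitModel()` read a
#' [MaintenanceFit-class].
#'
#' @param x The object.
#' @return A `data.table` (copies, safe to modify), numeric vector or scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
chromatinBins <- function(x) copy(x@bins)

#' @rdname accessors
#' @export
nucleosomeCenters <- function(x) copy(x@centers)

#' @rdname accessors
#' @export
moleculeTable <- function(x) copy(x@molecules)

#' @rdname accessors
#' @export
stateTable <- function(x) copy(x@states)

#' @rdname accessors
#' @export
fitParams <- function(x) x@params

#' @rdname accessors
#' @export
fitMse <- function(x) x@mse

#' @rdname accessors
#' @export
fitModel <- function(x) x@model
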