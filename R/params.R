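.defaultParamTable <- function() {
  # Arabidopsis-flavoured defaults: CG maintenance highly efficient in
  # euchromatin, CWG somewhat less so, CWWG essentially stochastic (de novo
  # dominated), CCG (the C1 cytosine of CSG) weakly maintained.
  rbindlist(list(
    data.table(context = "CG",  region = c("euchromatic", "heterochromatic"),
               qLo = c(0.05, 0.60), qHi = c(0.35, 0.95),
               E = c(0.93, 0.60), d = 0.005),
    data.table(context = "CWG", region = c("euchromatic", "heterochromatic"),
               qLo = c(0.01, 0.30), qHi = c(0.12, 0.80),
               E = c(0.87, 0.50), d = 0.005),
    data.table(context = "CWWG", region = c("euchromatic", "heterochromatic"),
               qLo = c(0.005, 0.05), qHi = c(0.05, 0.30),
               E = c(0.10, 0.10), d = 0.02),
    data.table(context = "CCG", region = c("euchromatic", "heterochromatic"),
               qLo = c(0.02, 0.30), qHi = c(0.15, 0.70),
               E = c(0.10, 0.10), d = 0.005)
  ))
}

#' Construct methylation model parameters
#'
#' See [MethylationParams-class] for the meaning of the fields. `q`, `E` and
#' `d` may be given to override the defaults uniformly across contexts and
#' regions; `table` overrides row-wise (joined on context + region).
#'
#' @param mode `"replication"` or `"independent"`.
#' @param shield Multiplicative reduction of maintenance efficiency for dyads
#'   under a nucleosome (1 = none). Applies to maintenance only, not de novo.
#' @param q Optional scalar or length-2 range recycled into `qLo`/`qHi` for
#'   all rows.
#' @param E,d Optional scalars recycled over all rows.
#' @param table Optional `data.table` with a subset of rows/columns of the
#'   default table to override.
#' @return A [MethylationParams-class].
#' @examples
#' methylationParams(mode = "independent", q = 0.2)
#' @export
methylationParams <- function(mode = c("replication", "independent"),
                              shield = 1, q = NULL, E = NULL, d = NULL,
                              table = NULL) {
  mode <- match.arg(mode)
  tb <- .defaultParamTable()
  if (!is.null(q)) {
    q <- rep(q, length.out = 2L)
    tb[, `:=`(qLo = q[1], qHi = q[2])]
  }
  if (!is.null(E)) data.table::set(tb, NULL, "E", E)
  if (!is.null(d)) data.table::set(tb, NULL, "d", d)
  if (!is.null(table)) {
    ov <- as.data.table(table)
    if (!"region" %in% names(ov)) {
      ov <- rbindlist(list(copy(ov)[, region := "euchromatic"],
                           copy(ov)[, region := "heterochromatic"]))
    }
    for (i in seq_len(nrow(ov))) {
      sel <- tb$context == ov$context[i] & tb$region == ov$region[i]
      for (col in intersect(c("qLo", "qHi", "E", "d"), names(ov))) {
        data.table::set(tb, which(sel), col, ov[[col]][i])
      }
    }
  }
  new("MethylationParams", table = tb, mode = mode, shield = shield)
}

#' Construct observation parameters
#'
#' @param conversionRate Probability an unmethylated cytosine is read as
#'   converted (default 0.995, a conventional library-quality figure).
#' @param overconversionRate Probability a methylated cytosine is read as
#'   converted.
#' @param missRate Probability a call is missing.
#' @param seed Integer seed for the observation stage.
#' @return An [ObservationParams-class].
#' @export
observationParams <- function(conversionRate = 0.995,
                              overconversionRate = 0, missRate = 0,
                              seed = 1L) {
  new("ObservationParams", conversionRate = conversionRate,
      overconversionRate = overconversionRate, missRate = missRate,
      seed = as.integer(seed))
}
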