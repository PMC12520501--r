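#' @import methods
#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv rbindlist fifelse fread fwrite setnames copy :=
#' @importFrom stats runif rbinom cor optimize p.adjust t.test wilcox.test
#'   median quantile setNames
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", ".GRP", "..keep", "chrom", "pos", "strand", "state",
  "molecule_id", "dyad_id", "cyt_id", "context", "w_pos", "c_pos", "w_state",
  "c_state", "status", "n_full", "n_hemi_watson", "n_hemi_crick", "n_unme",
  "coverage", "bin", "start", "end", "value", "width", "blacklisted", "q",
  "eff", "p_full", "p_hemi", "p_unme", "p_total", "n_dyads", "filtered",
  "label", "template", "fragment_id", "meth", "shielded", "d", "E",
  "cyt_context", "region", "offset", "n", "site_id", "qv", "group",
  "w_cyt", "c_cyt", "c1_strand", "csg_id", "s1", "s2", "s3", "center",
  "freqA", "freqB", "covA", "covB", "is_template", "x", "y", "weight",
  "spike", "p_t", "u", "maintM", "templM", "frac", "level_full", "level_sub",
  "obs_state", "nW", "nC", "keyid", "i.start", "i.end", "pairable", "V1",
  "m", "b0", "b1", "os", "oe", "f_full", "f_hemi", "fA", "fB", "fA_full",
  "fA_hemi", "fB_full", "fB_hemi", "meanA", "meanB", "delta", "delta_full",
  "delta_hemi", "p_ttest", "p_mwu", "q_ttest", "q_mwu", "complete_loss",
  "is_dmr", "csg_count", "E_eff", "templ_cyt", "nasc_cyt", "maint",
  "w_meth", "c_meth", "fs", "fe", "orient", "c1_pos", "c2_pos", "c3_pos",
  "c2_strand", "c3_strand", "cond", "cond_state", "occ", "p", "lo", "hi",
  "ratio", "a", "b", "len", "name", "score", "w_fragment", "c_fragment",
  "N", "i.N", "level", "group_lo", "theo_full", "exp_full", "n_hemi",
  "covered"
))

#' Derive a deterministic sub-seed from a master seed
#'
#' All stochastic stages of the package derive their own RNG substream from a
#' single master seed through this function, so that individual stages are
#' reproducible in isolation and adding draws to one stage does not perturb
#' another.
#'
#' @param seed Integer master seed.
#' @param k Integer stage tag (any small integer; each stage uses its own).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derivedSeed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(3L)) {
    s <- (s * 48271 + as.numeric(k) * 12345 + 1) %% m
  }
  as.integer(s %% (m - 2L)) + 1L
}

.assertProb <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

.checkCallTable <- function(calls) {
  calls <- as.data.table(calls)
  need <- c("molecule_id", "chrom", "pos", "strand", "state")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("call table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  calls
}
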