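.trivialChromatin <- function(genome, binSize = 1000L) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  bins <- rbindlist(lapply(names(lens), function(ch) {
    starts <- seq.int(0L, lens[[ch]] - 1L, by = binSize)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + binSize, lens[[ch]]),
               h3k9me2 = 0, region = "euchromatic")
  }))
  new("ChromatinState", bins = bins,
      centers = data.table(chrom = character(), center = integer()),
      binSize = as.integer(binSize))
}

# Static site-level annotation: one row per distinct cytosine with its
# context (CG takes precedence where a cytosine also sits in a CCG dyad),
# per-bin parental methylation probability q and de novo rate d; and the
# dyad table with effective maintenance efficiency (region- and
# nucleosome-adjusted).
.annotateSites <- function(sites, genome, chromatin, params, seed) {
  dy <- copy(sites$dyads)
  binSize <- chromatin@binSize
  bins <- chromatin@bins
  spike <- spikeInChrom(genome)

  mem <- rbindlist(list(
    dy[, .(chrom, pos = w_pos, strand = "+", context, dyad_id)],
    dy[, .(chrom, pos = c_pos, strand = "-", context, dyad_id)]
  ))
  prio <- c(CG = 1L, CWG = 2L, CWWG = 3L, CCG = 4L)
  cyt <- mem[, .(context = context[which.min(prio[context])]),
             by = .(chrom, pos, strand)]
  # spike-in cytosines (all of them, both strands) for conversion estimation
  if (!is.na(spike) && spike %in% names(genome)) {
    s <- genome[[spike]]
    cw <- .motifStarts(s, "C")
    cc <- .motifStarts(s, "G")
    cyt <- rbindlist(list(cyt[chrom != spike],
      unique(rbindlist(list(
        cyt[chrom == spike],
        data.table(chrom = spike, pos = cw, strand = "+", context = "CG"),
        data.table(chrom = spike, pos = cc, strand = "-", context = "CG")
      )), by = c("chrom", "pos", "strand"))))
  }
  setorder(cyt, chrom, pos, strand)
  cyt[, cyt_id := .I]

  # per-bin methylation intensity, shared across contexts within a bin
  set.seed(derivedSeed(seed, 301L))
  binTab <- copy(bins)[, bin := start %/% binSize]
  binTab[, m := runif(.N)]
  cyt[, bin := pos %/% binSize]
  cyt[binTab, `:=`(region = i.region, m = i.m), on = c("chrom", "bin")]
  cyt[is.na(region), `:=`(region = "euchromatic", m = 0.5)]
  pt <- params@table
  cyt[pt, `:=`(q = i.qLo + m * (i.qHi - i.qLo), d = i.d),
      on = c("context", "region")]
  if (!is.na(spike)) cyt[chrom == spike, `:=`(q = 0, d = 0)]

  dy[cyt[strand == "+"], w_cyt := i.cyt_id, on = c(chrom = "chrom",
     w_pos = "pos")]
  dy[cyt[strand == "-"], c_cyt := i.cyt_id, on = c(chrom = "chrom",
     c_pos = "pos")]
  dy[, bin := w_pos %/% binSize]
  dy[binTab, region := i.region, on = c("chrom", "bin")]
  dy[is.na(region), region := "euchromatic"]
  dy[pt, E := i.E, on = c("context", "region")]
  # nucleosome shielding: dyad anchor within 73 bp of a centre
  dy[, shielded := FALSE]
  cen <- chromatin@centers
  if (nrow(cen)) {
    for (ch in unique(cen$chrom)) {
      cc <- cen[chrom == ch, center]
      idx <- dy[, which(chrom == ch)]
      if (length(idx)) {
        p <- dy$w_pos[idx]
        j <- findInterval(p, cc)
        dl <- abs(p - cc[pmax(j, 1L)])
        dr <- abs(cc[pmin(j + 1L, length(cc))] - p)
        dy$shielded[idx] <- pmin(dl, dr) <= 73L
      }
    }
  }
  dy[, E_eff := E * fifelse(shielded, params@shield, 1)]
  if (!is.na(spike)) dy[chrom == spike, E_eff := 0]
  list(cyt = cyt[], dyads = dy[])
}

#' Simulate a population of double-stranded molecules with
#' replication-structured methylation
#'
#' Each molecule is an independent snapshot of one cell's DNA duplex at a
#' random genomic location (fragment length uniform in `fragLen`). In
#' `"replication"` mode a template strand is chosen uniformly per molecule;
#' template-strand cytosines carry parental methylation (probability `q` per
#' site), each dyad whose template cytosine is methylated has its nascent
#' cytosine methylated with probability `E` (times the nucleosome shield for
#' dyads under a nucleosome), and remaining unmethylated cytosines gain de
#' novo methylation with probability `d`. In `"independent"` mode every
#' cytosine is methylated independently with probability `q`. Only
#' dyad-member cytosines (plus all spike-in cytosines) are simulated; dyads
#' straddling a fragment edge are simulated in full so that in-fragment
#' members have well-defined states, but only in-fragment positions are
#' observable.
#'
#' Random draws are organised in fixed-order stages (template, maintenance,
#' de novo) with one substream each, so that for a fixed seed the realised
#' parental states are identical across different values of `E`; increasing
#' `E` can then only convert maintenance failures into successes.
#'
#' @param genome `DNAStringSet` (see [makeGenome()]).
#' @param params A [MethylationParams-class].
#' @param nMolecules Number of molecules (> 0).
#' @param seed Integer master seed.
#' @param chromatin A [ChromatinState-class]; `NULL` gives a neutral state
#'   (all euchromatic, no nucleosomes).
#' @param fragLen Length-2 integer range of fragment lengths in bp.
#' @return A [MoleculeSet-class].
#' @export
simulatePopulation <- function(genome, params, nMolecules, seed = 1L,
                               chromatin = NULL, fragLen = c(100L, 200L)) {
  if (nMolecules <= 0) stop("nMolecules must be > 0", call. = FALSE)
  if (is.null(chromatin)) chromatin <- .trivialChromatin(genome)
  sites <- findDyads(genome)
  ann <- .annotateSites(sites, genome, chromatin, params, seed)
  cyt <- ann$cyt
  dy <- ann$dyads
  lens <- setNames(Biostrings::width(genome), names(genome))

  set.seed(derivedSeed(seed, 302L))
  chs <- sample(names(lens), nMolecules, replace = TRUE,
                prob = lens / sum(lens))
  fl <- sample(seq.int(fragLen[1], fragLen[2]), nMolecules, replace = TRUE)
  fl <- pmin(fl, lens[chs])
  st <- floor(runif(nMolecules) * (lens[chs] - fl + 1))
  mol <- data.table(molecule_id = seq_len(nMolecules), chrom = chs,
                    start = as.integer(st), end = as.integer(st + fl))
  set.seed(derivedSeed(seed, 303L))
  mol[, template := if (params@mode == "replication")
        sample(c("+", "-"), .N, replace = TRUE) else NA_character_]

  # dyad instances: dyads with any member inside the fragment
  dyj <- dy[, .(dyad_id, chrom, w_pos, c_pos, w_cyt, c_cyt, E_eff)]
  inst_dy <- dyj[mol, on = .(chrom, c_pos >= start, w_pos < end),
                 allow.cartesian = TRUE, nomatch = NULL,
                 .(molecule_id, dyad_id, w_cyt, c_cyt, E_eff,
                   template = i.template)]
  # cytosine instances: members of those dyads, plus spike-in cytosines
  inst_cyt <- unique(rbindlist(list(
    inst_dy[, .(molecule_id, cyt_id = w_cyt)],
    inst_dy[, .(molecule_id, cyt_id = c_cyt)]
  )))
  spike <- spikeInChrom(genome)
  if (!is.na(spike)) {
    sc <- cyt[chrom == spike, .(cyt_id, chrom, pos)]
    inst_sp <- sc[mol[chrom == spike], on = .(chrom, pos >= start,
                  pos < end), nomatch = NULL, allow.cartesian = TRUE,
                  .(molecule_id, cyt_id)]
    inst_cyt <- unique(rbindlist(list(inst_cyt, inst_sp)))
  }
  setorder(inst_cyt, molecule_id, cyt_id)
  inst_cyt[cyt, `:=`(chrom = i.chrom, pos = i.pos, strand = i.strand,
                     q = i.q, d = i.d), on = "cyt_id"]
  inst_cyt[mol, template := i.template, on = "molecule_id"]

  if (params@mode == "independent") {
    set.seed(derivedSeed(seed, 304L))
    inst_cyt[, meth := runif(.N) < q]
  } else {
    set.seed(derivedSeed(seed, 304L))
    inst_cyt[, templM := strand == template & runif(.N) < q]
    setorder(inst_dy, molecule_id, dyad_id)
    set.seed(derivedSeed(seed, 305L))
    inst_dy[, u := runif(.N)]
    inst_dy[, templ_cyt := fifelse(template == "+", w_cyt, c_cyt)]
    inst_dy[, nasc_cyt := fifelse(template == "+", c_cyt, w_cyt)]
    inst_dy[inst_cyt, templM := i.templM,
            on = c(molecule_id = "molecule_id", templ_cyt = "cyt_id")]
    inst_dy[, maintM := templM & u < E_eff]
    ma <- inst_dy[, .(maint = any(maintM)),
                  by = .(molecule_id, cyt_id = nasc_cyt)]
    inst_cyt[ma, maint := i.maint, on = c("molecule_id", "cyt_id")]
    inst_cyt[is.na(maint), maint := FALSE]
    inst_cyt[, meth := templM | maint]
    set.seed(derivedSeed(seed, 306L))
    inst_cyt[, meth := meth | (!meth & runif(.N) < d)]
    inst_cyt[, c("templM", "maint") := NULL]
  }
  states <- inst_cyt[, .(molecule_id, chrom, pos, strand, meth)]
  new("MoleculeSet", molecules = mol, states = states,
      sites = sites$dyads, csg = sites$csg,
      spikeIn = if (is.na(spike)) NA_character_ else spike)
}

#' True dyad statuses of a simulated population
#'
#' Recovers, from the generator's ground-truth states, the dyad status of
#' every dyad both of whose cytosines lie inside the molecule's fragment —
#' the oracle against which the observation/caller pipeline can be compared.
#'
#' @param ms A [MoleculeSet-class].
#' @return `data.table`: `molecule_id`, `dyad_id`, `chrom`, `pos`, `context`,
#'   `w_meth`, `c_meth`, `status` in
#'   `full`/`hemi_watson`/`hemi_crick`/`unme`.
#' @export
trueDyadStatus <- function(ms) {
  st <- ms@states
  dy <- ms@sites
  mol <- ms@molecules
  w <- st[strand == "+"][dy, on = c(chrom = "chrom", pos = "w_pos"),
        nomatch = NULL, allow.cartesian = TRUE,
        .(molecule_id, dyad_id = i.dyad_id, chrom, pos,
          context = i.context, c_pos = i.c_pos, w_meth = meth)]
  cst <- st[strand == "-"]
  w[cst, c_meth := i.meth, on = c("molecule_id", "chrom", c_pos = "pos")]
  w <- w[!is.na(c_meth)]
  w[mol, `:=`(fs = i.start, fe = i.end), on = "molecule_id"]
  w <- w[pos >= fs & c_pos < fe]
  w[, status := fifelse(w_meth & c_meth, "full",
               fifelse(w_meth, "hemi_watson",
               fifelse(c_meth, "hemi_crick", "unme")))]
  w[, c("fs", "fe", "c_pos") := NULL]
  setorder(w, molecule_id, chrom, pos)
  w[]
}
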