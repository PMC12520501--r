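---
title: "Dyad-resolution methylation analysis: models and methods"
author: "dyadMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyad-resolution methylation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadMeth)
library(data.table)
```

## The problem

Standard whole-genome bisulfite sequencing reads one strand of each DNA
molecule, so it cannot distinguish a fully methylated cytosine dyad (5mC on
both strands) from a hemi-methylated one (5mC on one strand). Hairpin
bisulfite sequencing (hpBS-seq) covalently links the two strands of a
molecule before conversion, so each read pair reports both cytosines of a
dyad on the *same* molecule. This package implements the downstream
analysis for such data in plants, where symmetric dyads exist in three
sequence contexts:

* **CG** — partner cytosine at +1 on the Crick strand;
* **CWG** (W = A/T) — partner at +2; the CCG subcontext is excluded because
  its reverse complement CGG is not CHG;
* **CWWG** — two symmetric CHH cytosines, partner at +3; the palindromic
  CTAG subcontext is the cleanest for modelling;
* **CCG/CGG ("CSG")** — not a symmetric CHG pair, but a trinucleotide
  nesting a CG dyad: two consecutive cytosines C1 (CHG context) and C2 on
  one strand and C3 on the other, with C2–C3 a CG dyad.

Each dyad on each molecule has one of four statuses — `full`,
`hemi_watson`, `hemi_crick`, `unme` — and per-site tallies of these
statuses are the raw material for everything downstream.

## The generative model behind the simulator

All statistical behaviour of the pipeline is tested against a synthetic
methylome generator (`makeGenome()`, `simulateChromatin()`,
`simulatePopulation()`, `emitCallTable()`) that emulates
replication-coupled maintenance methylation:

1. each molecule is an independent snapshot of one cell's duplex at a
   random position (fragment length uniform in 100–200 bp, matching
   sonication of hpBS libraries);
2. a template strand is chosen uniformly; template cytosines carry
   parental methylation with a per-site probability `q`;
3. each dyad whose template cytosine is methylated is restored to full
   methylation with probability `E` (maintenance efficiency), multiplied
   by a shielding factor `s ≤ 1` when the dyad lies within 73 bp of a
   nucleosome centre (shielding applies to maintenance only, not de novo);
4. remaining unmethylated cytosines gain de novo methylation with
   probability `d`.

A single replication + maintenance + de novo pass is used: the experiment
being emulated is a population snapshot, not a lineage. An `independent`
mode methylates every cytosine i.i.d. with probability `q`; it is the
stochastic null against which maintenance signatures are measured.

`q` is drawn per 1-kb bin as `qLo + m (qHi - qLo)`, where the intensity
`m ~ U(0, 1)` is *shared across contexts within a bin*. This regional
covariation mirrors real methylomes (pericentromeric bins are high in all
contexts) and is what lets same-strand neighbouring sites co-segregate
through replication — the mechanism behind the strand-specificity
analyses. Defaults (see `methylationParams()`) are Arabidopsis-flavoured:
efficient CG maintenance in euchromatin (`E = 0.93`), somewhat weaker CWG
maintenance (`E = 0.87`), essentially stochastic CWWG methylation
(`E = 0.1`, larger `d`), and weak CCG-dyad maintenance (`E = 0.1`),
with heterochromatic bins more methylated but less efficiently maintained.

Two modelling consequences are worth spelling out:

* **Cross-pathway coupling at CSG sites.** The nested CG dyad (C2–C3) and
  the CCG dyad (C1–C3) share cytosine C3. Maintenance is defined per
  dyad, so a nascent C3 can be methylated through either pathway; with
  `E = 1` this can leave hemi CG dyads whose methyl sits on the *nascent*
  strand. Away from CSG sites, the classic limits hold exactly (no hemi
  at `E = 1, d = 0`; all hemi methyl on the template strand at `d = 0`),
  and the tests assert them there.
* **Coupled randomness across parameter values.** Stage-wise substreams
  (`derivedSeed()`) guarantee that, at a fixed seed, parental states are
  identical across different `E`, so the population full-dyad fraction is
  provably monotone in `E`.

A second, model-level simulator (`makeBinParams()` /
`simulateBinnedDyads()`) skips molecules entirely and draws per-dyad
multinomial status counts from per-bin `(q, eff)`: `p_full = eff·q`,
`p_hemi = 2q(1 - eff)`, `p_unme = 1 - q(2 - eff)`. It is the right tool
for count-level statistics (Exp/Theo calibration, curve-fit recovery, DMR
calibration), where molecule structure is irrelevant and speed matters.

What the generator does *not* emulate: PCR duplicates, alignment and
mapping artefacts, sequencing errors beyond the conversion model,
multi-generation lineages, or genome repeat structure. Passing tests
therefore demonstrate correctness of the *computations* under a
replication-structured model, not robustness to upstream artefacts.

## From calls to dyads

`findDyads()` enumerates dyad sites by scanning the Watson strand
(palindromy of CG / C[AT]G / C[AT][AT]G makes this exhaustive; CCG and
CGG are scanned separately and reported with strand roles swapped so C1
is always the CHG-context cytosine). `callDyads()` joins per-strand calls
to sites per molecule: (M,M) → full, (M,U) → hemi_watson, (U,M) →
hemi_crick, (U,U) → unme; a missing member leaves the dyad unresolved and
excluded from counts. Conflicting duplicate calls at one cytosine are
treated as missing — the conservative reading when overlapping mates
disagree. Coordinates are 0-based half-open throughout (BED-compatible);
a dyad's position key is its Watson-anchor cytosine.

The bisulfite conversion rate is estimated as the converted fraction of
calls on the unmethylated spike-in chromosome (`conversionRate()`); the
generator's default conversion rate of 0.995 is a conventional
library-quality figure, configurable in `observationParams()`.

`isaPair()` implements in silico strand annealing for unlinked WGBS-style
fragments: Watson and Crick records sharing (chrom, start, end) are
paired one-to-one; pairing specificity is the ratio of observed
same-ends pairs to the mean obtained after permuting end coordinates
within chromosomes (10 permutations by default — the estimator is not
prescribed more precisely by the protocol). `titrateCoverage()`
subsamples molecules to target mean dyad coverages and reports per-unit
methylation-level ratios against full depth at several resolutions.

## Binned aggregation and the efficiency models

`aggregateBins()` computes per-dyad frequencies at dyads with resolved
coverage ≥ 5 reads and averages them (unweighted) within 1-kb bins; a
pooled-count mode exists, but the per-dyad mean is the default so that a
handful of deeply covered dyads cannot dominate a bin. Bins with total
methylation `p_total = p_full + p_hemi/2` below 2.5% are flagged (not
deleted) as noise-dominated. `p_total` is the per-cytosine methylation
frequency within dyads; since each daughter duplex inherits one parental
strand, it equals the expected hemi-methylation frequency immediately
after replication — which is why it plays the role of the substrate
concentration in the models below.

* **Exp/Theo ratio** (`expTheoCurve()`): under per-cytosine stochastic
  methylation the expected full-methylation frequency of a bin is
  `p_total²`. Bins are grouped by `p_total` (default 10 equal groups over
  [0.025, 1]; the grouping is a declared default, not inferred), and
  `log2(exp/theo)` per group measures departure from stochasticity.
* **Saturation model** (`fitSaturation()`):
  `y = Emax·x / (km + x)` with `y = P_me/P_total`, `x = P_total` — an
  enzyme-kinetics-shaped curve where `Emax` is the maximal maintenance
  efficiency and `km` an affinity constant. Given `km`, the optimal
  `Emax` is closed-form, so the fit profiles `Emax` out and minimises
  over `log(km)` with a 41-point multi-start grid plus golden-section
  refinement; bounds `Emax ∈ [0, 1.05]` (slack keeps boundary estimates
  diagnosable), `km ∈ (1e-5, 1]`. Points are unweighted in the MSE by
  default, and `y` is never clipped before fitting — sampling noise can
  push it above 1 and clipping would bias `Emax`.
* **Linear model** (`fitLinear()`): `y = Ebase + kp·x` by closed-form
  least squares; `stochasticLimitCheck()` compares the free line to the
  forced identity `y = x`, the exact limit when symmetric methylation
  arises from two independent de novo events.

Fits use merged counts (one population), not per-replicate fits; with
replicate data one would fit each replicate and compare parameters.

## DMRs

`callDmrs()` tests, per 1-kb bin, the paired per-dyad full- (or hemi-)
methylation frequencies over dyads shared between two samples, with a
paired two-sided t-test and a Mann–Whitney U test, BH-adjusted per run. A
bin is a DMR when **both** adjusted p-values are < 0.05 — the
conjunction is the conservative reading of "both tests were performed";
a disjunctive mode is available (`combination = "either"`). The U test
is applied to the two frequency vectors as named (a paired Wilcoxon
would be the alternative reading). Bins whose mutant frequency is
exactly 0 are additionally called when they hold > 10 shared dyads and
the absolute change exceeds 0.30 ("methylation changes > 30%" is read
as absolute, matching the complete-loss context). Zero-variance paired
differences leave the t-test undefined; the decision then falls to the
U test plus the complete-loss rule. Called bins are classified by the
signs of (Δfull, Δhemi) into Groups 1–4 (−−, −+, +−, ++; a zero delta is
unassigned), and `countCsg()` counts CCG/CGG occurrences per DMR.

## Strand concordance and CSG correlations

`proximalStatus()` classifies, for every hemi focal dyad on a molecule,
the nearest resolved neighbour dyad (ties to the left by default,
configurable): hemi on the same strand as the focal 5mC, hemi on the
opposite strand, full, or unme. Replication places the 5mC of every
maintenance-failure hemi dyad on the template strand, so in replication
mode with `d = 0` neighbouring hemi dyads are strand-concordant;
independent methylation gives a ~1:1 same/opposite ratio. Pairs are
pooled over (site × molecule), not averaged per site.

`csgTriplets()` extracts (C1, C2, C3) states per molecule (all three
resolved), and `conditionalPearson()` computes the six conditional
correlations r(pair | third cytosine fixed U or M), requiring 30
observations and non-constant vectors (undefined results are NA, never
0). The package reproduces the diagnostic ordering
r(C1,C2 | C3=U) > r(C1,C3 | C2=U) in a *maintenance-failure* regime:
het-like CG maintenance (`E = 0.6`), CSG-dyad maintenance off (CMT3
maintains symmetric CSG poorly), shared per-bin intensity. The mechanism
is replication co-segregation: co-methylated C1 and C2 ride the same
strand into the daughter cell, while C1 and C3 are separated. With very
efficient CG maintenance the conditioning on C3 = U nearly fixes C2 and
the same-strand signal is suppressed — the regime matters, and the
package documents rather than hides this.

## Nucleosome-centred profiles

`centerProfile()` averages any positional signal in offset cells of
width `step` within ±`window` of nucleosome centres;
`occupancyProfile()` does the same for the 147-bp particle indicator;
`contextDensity()` profiles dyad-anchor counts normalised to mean 1;
`ratioAndCorrelation()` forms the full/hemi ratio per offset and its
Pearson correlation with occupancy across offsets (correlations are
computed on the averaged profiles — the per-nucleosome alternative is a
known variant not enabled by default); `stratifiedCorrelation()` repeats
this per low/high mark stratum of the centre's containing bin.

Two numerical points discovered while validating the shielding
signature, both now defaults in the acceptance analyses:

* offset cells one repeat length apart contain the *same* genomic dyads
  (each dyad is seen by every centre within the window), so the
  effective degrees of freedom of a profile correlation is roughly
  `spacing/step`, independent of genome size. A 2-bp step keeps the null
  distribution of r tight; a 10-bp step leaves it wide enough to produce
  spurious |r| ≈ 0.4.
* a full/hemi *ratio* is only as good as its denominator: at `E = 0.9`
  hemi dyads are ~3% of dyads and the ratio profile is noise-dominated.
  The shielding experiments therefore run at `E = 0.7`.

With shielding (`s < 1`) the full/hemi ratio anti-correlates strongly
with occupancy (r ≈ −0.93 in the acceptance run); without shielding the
correlation is statistically indistinguishable from 0.

## Problem sizes and reproducibility

The test-suite and `scripts/acceptance.R` run entirely on synthetic data
at desk scale: 100-kb genomes, 4,000–30,000 molecules, and binned
simulations of 1,000–6,000 bins at 15× coverage with 20–60 dyads per bin
(60/kb mirrors the ~1/16 bp CG dyad density). The Exp/Theo null uses
6,000 bins so the lowest-methylation group's ratio SE is ≈ 0.01;
saturation recovery draws `P_total` over [0.025, 0.6] — down to the
total-methylation filter — because `km ≈ 0.007` is identifiable only
from bins near `km`. Every random stage derives its own substream from
one master seed via `derivedSeed()`, so each stage is independently
reproducible and the acceptance script is deterministic given `--seed`.

## Known limitations

* The generator's single-pass snapshot has no explicit time axis;
  "maintenance efficiency" is a per-cell-cycle probability, not a rate.
* Conflicting overlapping mate calls are discarded rather than
  quality-weighted (base qualities are upstream of the call table).
* iSA pairing among coordinate-duplicate fragments is by arbitrary
  one-to-one assignment; dyad counts are unaffected but molecule
  identities within a duplicate group are exchangeable.
* Real-data conveniences (BigWig input, TE annotation joins, RNA-seq
  stratification) are out of scope; tracks enter as bedGraph, features
  and centres as BED.
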