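test_that("genome generation is deterministic, validated, and hits the
          motif densities implied by the base weights", {
  expect_error(makeGenome(c(chr1 = 0)), "1 kb")
  expect_error(makeGenome(c(chr1 = 5000), baseWeights = c(-1, 1, 1, 1)),
               "non-negative")

  g1 <- makeGenome(c(chr1 = 20000), seed = 42)
  g2 <- makeGenome(c(chr1 = 20000), seed = 42)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- makeGenome(c(chr1 = 20000), seed = 43)
  expect_false(identical(as.character(g1), as.character(g3)))

  bw <- c(A = 0.3, C = 0.22, G = 0.22, T = 0.26)
  g <- makeGenome(c(chr1 = 100000), baseWeights = bw, seed = 1)
  nCG <- length(Biostrings::start(
    Biostrings::matchPattern("CG", g[[1]])))
  expected <- expectedCgCount(100000, bw)
  expect_gt(nCG, 0.8 * expected)
  expect_lt(nCG, 1.2 * expected)

  gs <- makeGenome(c(chr1 = 5000), spikeIn = 1500, seed = 1)
  expect_identical(spikeInChrom(gs), "spike")
  expect_identical(length(gs[["spike"]]), 1500L)
})

test_that("chromatin simulation produces contiguous heterochromatin with
          elevated H3K9me2 and periodic nucleosomes", {
  g <- makeGenome(c(chr1 = 50000), seed = 3)
  expect_error(simulateChromatin(g, spacing = 100), "146")

  ch0 <- simulateChromatin(g, hetFraction = 0, jitter = 0, seed = 1)
  bins <- chromatinBins(ch0)
  expect_true(all(bins$region == "euchromatic"))
  cen <- nucleosomeCenters(ch0)
  expect_true(all(diff(cen$center) == diff(cen$center)[1]))

  ch <- simulateChromatin(g, hetFraction = 0.3, seed = 2)
  b <- chromatinBins(ch)
  expect_gt(sum(b$region == "heterochromatic"), 0)
  expect_gt(sum(b$region == "euchromatic"), 0)
  expect_gt(mean(b[region == "heterochromatic", h3k9me2]),
            mean(b[region == "euchromatic", h3k9me2]))
  # heterochromatic block is contiguous
  r <- rle(b$region)$values
  expect_lte(sum(r == "heterochromatic"), 1L)
  # centers strictly increasing
  expect_true(nucleosomeCenters(ch)[, all(diff(center) > 0), by = chrom][
    , all(V1)])
})

# dyads sharing a cytosine with a CSG site (the nested CG dyad and the
# CCG-context dyad) are coupled across maintenance pathways; the simple
# single-dyad limits below are asserted away from them
standaloneDyads <- function(tr, sites) {
  nestedCg <- sites$csg[, fifelse(orient == "+", c2_pos, c3_pos)]
  tr[!(context == "CCG") & !(context == "CG" & pos %in% nestedCg)]
}

test_that("replication-mode populations respect the maintenance model in
          its deterministic limits", {
  g <- makeGenome(c(chr1 = 30000), seed = 5)
  ch <- simulateChromatin(g, seed = 5)
  sites <- findDyads(g)
  # E = 1, d = 0: no hemi dyads away from cross-pathway (CSG) coupling,
  # and every hemi elsewhere carries its methyl on the nascent strand
  p1 <- methylationParams(mode = "replication", E = 1, d = 0)
  m1 <- simulatePopulation(g, p1, 800, seed = 6, chromatin = ch)
  t1 <- trueDyadStatus(m1)
  expect_identical(
    sum(standaloneDyads(t1, sites)$status %in%
          c("hemi_watson", "hemi_crick")), 0L)
  hemi1 <- t1[status %in% c("hemi_watson", "hemi_crick")]
  hemi1[moleculeTable(m1), template := i.template, on = "molecule_id"]
  # E = 1 turns every template-methylated dyad full, so any residual hemi
  # methyl must sit on the nascent strand
  expect_true(hemi1[, all(fifelse(status == "hemi_watson", "+", "-") !=
                            template)])

  # E = 0, d = 0: no full dyads; every hemi methyl on the template strand
  p0 <- methylationParams(mode = "replication", E = 0, d = 0)
  m0 <- simulatePopulation(g, p0, 800, seed = 6, chromatin = ch)
  t0 <- trueDyadStatus(m0)
  expect_identical(sum(t0$status == "full"), 0L)
  hemi <- t0[status %in% c("hemi_watson", "hemi_crick")]
  # with no maintenance at all, every methyl is parental
  hemi[moleculeTable(m0), template := i.template, on = "molecule_id"]
  expect_gt(nrow(hemi), 100)
  expect_true(hemi[, all(fifelse(status == "hemi_watson", "+", "-") ==
                           template)])
})

test_that("with de novo off, hemi methyl marks of standalone dyads always
          sit on the template strand", {
  g <- makeGenome(c(chr1 = 40000), seed = 9)
  sites <- findDyads(g)
  pp <- methylationParams(mode = "replication", d = 0)
  ms <- simulatePopulation(g, pp, 1200, seed = 10)
  tr <- standaloneDyads(trueDyadStatus(ms), sites)
  hemi <- tr[status %in% c("hemi_watson", "hemi_crick")]
  hemi[moleculeTable(ms), template := i.template, on = "molecule_id"]
  expect_gt(nrow(hemi), 100)
  expect_true(hemi[, all(fifelse(status == "hemi_watson", "+", "-") ==
                           template)])
})

test_that("independent mode reproduces the binomial dyad-status fractions
          q^2 / 2q(1-q) / (1-q)^2", {
  q <- 0.2
  g <- makeGenome(c(chr1 = 100000), seed = 11)
  pp <- methylationParams(mode = "independent", q = q)
  ms <- simulatePopulation(g, pp, 16000, seed = 12)
  tr <- trueDyadStatus(ms)[context == "CG"]
  n <- nrow(tr)
  expect_gt(n, 1e5)
  se <- function(p) 3 * sqrt(p * (1 - p) / n)
  fullFrac <- mean(tr$status == "full")
  hemiFrac <- mean(tr$status %in% c("hemi_watson", "hemi_crick"))
  unmeFrac <- mean(tr$status == "unme")
  expect_lt(abs(fullFrac - q^2), se(q^2))
  expect_lt(abs(hemiFrac - 2 * q * (1 - q)), se(2 * q * (1 - q)))
  expect_lt(abs(unmeFrac - (1 - q)^2), se((1 - q)^2))
})

test_that("increasing maintenance efficiency never decreases the full-dyad
          fraction at a fixed seed", {
  g <- makeGenome(c(chr1 = 30000), seed = 13)
  ch <- simulateChromatin(g, seed = 13)
  fullFrac <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(E) {
    pp <- methylationParams(mode = "replication", E = E, d = 0)
    tr <- trueDyadStatus(simulatePopulation(g, pp, 600, seed = 14,
                                            chromatin = ch))
    mean(tr$status == "full")
  }, numeric(1))
  expect_true(all(diff(fullFrac) >= 0))
})

test_that("population simulation is deterministic for a fixed seed", {
  g <- makeGenome(c(chr1 = 20000), seed = 15)
  pp <- methylationParams(mode = "replication")
  m1 <- simulatePopulation(g, pp, 300, seed = 16)
  m2 <- simulatePopulation(g, pp, 300, seed = 16)
  expect_identical(stateTable(m1), stateTable(m2))
  expect_identical(moleculeTable(m1), moleculeTable(m2))
})

test_that("the observation model distorts calls at the configured rates and
          emits byte-identical tables on rerun", {
  s <- quickSim(genomeLen = 30000L, nMol = 1500L, seed = 17)
  # perfect observation: observed states equal true states
  perfect <- emitCallTable(s$ms, observationParams(conversionRate = 1,
    overconversionRate = 0, missRate = 0, seed = 1))
  st <- stateTable(s$ms)
  j <- merge(perfect, st, by = c("molecule_id", "chrom", "pos", "strand"))
  expect_identical(nrow(j), nrow(perfect))
  expect_true(all((j$state == "M") == j$meth))

  # spike-in apparent methylation ~ 1 - conversion rate
  g <- makeGenome(c(chr1 = 5000), spikeIn = 20000, seed = 18)
  pp <- methylationParams(mode = "replication")
  ms <- simulatePopulation(g, pp, 4000, seed = 19)
  calls <- emitCallTable(ms, observationParams(conversionRate = 0.995,
                                               seed = 20))
  sp <- calls[chrom == "spike" & state != "."]
  expect_gt(nrow(sp), 1e4)
  appMeth <- mean(sp$state == "M")
  expect_lt(abs(appMeth - 0.005),
            3 * sqrt(0.005 * 0.995 / nrow(sp)))

  # determinism
  c1 <- emitCallTable(ms, observationParams(seed = 21))
  c2 <- emitCallTable(ms, observationParams(seed = 21))
  expect_identical(c1, c2)
  f1 <- tempfile(); f2 <- tempfile()
  writeCallTable(c1, f1); writeCallTable(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("unlinked fragment emission yields two coordinate-matched strand
          records per molecule", {
  s <- quickSim(genomeLen = 20000L, nMol = 400L, seed = 22)
  uf <- emitUnlinkedFragments(s$ms, observationParams(seed = 23))
  expect_identical(nrow(uf$fragments), 800L)
  key <- uf$fragments[, .N, by = .(chrom, start, end, strand)]
  w <- key[strand == "+"]; cc <- key[strand == "-"]
  j <- merge(w, cc, by = c("chrom", "start", "end"))
  # every Watson coordinate triple has a Crick counterpart with equal count
  expect_identical(nrow(j), nrow(w))
  expect_true(all(j$N.x == j$N.y))

  # injected coordinate duplicates: collision count matches a brute count
  fr <- copy(uf$fragments)
  dup <- fr[strand == "+"][1:20]
  dup[, fragment_id := max(fr$fragment_id) + .I]
  fr2 <- rbindlist(list(fr, dup))
  tab <- fr2[, .(nW = sum(strand == "+"), nC = sum(strand == "-")),
             by = .(chrom, start, end)]
  bruteCollisions <- sum(pmin(tab$nW, tab$nC))
  ip <- isaPair(fr2, nPerm = 2, seed = 1)
  expect_identical(ip$nPairs, as.integer(bruteCollisions))
  expect_identical(ip$nDropped, nrow(fr2) - 2L * ip$nPairs)
})
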