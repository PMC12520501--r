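test_that("dyad discovery handles the canonical micro-sequences", {
  g <- Biostrings::DNAStringSet(c(chr = "ACGT"))
  d <- findDyads(g)$dyads
  expect_identical(nrow(d), 1L)
  expect_identical(d$context, "CG")
  expect_identical(d$w_pos, 1L)
  expect_identical(d$c_pos, 2L)

  g <- Biostrings::DNAStringSet(c(chr = "CAG"))
  d <- findDyads(g)$dyads
  expect_identical(d$context, "CWG")
  expect_identical(c(d$w_pos, d$c_pos), c(0L, 2L))

  g <- Biostrings::DNAStringSet(c(chr = "CATG"))
  d <- findDyads(g)$dyads
  expect_identical(d$context, "CWWG")
  expect_identical(c(d$w_pos, d$c_pos), c(0L, 3L))

  # ACCGT: CSG with C1 = (Watson, 1), C2 = (Watson, 2), C3 = (Crick, 3),
  # plus the nested CG dyad at 2 and the CCG-context dyad
  g <- Biostrings::DNAStringSet(c(chr = "ACCGT"))
  fd <- findDyads(g)
  expect_setequal(fd$dyads$context, c("CG", "CCG"))
  cgd <- fd$dyads[context == "CG"]
  expect_identical(c(cgd$w_pos, cgd$c_pos), c(2L, 3L))
  expect_identical(nrow(fd$csg), 1L)
  expect_identical(fd$csg$c1_pos, 1L)
  expect_identical(fd$csg$c1_strand, "+")
  expect_identical(fd$csg$c2_pos, 2L)
  expect_identical(fd$csg$c3_pos, 3L)
  expect_identical(fd$csg$c3_strand, "-")

  # mirrored orientation: Watson CGG -> C1 on the Crick strand
  g <- Biostrings::DNAStringSet(c(chr = "ACGGT"))
  fd <- findDyads(g)
  expect_identical(fd$csg$orient, "-")
  expect_identical(fd$csg$c1_pos, 3L)
  expect_identical(fd$csg$c1_strand, "-")
  expect_identical(fd$csg$c3_pos, 1L)
  expect_identical(fd$csg$c3_strand, "+")

  expect_error(findDyads(Biostrings::DNAStringSet(c(chr = "ACGN"))),
               "non-ACGT")
})

test_that("dyad discovery matches a brute-force window scan on a random
          sequence, and CTAG-only filtering works", {
  set.seed(31)
  seqStr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                         prob = c(0.28, 0.24, 0.24, 0.24)), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr = seqStr))
  got <- findDyads(g)$dyads[, .(w_pos, c_pos, context, c1_strand)]
  setorder(got, w_pos, context)
  want <- bruteDyadScan(seqStr)[, .(w_pos, c_pos, context, c1_strand)]
  expect_equal(as.data.frame(got), as.data.frame(want))

  ct <- findDyads(g, ctagOnly = TRUE)$dyads[context == "CWWG"]
  sub <- substring(seqStr, ct$w_pos + 1L, ct$w_pos + 4L)
  expect_true(all(sub == "CTAG"))
})

test_that("dyad status assignment follows the Watson/Crick state table", {
  g <- Biostrings::DNAStringSet(c(chr = "ACGT"))
  sites <- findDyads(g)
  mk <- function(w, c) tinyCallTable(list(
    list(1L, "chr", 1L, "+", w), list(1L, "chr", 2L, "-", c)))
  for (case in list(c("M", "M", "full"), c("M", "U", "hemi_watson"),
                    c("U", "M", "hemi_crick"), c("U", "U", "unme"),
                    c("M", ".", "unresolved"))) {
    res <- callDyads(mk(case[1], case[2]), sites)
    expect_identical(res$calls$status, case[3])
  }
  # coverage of only one member -> unresolved, excluded from counts
  res <- callDyads(tinyCallTable(list(list(1L, "chr", 1L, "+", "M"))),
                   sites)
  expect_identical(res$calls$status, "unresolved")
  expect_identical(nrow(res$counts), 0L)
  # conflicting duplicate calls at one cytosine -> missing
  res <- callDyads(tinyCallTable(list(
    list(1L, "chr", 1L, "+", "M"), list(1L, "chr", 1L, "+", "U"),
    list(1L, "chr", 2L, "-", "M"))), sites)
  expect_identical(res$calls$status, "unresolved")
  # calls at non-dyad positions are tallied as ignored
  res <- callDyads(tinyCallTable(list(
    list(1L, "chr", 0L, "+", "U"), list(1L, "chr", 1L, "+", "M"),
    list(1L, "chr", 2L, "-", "M"))), sites)
  expect_identical(res$nIgnored, 1L)
})

test_that("per-site counts equal a brute-force recount from generator
          truth and conserve coverage", {
  s <- quickSim(genomeLen = 40000L, nMol = 1000L, seed = 33)
  calls <- emitCallTable(s$ms, observationParams(conversionRate = 1,
                                                 seed = 34))
  res <- callDyads(calls, s$sites)
  tr <- trueDyadStatus(s$ms)
  want <- tr[, .(n_full = sum(status == "full"),
                 n_hemi_watson = sum(status == "hemi_watson"),
                 n_hemi_crick = sum(status == "hemi_crick"),
                 n_unme = sum(status == "unme")),
             by = .(chrom, pos, context)]
  got <- res$counts[, .(chrom, pos, context, n_full, n_hemi_watson,
                        n_hemi_crick, n_unme)]
  cmp <- merge(got, want, by = c("chrom", "pos", "context"))
  expect_identical(nrow(cmp), nrow(got))
  expect_identical(nrow(got), nrow(want))
  for (col in c("n_full", "n_hemi_watson", "n_hemi_crick", "n_unme"))
    expect_identical(cmp[[paste0(col, ".x")]], cmp[[paste0(col, ".y")]])
  # status conservation
  expect_true(res$counts[, all(coverage ==
    n_full + n_hemi_watson + n_hemi_crick + n_unme)])
})

test_that("strand relabelling swaps hemi counts and fixes full/unme", {
  s <- quickSim(genomeLen = 30000L, nMol = 800L, seed = 35)
  calls <- emitCallTable(s$ms, observationParams(seed = 36))
  swapped <- copy(calls)[, strand := fifelse(strand == "+", "-", "+")]
  a <- callDyads(calls, s$sites)$counts
  b <- callDyads(swapped, s$sites)$counts
  # restrict to CG dyads (w/c swap maps a CG dyad onto itself)
  a <- a[context == "CG"]; b <- b[context == "CG"]
  j <- merge(a, b, by = c("chrom", "pos"))
  expect_identical(j$n_full.x, j$n_full.y)
  expect_identical(j$n_unme.x, j$n_unme.y)
  expect_identical(j$n_hemi_watson.x, j$n_hemi_crick.y)
  expect_identical(j$n_hemi_crick.x, j$n_hemi_watson.y)
})

test_that("conversion-rate estimation is the spike-in converted fraction", {
  mk <- function(nU, nM) tinyCallTable(c(
    lapply(seq_len(nU), function(i) list(i, "spike", i, "+", "U")),
    lapply(seq_len(nM), function(i) list(nU + i, "spike", i, "+", "M"))))
  expect_identical(conversionRate(mk(10, 0), "spike"), 1)
  expect_equal(conversionRate(mk(995, 5), "spike"), 0.995)
  expect_error(conversionRate(mk(5, 0), "chr1"), "undefined")

  # simulated: estimate within 3 binomial SEs of the configured rate
  g <- makeGenome(c(chr1 = 2000), spikeIn = 30000, seed = 37)
  pp <- methylationParams(mode = "replication")
  ms <- simulatePopulation(g, pp, 3000, seed = 38)
  calls <- emitCallTable(ms, observationParams(conversionRate = 0.99,
                                               seed = 39))
  n <- nrow(calls[chrom == "spike" & state != "."])
  expect_gt(n, 1e4)
  est <- conversionRate(calls, "spike")
  expect_lt(abs(est - 0.99), 3 * sqrt(0.99 * 0.01 / n))
})

test_that("iSA re-pairs strands by coordinates and detects strandedness
          degenerate cases", {
  fr <- data.table(fragment_id = 1:2, chrom = "chr1", start = 10L,
                   end = 110L, strand = c("+", "-"))
  ip <- isaPair(fr, nPerm = 2, seed = 1)
  expect_identical(ip$nPairs, 1L)
  fr$strand <- "+"
  expect_warning(ip <- isaPair(fr, nPerm = 2, seed = 1), "pairable")
  expect_identical(ip$nPairs, 0L)
})

test_that("iSA recovers simulated molecules and re-paired calls reproduce
          the linked dyad counts", {
  s <- quickSim(genomeLen = 50000L, nMol = 1500L, seed = 40)
  obs <- observationParams(conversionRate = 1, seed = 41)
  uf <- emitUnlinkedFragments(s$ms, obs)
  ip <- isaPair(uf$fragments, uf$calls, nPerm = 5, seed = 42)
  expect_gte(ip$nPairs / nrow(moleculeTable(s$ms)), 0.99)
  # counts from re-paired molecules match counts from true linkage
  direct <- callDyads(emitCallTable(s$ms, obs), s$sites)$counts
  viaIsa <- callDyads(ip$calls, s$sites)$counts
  j <- merge(direct, viaIsa, by = c("chrom", "pos", "context"))
  expect_identical(nrow(j), nrow(direct))
  expect_identical(j$n_full.x, j$n_full.y)
  expect_identical(j$n_unme.x, j$n_unme.y)
})

test_that("coverage titration reports unit ratios around 1 and validates
          its inputs", {
  s <- quickSim(genomeLen = 60000L, nMol = 6000L, seed = 43)
  calls <- emitCallTable(s$ms, observationParams(seed = 44))
  full <- callDyads(calls, s$sites)$counts[context == "CG"]
  achieved <- mean(full$coverage)
  expect_gt(achieved, 10)
  expect_error(titrateCoverage(calls, s$sites, achieved * 2, 1000),
               "exceeds")
  # empty resolution list -> empty report
  empty <- titrateCoverage(calls, s$sites, numeric(0), integer(0))
  expect_identical(nrow(empty), 0L)
  # target == achieved -> all ratios exactly 1
  tt <- titrateCoverage(calls, s$sites, achieved, c(1000L, 10000L))
  expect_true(all(tt$ratio_median == 1))
  expect_true(all(tt$ratio_q25 == 1 & tt$ratio_q75 == 1))
  # subsampling to half depth preserves 1-kb levels in the median
  th <- titrateCoverage(calls, s$sites, achieved / 2, 1000L, seed = 45)
  expect_gt(th$ratio_median, 0.95)
  expect_lt(th$ratio_median, 1.05)
})
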