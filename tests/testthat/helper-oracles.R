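library(data.table)

# Brute-force window-scan oracle for dyad sites: enumerates every dyad
# context by sliding a character window along the Watson sequence.
bruteDyadScan <- function(seqStr, chrom = "chr") {
  s <- strsplit(seqStr, "")[[1]]
  n <- length(s)
  rows <- list()
  add <- function(w, c, ctx, c1s = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.table(
      chrom = chrom, w_pos = w, c_pos = c, context = ctx, c1_strand = c1s)
  }
  for (i in seq_len(n)) {
    p <- i - 1L  # 0-based
    if (s[i] == "C") {
      if (i + 1L <= n && s[i + 1L] == "G") add(p, p + 1L, "CG")
      if (i + 2L <= n && s[i + 1L] %in% c("A", "T") && s[i + 2L] == "G")
        add(p, p + 2L, "CWG")
      if (i + 3L <= n && s[i + 1L] %in% c("A", "T") &&
          s[i + 2L] %in% c("A", "T") && s[i + 3L] == "G")
        add(p, p + 3L, "CWWG")
      if (i + 2L <= n && s[i + 1L] == "C" && s[i + 2L] == "G")
        add(p, p + 2L, "CCG", "+")
      if (i + 2L <= n && s[i + 1L] == "G" && s[i + 2L] == "G")
        add(p, p + 2L, "CCG", "-")
    }
  }
  out <- rbindlist(rows)
  setorder(out, w_pos, context)
  out
}

# Closed-form expected CG-dyad count for i.i.d. base sampling.
expectedCgCount <- function(L, baseWeights) {
  p <- baseWeights / sum(baseWeights)
  (L - 1) * p[["C"]] * p[["G"]]
}

# Brute-force per-base binned mean oracle for bedGraph binning.
bruteBinMeans <- function(rec, binSize, chromLen, chrom = "chr") {
  vals <- rep(NA_real_, chromLen)
  for (i in seq_len(nrow(rec))) {
    idx <- (rec$start[i] + 1L):rec$end[i]
    vals[idx] <- rec$value[i]
  }
  nb <- ceiling(chromLen / binSize)
  out <- data.table(
    chrom = chrom, start = (seq_len(nb) - 1L) * binSize)
  out$value <- vapply(seq_len(nb), function(b) {
    v <- vals[((b - 1L) * binSize + 1L):min(b * binSize, chromLen)]
    if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  }, numeric(1))
  out$covered <- vapply(seq_len(nb), function(b) {
    v <- vals[((b - 1L) * binSize + 1L):min(b * binSize, chromLen)]
    sum(!is.na(v))
  }, numeric(1))
  out
}

# Brute-force per-offset averaging oracle for centre profiles.
bruteCenterProfile <- function(values, centers, window, step) {
  acc <- list()
  for (i in seq_len(nrow(centers))) {
    ch <- centers$chrom[i]; ce <- centers$center[i]
    v <- values[values$chrom == ch &
                  values$pos >= ce - window - step / 2 &
                  values$pos <= ce + window + step / 2, ]
    if (!nrow(v)) next
    off <- round((v$pos - ce) / step) * step
    keep <- abs(off) <= window
    acc[[length(acc) + 1L]] <- data.table(offset = off[keep],
                                          value = v$value[keep])
  }
  dt <- rbindlist(acc)
  out <- dt[, .(value = mean(value), n = .N), by = offset]
  setorder(out, offset)
  out
}

# Small deterministic call table written by hand.
tinyCallTable <- function(rows) {
  dt <- rbindlist(lapply(rows, function(r) {
    data.table(molecule_id = r[[1]], chrom = r[[2]], pos = r[[3]],
               strand = r[[4]], state = r[[5]])
  }))
  dt
}

# Default quick simulation shared by several tests.
quickSim <- function(genomeLen = 60000L, nMol = 3000L, seed = 7L,
                     mode = "replication", ...) {
  g <- makeGenome(c(chr1 = genomeLen), seed = seed)
  ch <- simulateChromatin(g, seed = seed)
  pp <- methylationParams(mode = mode, ...)
  ms <- simulatePopulation(g, pp, nMol, seed = seed + 1L, chromatin = ch)
  list(genome = g, chromatin = ch, params = pp, ms = ms,
       sites = findDyads(g))
}
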