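#' Read and write the bespoke TSV tables
#'
#' Call tables carry one row per observed cytosine: `molecule_id`, `chrom`,
#' `pos` (0-based), `strand` (`+`/`-`), `state` (`M`/`U`/`.`). Dyad count
#' tables carry `chrom`, `pos`, `c_pos`, `context` and the four status
#' counts. Paths ending in `.gz` are compressed transparently.
#'
#' @param x Table to write.
#' @param path File path (`.gz` optional).
#' @return Readers return a `data.table`; writers return `path` invisibly.
#' @export
writeCallTable <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t",
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

.freadMaybeGz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path)
    on.exit(close(con))
    fread(text = readLines(con), ...)
  } else {
    fread(path, ...)
  }
}

#' @rdname writeCallTable
#' @export
readCallTable <- function(path) {
  dt <- .freadMaybeGz(path, sep = "\t",
              colClasses = list(character = c("chrom", "strand", "state")))
  .checkCallTable(dt)
}

#' @rdname writeCallTable
#' @export
writeDyadCounts <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname writeCallTable
#' @export
readDyadCounts <- function(path) {
  dt <- .freadMaybeGz(path, sep = "\t")
  need <- c("chrom", "pos", "c_pos", "context", "n_full", "n_hemi_watson",
            "n_hemi_crick", "n_unme")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("dyad count table lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"coverage" %in% names(dt))
    dt[, coverage := n_full + n_hemi_watson + n_hemi_crick + n_unme]
  dt
}

#' Read a chrom.sizes file
#'
#' @param path Two-column TSV (chrom, length).
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "len"))
  setNames(as.integer(dt$len), dt$chrom)
}

#' Export dyad sites as BED
#'
#' Writes each dyad as a BED interval spanning its two cytosines, with the
#' context in the name column.
#'
#' @param dyads `dyads` table from [findDyads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDyadBed <- function(dyads, path) {
  dt <- as.data.table(dyads)[, .(chrom, start = w_pos, end = c_pos + 1L,
                                 name = context, score = 0L,
                                 strand = "+")]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
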