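# Internal helpers shared across the package.

# Evaluate expr under a given seed without disturbing the caller's RNG
# stream. All simulator and permutation code routes randomness through this
# so results are reproducible from explicit seeds only.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

# GRanges (1-based inclusive) <-> BED (0-based half-open) data.frame.
grangesToBed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L,
             end = end(gr),
             stringsAsFactors = FALSE)
}

bedToGRanges <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

# Named integer vector of chromosome lengths for a SimGenomeConfig.
simChromLengths <- function(config) {
  stats::setNames(rep(config@chromLength, config@nChrom),
                  paste0("chr", seq_len(config@nChrom)))
}

sweepRegionsGRanges <- function(config) {
  sr <- config@sweepRegions
  if (!nrow(sr)) return(GRanges())
  gr <- GRanges(sr$chrom, IRanges(as.integer(sr$start), as.integer(sr$end)),
                reduction = sr$reduction)
  setChromLengths(gr, simChromLengths(config))
}

# Register all chromosomes (with lengths) on a GRanges, whether or not a
# range touches each of them.
setChromLengths <- function(gr, chromLengths) {
  seqlevels(gr) <- union(names(chromLengths), seqlevels(gr))
  seqlengths(gr)[names(chromLengths)] <- chromLengths
  gr
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}
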