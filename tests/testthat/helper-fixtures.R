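# Shared builders and independent oracles for the test suite.

# A small GenotypeMatrix from an explicit dosage matrix.
makeGm <- function(pos, dosage, group, chrom = "chr1", ref = NULL,
                   alt = NULL, chromLength = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                               ref = ref, alt = alt)
  if (!is.null(chromLength)) {
    lens <- stats::setNames(rep(chromLength, length(unique(chrom))),
                            unique(chrom))
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- lens
  }
  GenotypeMatrix(gr, dosage, group = group)
}

# Brute-force nucleotide diversity over a window: expand each site into
# its allele vector, average the difference indicator over all allele
# pairs, sum over sites, divide by the span. Independent of sitePi().
bruteForcePi <- function(dosageGroup, span) {
  total <- 0
  for (i in seq_len(nrow(dosageGroup))) {
    d <- dosageGroup[i, ]
    d <- d[!is.na(d)]
    alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      pairs <- pairs + 1
      diffs <- diffs + as.integer(alleles[a] != alleles[b])
    }
    total <- total + diffs / pairs
  }
  total / span
}

# Exact HWE p-value by enumerating every heterozygote configuration at
# fixed allele counts (probability-ordered tail).
hweEnumOracle <- function(cnt) {
  nA <- 2 * cnt[1] + cnt[2]
  nB <- 2 * cnt[3] + cnt[2]
  n <- sum(cnt)
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
    exp(lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
          h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  pObs <- pr[match(cnt[2], hets)]
  sum(pr[pr <= pObs + 1e-12])
}

# Write a VCF text fixture from raw lines (prepends a minimal header).
writeVcfFixture <- function(path, bodyLines, samples = c("s1", "s2", "s3"),
                            contigs = c(chr1 = 100000L)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, bodyLines), path)
  path
}

# Expression records straight from a ratio matrix (one row per record).
recordsFromRatios <- function(ratios, ids = NULL) {
  ratios <- as.matrix(ratios)
  if (is.null(ids)) ids <- sprintf("tx%03d", seq_len(nrow(ratios)))
  df <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ratios)))
    df[[sprintf("ratio_%d", j)]] <- ratios[, j]
  df
}
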