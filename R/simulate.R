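#' Simulate a two-group diploid SNP panel
#'
#' Draws independent bi-allelic SNP sites on a multi-chromosome genome for
#' two accession groups. Each site's minor-allele frequency comes from the
#' uniform distribution in the config; inside a planted sweep region the
#' high group's frequency is scaled by `(1 - reduction)`, so `reduction = 1`
#' leaves the high group monomorphic for the reference allele there.
#' Genotypes are drawn per diploid sample under Hardy-Weinberg proportions
#' at the group's site frequency; sites are independent (no linkage).
#'
#' @param config a [SimGenomeConfig-class]; its `seed` drives all
#'   randomness, and equal seeds give byte-identical files.
#' @param dir optional directory; when given, writes `panel.vcf` (VCF 4.2
#'   whose header also records the planted sweep regions),
#'   `groups.tsv` (sample_id, group) and `truth.json`.
#' @return A list with elements `genotypes` (a [GenotypeMatrix-class]),
#'   `truth` (planted sweep regions plus per-site group allele
#'   frequencies), and — when `dir` is given — `paths`.
#' @examples
#' cfg <- SimGenomeConfig(nChrom = 1, chromLength = 2e5, nSnpsPerChrom = 100,
#'                        seed = 7)
#' sim <- simulateGenotypes(cfg)
#' sim$genotypes
#' @export
simulateGenotypes <- function(config, dir = NULL) {
  stopifnot(is(config, "SimGenomeConfig"))
  validObject(config)
  chromLens <- simChromLengths(config)
  sweeps <- sweepRegionsGRanges(config)
  nHigh <- config@nHigh; nNone <- config@nNone

  sim <- withSeed(config@seed, {
    chroms <- character(0); pos <- integer(0)
    for (chr in names(chromLens)) {
      p <- sort(sample.int(chromLens[[chr]], config@nSnpsPerChrom))
      chroms <- c(chroms, rep(chr, length(p)))
      pos <- c(pos, p)
    }
    n <- length(pos)
    ref <- sample(.VALID_BASES, n, replace = TRUE)
    isTs <- stats::runif(n) < config@tsProb
    tsPartner <- c(A = "G", G = "A", C = "T", T = "C")
    alt <- character(n)
    alt[isTs] <- tsPartner[ref[isTs]]
    for (i in which(!isTs)) {
      choices <- setdiff(.VALID_BASES, c(ref[i], tsPartner[[ref[i]]]))
      alt[i] <- choices[sample.int(2L, 1L)]
    }
    maf <- stats::runif(n, config@mafLower, config@mafUpper)
    pHigh <- maf; pNone <- maf
    if (length(sweeps)) {
      sites <- GRanges(chroms, IRanges(pos, width = 1L))
      hit <- findOverlaps(sites, sweeps)
      idx <- S4Vectors::queryHits(hit)
      pHigh[idx] <- maf[idx] *
        (1 - mcols(sweeps)$reduction[S4Vectors::subjectHits(hit)])
    }
    dosage <- matrix(NA_integer_, nrow = n, ncol = nHigh + nNone)
    for (j in seq_len(nHigh))
      dosage[, j] <- stats::rbinom(n, 2L, pHigh)
    for (j in seq_len(nNone))
      dosage[, nHigh + j] <- stats::rbinom(n, 2L, pNone)
    list(chroms = chroms, pos = pos, ref = ref, alt = alt,
         maf = maf, pHigh = pHigh, pNone = pNone, dosage = dosage)
  })

  samples <- c(sprintf("A%d", seq_len(nHigh)), sprintf("N%d", seq_len(nNone)))
  gr <- GRanges(sim$chroms, IRanges(sim$pos, width = 1L),
                ref = sim$ref, alt = sim$alt)
  gr <- setChromLengths(gr, chromLens)
  colnames(sim$dosage) <- samples
  gm <- GenotypeMatrix(gr, sim$dosage,
                       group = rep(c("high", "none"), c(nHigh, nNone)))
  truth <- list(
    sweep_regions = config@sweepRegions,
    sites = data.frame(chrom = sim$chroms, pos = sim$pos,
                       ref = sim$ref, alt = sim$alt, maf = sim$maf,
                       p_high = sim$pHigh, p_none = sim$pNone,
                       stringsAsFactors = FALSE))
  out <- list(genotypes = gm, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    vcf <- file.path(dir, "panel.vcf")
    groups <- file.path(dir, "groups.tsv")
    truthPath <- file.path(dir, "truth.json")
    writeSimVcf(gm, vcf, sweepRegions = config@sweepRegions)
    writeTsv(data.frame(sample_id = samples,
                        group = rep(c("high", "none"), c(nHigh, nNone))),
             groups)
    jsonlite::write_json(
      list(sweep_regions = config@sweepRegions,
           sites = truth$sites,
           seed = config@seed),
      truthPath, digits = NA, auto_unbox = TRUE)
    out$paths <- c(vcf = vcf, groups = groups, truth = truthPath)
  }
  out
}

#' Write a GenotypeMatrix as a minimal, deterministic VCF 4.2 file
#'
#' Emits contig headers, a GT-only FORMAT, and (optionally) the planted
#' sweep regions as `##sweepscreen_sweep_region` header lines so simulated
#' fixtures are self-describing. Output bytes depend only on the object.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @param sweepRegions optional data.frame (chrom, start, end, reduction).
#' @return `path`, invisibly.
#' @export
writeSimVcf <- function(gm, path, sweepRegions = NULL) {
  gr <- snpRanges(gm)
  lens <- seqlengths(gr)
  hdr <- c("##fileformat=VCFv4.2", "##source=sweepscreen")
  for (chr in seqlevels(gr))
    hdr <- c(hdr, sprintf("##contig=<ID=%s%s>", chr,
                          if (is.na(lens[[chr]])) ""
                          else sprintf(",length=%d", lens[[chr]])))
  if (!is.null(sweepRegions) && nrow(sweepRegions))
    hdr <- c(hdr, sprintf("##sweepscreen_sweep_region=%s:%d-%d:%s",
                          sweepRegions$chrom, as.integer(sweepRegions$start),
                          as.integer(sweepRegions$end),
                          format(sweepRegions$reduction)))
  hdr <- c(hdr,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gm)), collapse = "\t"))
  d <- genoDosage(gm)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  body <- paste(as.character(seqnames(gr)), start(gr), ".",
                mcols(gr)$ref, mcols(gr)$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Recover planted sweep regions from a simulated VCF header
#'
#' @param path VCF written by [writeSimVcf()] with sweep-region header
#'   lines.
#' @return data.frame with columns chrom, start, end, reduction (0 rows if
#'   none recorded).
#' @export
sweepRegionsFromVcf <- function(path) {
  lines <- grep("^##sweepscreen_sweep_region=", readLines(path), value = TRUE)
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), reduction = numeric()))
  m <- regmatches(lines,
                  regexec("=([^:]+):([0-9]+)-([0-9]+):([0-9.eE+-]+)$", lines))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             reduction = as.numeric(vapply(m, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Simulate a gene annotation over the synthetic genome
#'
#' Places non-overlapping gene intervals with stable identifiers and random
#' strand. One gene is forced inside every planted sweep region so
#' downstream gene-overlap reports always have a recoverable target.
#'
#' @param config the [SimGenomeConfig-class] that defines the genome.
#' @param nGenes total number of genes (>= number of sweep regions).
#' @param seed RNG seed for placement.
#' @param path optional GFF3 output path.
#' @param geneLength range (bp) gene lengths are drawn from.
#' @return A `GRanges` of genes with metadata columns `ID` and
#'   `description`, sorted by (chrom, start).
#' @export
simulateGff <- function(config, nGenes, seed, path = NULL,
                        geneLength = c(2000L, 6000L)) {
  stopifnot(is(config, "SimGenomeConfig"), nGenes >= 1L)
  chromLens <- simChromLengths(config)
  sweeps <- sweepRegionsGRanges(config)
  if (nGenes < length(sweeps))
    stop("nGenes must be at least the number of sweep regions")
  mkGr <- function(chr, start, len)
    GRanges(factor(chr, names(chromLens)), IRanges(start, width = len))
  genes <- withSeed(seed, {
    placed <- mkGr(character(0), integer(0), integer(0))
    lens <- sample(seq(geneLength[1], geneLength[2]), nGenes, replace = TRUE)
    # one gene per sweep region first
    for (i in seq_along(sweeps)) {
      reg <- sweeps[i]
      len <- min(lens[i], width(reg))
      lo <- start(reg)
      hi <- end(reg) - len + 1L
      s <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      placed <- c(placed, mkGr(as.character(seqnames(reg)), s, len))
    }
    tries <- 0L
    while (length(placed) < nGenes) {
      tries <- tries + 1L
      if (tries > 200L * nGenes)
        stop("genome too small to place ", nGenes, " non-overlapping genes")
      chr <- sample(names(chromLens), 1L)
      len <- lens[length(placed) + 1L]
      if (chromLens[[chr]] < len) next
      s <- sample.int(chromLens[[chr]] - len + 1L, 1L)
      cand <- mkGr(chr, s, len)
      if (!length(findOverlaps(cand, placed)))
        placed <- c(placed, cand)
    }
    strand(placed) <- sample(c("+", "-"), nGenes, replace = TRUE)
    placed
  })
  genes <- setChromLengths(genes, chromLens)
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  mcols(genes)$ID <- sprintf("gene%04d", seq_len(nGenes))
  mcols(genes)$description <- sprintf("simulated gene %d", seq_len(nGenes))
  mcols(genes)$type <- "gene"
  if (!is.null(path)) writeGeneModels(genes, path)
  genes
}

#' Simulate per-accession FPKM tables with planted fold changes
#'
#' Emulates a non-replicated RNA-seq design over two accession groups at
#' several time points. Non-DE transcripts have a high/none expected ratio
#' of 1 at every time point; each planted DE transcript carries a constant
#' fold (drawn from `foldRange`, direction up or down) at all time points.
#' Observed FPKM is the expected value times multiplicative log-normal
#' noise with coefficient of variation `noiseCv` (mean 1), floored at
#' `epsilon` so expressed transcripts never report exactly zero.
#'
#' @param nTranscripts number of transcripts.
#' @param deFraction fraction of transcripts planted as DE, in `[0, 1)`.
#' @param foldRange `(low, high)` bounds of the planted fold; `low` must be
#'   at least 2 so planted effects clear the twofold screen.
#' @param nTimepoints time points per accession (default 3).
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param nHigh,nNone accessions per group (defaults 8 and 2).
#' @param seed mandatory RNG seed.
#' @param epsilon FPKM floor for expressed transcripts.
#' @param dir optional directory; writes `fpkm.tsv` (transcript_id,
#'   sample_id, timepoint, fpkm), `rna_groups.tsv` and `de_truth.json`.
#' @return list with `fpkm` (long data.frame), `groups` (data.frame),
#'   `truth` (transcript_id, de, direction, fold) and optional `paths`.
#' @export
simulateExpression <- function(nTranscripts, deFraction, foldRange = c(4, 8),
                               nTimepoints = 3L, noiseCv = 0.2, nHigh = 8L,
                               nNone = 2L, seed, epsilon = 0.001,
                               dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory for simulateExpression")
  if (deFraction < 0 || deFraction >= 1)
    stop("deFraction must lie in [0, 1)")
  if (deFraction > 0 && foldRange[1] < 2)
    stop("foldRange low bound must be >= 2")
  samples <- c(sprintf("AR%d", seq_len(nHigh)), sprintf("NR%d", seq_len(nNone)))
  groups <- data.frame(sample_id = samples,
                       group = rep(c("high", "none"), c(nHigh, nNone)),
                       stringsAsFactors = FALSE)
  txid <- sprintf("tx%05d", seq_len(nTranscripts))
  res <- withSeed(seed, {
    nDe <- round(deFraction * nTranscripts)
    de <- rep(FALSE, nTranscripts); de[seq_len(nDe)] <- TRUE
    direction <- rep("none", nTranscripts)
    if (nDe) direction[seq_len(nDe)] <-
        sample(c("up", "down"), nDe, replace = TRUE)
    fold <- rep(1, nTranscripts)
    if (nDe) fold[seq_len(nDe)] <- stats::runif(nDe, foldRange[1], foldRange[2])
    base <- stats::rlnorm(nTranscripts, meanlog = log(20), sdlog = 1)
    muHigh <- base * ifelse(direction == "up", fold,
                            ifelse(direction == "down", 1 / fold, 1))
    s <- sqrt(log(1 + noiseCv^2))
    noise <- function(n) if (noiseCv == 0) rep(1, n)
      else stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    rows <- vector("list", (nHigh + nNone) * nTimepoints)
    k <- 0L
    for (tp in seq_len(nTimepoints)) {
      for (i in seq_along(samples)) {
        mu <- if (groups$group[i] == "high") muHigh else base
        k <- k + 1L
        rows[[k]] <- data.frame(
          transcript_id = txid, sample_id = samples[i], timepoint = tp,
          fpkm = pmax(mu * noise(nTranscripts), epsilon),
          stringsAsFactors = FALSE)
      }
    }
    list(fpkm = do.call(rbind, rows),
         truth = data.frame(transcript_id = txid, de = de,
                            direction = direction, fold = fold,
                            stringsAsFactors = FALSE))
  })
  out <- list(fpkm = res$fpkm, groups = groups, truth = res$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- c(fpkm = file.path(dir, "fpkm.tsv"),
           groups = file.path(dir, "rna_groups.tsv"),
           truth = file.path(dir, "de_truth.json"))
    writeTsv(res$fpkm, p[["fpkm"]])
    writeTsv(groups, p[["groups"]])
    jsonlite::write_json(res$truth, p[["truth"]], digits = NA,
                         auto_unbox = TRUE)
    out$paths <- p
  }
  out
}
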