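#' Tile or slide fixed-size windows over a genome
#'
#' Windows start at 0, `step`, `2*step`, ... (0-based); a window is emitted
#' iff its start lies inside the chromosome, and its end is clipped at the
#' chromosome length, so the terminal window may be short. `step == size`
#' gives the non-overlapping scheme.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step slide step in bp, `0 < step <= size` (default `size`).
#' @return `GRanges` of windows (1-based inclusive internally) with a
#'   logical metadata column `short` marking clipped terminal windows.
#' @examples
#' makeWindows(c(chr1 = 250000), size = 100000, step = 20000)  # 13 windows
#' @export
makeWindows <- function(chromLengths, size, step = size) {
  if (size <= 0) stop("size must be positive")
  if (step <= 0 || step > size) stop("require 0 < step <= size")
  parts <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    starts0 <- seq(0L, len - 1L, by = as.integer(step))
    data.frame(chr = chr, start = starts0 + 1L,
               end = pmin(starts0 + as.integer(size), len))
  })
  df <- do.call(rbind, parts)
  gr <- GRanges(factor(df$chr, names(chromLengths)),
                IRanges(df$start, df$end))
  gr <- setChromLengths(gr, chromLengths)
  mcols(gr)$short <- width(gr) < as.integer(size)
  gr
}

#' Per-site nucleotide diversity
#'
#' Unbiased average pairwise difference at a bi-allelic site:
#' `2 p (1 - p) n / (n - 1)` with `p` the alternate-allele frequency among
#' `n` called alleles.
#'
#' @param altAlleleCount alternate-allele count(s).
#' @param nAlleles total called alleles (>= 2); vectorized.
#' @return per-site diversity value(s).
#' @examples
#' sitePi(1, 2)   # two sequences that differ -> 1
#' sitePi(0, 10)  # monomorphic -> 0
#' @export
sitePi <- function(altAlleleCount, nAlleles) {
  if (any(nAlleles < 2)) stop("need at least 2 alleles per site")
  if (any(altAlleleCount < 0 | altAlleleCount > nAlleles))
    stop("altAlleleCount must lie in [0, nAlleles]")
  p <- altAlleleCount / nAlleles
  2 * p * (1 - p) * nAlleles / (nAlleles - 1)
}

# Sum a per-site quantity into windows via overlap. Sites in several
# (sliding) windows contribute to each.
.windowSum <- function(siteGr, values, windows) {
  hits <- findOverlaps(siteGr, windows)
  out <- numeric(length(windows))
  if (length(hits)) {
    s <- rowsum(values[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits))
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Windowed nucleotide diversity per bp for one group
#'
#' Sums [sitePi()] over the in-window SNPs of the group and divides by the
#' window span in bp. Sites with fewer than two called alleles in the
#' group are skipped; windows without SNPs return 0.
#'
#' @param gm a [GenotypeMatrix-class] (sites are sorted by construction).
#' @param windows `GRanges` from [makeWindows()].
#' @param group `"high"`, `"none"`, or `"pooled"`.
#' @return numeric vector of per-bp diversity, one value per window.
#' @export
windowPi <- function(gm, windows, group) {
  ac <- alleleCounts(gm, group)
  ok <- ac[, "n_alleles"] >= 2L
  pi <- numeric(nrow(ac))
  pi[ok] <- sitePi(ac[ok, "n_alt"], ac[ok, "n_alleles"])
  .windowSum(snpRanges(gm), pi, windows) / width(windows)
}

#' Reduction of diversity
#'
#' `ROD = 1 - pi_high / pi_none`: values near 1 mean the high group has
#' lost diversity relative to the reference ("none") group, the signature
#' of a selective sweep; `NA` where `pi_none` is 0 (the statistic is
#' undefined and the window carries no contrast).
#'
#' @param piHigh,piNone non-negative per-window diversities (vectorized).
#' @return numeric vector; `rod <= 1` always, 0 when the diversities are
#'   equal.
#' @examples
#' rod(0.001, 0.004)  # 0.75
#' rod(0, 0.004)      # complete sweep -> 1
#' @export
rod <- function(piHigh, piNone) {
  if (any(piHigh < 0, na.rm = TRUE) || any(piNone < 0, na.rm = TRUE))
    stop("diversities must be >= 0")
  ifelse(piNone > 0, 1 - piHigh / piNone, NA_real_)
}

#' Windowed pooled heterozygosity (Hp)
#'
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`, where `S_maj` and `S_min`
#' sum the major- and minor-allele counts of the window's SNPs in the
#' chosen group. Hp lies in `[0, 0.5]`; windows with no scorable SNP
#' return `NA`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param windows `GRanges` of windows.
#' @param group `"high"` (default, the sweep target), `"none"`, or
#'   `"pooled"`.
#' @return numeric vector of Hp values per window.
#' @export
windowHp <- function(gm, windows, group = "high") {
  ac <- alleleCounts(gm, group)
  nMaj <- pmax(ac[, "n_alt"], ac[, "n_alleles"] - ac[, "n_alt"])
  nMin <- pmin(ac[, "n_alt"], ac[, "n_alleles"] - ac[, "n_alt"])
  sMaj <- .windowSum(snpRanges(gm), nMaj, windows)
  sMin <- .windowSum(snpRanges(gm), nMin, windows)
  tot <- sMaj + sMin
  ifelse(tot > 0, 2 * sMaj * sMin / tot^2, NA_real_)
}

#' Z-transform windowed Hp genome-wide
#'
#' Centers and scales Hp by the mean and standard deviation over scored
#' windows, so ZHp has mean 0 and sd 1 there; `NA` windows stay `NA` and
#' are excluded from the moments. Strongly negative ZHp flags candidate
#' sweep windows.
#'
#' @param hp numeric vector of per-window Hp values (may contain `NA`).
#' @return numeric vector of ZHp values.
#' @export
zhpScores <- function(hp) {
  ok <- !is.na(hp)
  if (sum(ok) < 2L) stop("need at least 2 scored windows")
  s <- stats::sd(hp[ok])
  if (s == 0) stop("degenerate scan: all windows have identical Hp")
  (hp - mean(hp[ok])) / s
}

#' Windowed Hudson FST between the two groups
#'
#' Hudson's two-population estimator accumulated as a ratio of sums over
#' the window's SNPs: per site the numerator is
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`; sums are taken separately and divided. Sites
#' need at least two called alleles in each group; windows with no
#' scorable site (or zero denominator) return `NA`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param windows `GRanges` of windows.
#' @return numeric vector of FST values per window.
#' @export
windowFst <- function(gm, windows) {
  acH <- alleleCounts(gm, "high")
  acN <- alleleCounts(gm, "none")
  n1 <- acH[, "n_alleles"]; n2 <- acN[, "n_alleles"]
  ok <- n1 >= 2L & n2 >= 2L
  p1 <- ifelse(ok, acH[, "n_alt"] / n1, NA)
  p2 <- ifelse(ok, acN[, "n_alt"] / n2, NA)
  num <- den <- numeric(length(ok))
  num[ok] <- (p1[ok] - p2[ok])^2 -
    p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
    p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
  den[ok] <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
  sNum <- .windowSum(snpRanges(gm), num, windows)
  sDen <- .windowSum(snpRanges(gm), den, windows)
  ifelse(sDen > 0, sNum / sDen, NA_real_)
}

#' Full per-window statistics table for the sweep scan
#'
#' Computes, for one window scheme, the SNP count, per-group per-bp
#' diversity, ROD, Hp and genome-wide ZHp, and the Hudson FST track.
#' Windows with fewer than `minSnpsPerWindow` SNPs (and, when
#' `dropShortWindows`, clipped terminal windows) are left unscored: their
#' Hp/ZHp/ROD/FST are `NA` and they do not enter the ZHp moments or the
#' ROD quantile downstream.
#'
#' @param gm a filtered [GenotypeMatrix-class].
#' @param cfg a [SweepCallConfig-class].
#' @param windows optional `GRanges`; defaults to
#'   `makeWindows(seqlengths(gm), cfg@windowSize, cfg@step)`.
#' @return the `windows` `GRanges` with metadata columns `n_snps`,
#'   `pi_high`, `pi_none`, `rod`, `hp`, `zhp`, `fst`, `scored`, `short`.
#' @export
windowStats <- function(gm, cfg = SweepCallConfig(), windows = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"), is(cfg, "SweepCallConfig"))
  if (is.null(windows)) {
    lens <- seqlengths(snpRanges(gm))
    if (anyNA(lens))
      stop("genotype object lacks chromosome lengths; supply windows")
    windows <- makeWindows(lens, cfg@windowSize, cfg@step)
  }
  if (is.null(mcols(windows)$short))
    mcols(windows)$short <- FALSE
  nSnps <- countOverlaps(windows, snpRanges(gm))
  scored <- nSnps >= cfg@minSnpsPerWindow
  if (cfg@dropShortWindows) scored <- scored & !mcols(windows)$short
  piH <- windowPi(gm, windows, "high")
  piN <- windowPi(gm, windows, "none")
  rodv <- rod(piH, piN)
  hp <- windowHp(gm, windows, if (cfg@pooledHp) "pooled" else "high")
  hp[!scored] <- NA_real_
  rodv[!scored] <- NA_real_
  zhp <- zhpScores(hp)
  fst <- windowFst(gm, windows)
  fst[!scored] <- NA_real_
  mcols(windows)$n_snps <- nSnps
  mcols(windows)$pi_high <- piH
  mcols(windows)$pi_none <- piN
  mcols(windows)$rod <- rodv
  mcols(windows)$hp <- hp
  mcols(windows)$zhp <- zhp
  mcols(windows)$fst <- fst
  mcols(windows)$scored <- scored
  windows
}

#' Call merged sweep regions from window statistics
#'
#' A scored window is a hit when its ZHp is at or below the threshold, OR
#' when its ROD reaches the empirical upper `(1 - rodQuantileAlpha)`
#' quantile of the defined ROD values, is positive, and the high group's
#' per-bp diversity does not exceed `piMaxForCandidate`. Overlapping or
#' book-ended hit windows on a chromosome merge into maximal regions; a
#' region's ZHp is the minimum over its member windows.
#'
#' @param stats `GRanges` from [windowStats()].
#' @param cfg the [SweepCallConfig-class] used for the scan.
#' @return `GRanges` of merged regions with metadata columns `zhp`
#'   (minimum member ZHp), `n_windows`, and `max_rod`.
#' @export
callSweepRegions <- function(stats, cfg = SweepCallConfig()) {
  if (!length(stats)) return(GRanges())
  m <- mcols(stats)
  rodDefined <- m$rod[!is.na(m$rod)]
  rodCut <- if (length(rodDefined))
    stats::quantile(rodDefined, probs = 1 - cfg@rodQuantileAlpha,
                    names = FALSE, type = 7)
  else Inf
  hitZ <- !is.na(m$zhp) & m$zhp <= cfg@zhpThreshold
  hitR <- !is.na(m$rod) & m$rod >= rodCut & m$rod > 0 &
    m$pi_high <= cfg@piMaxForCandidate
  hit <- m$scored & (hitZ | hitR)
  if (!any(hit)) return(GRanges())
  hits <- stats[hit]
  regions <- reduce(granges(hits), min.gapwidth = 1L)
  ov <- findOverlaps(hits, regions)
  ri <- S4Vectors::subjectHits(ov)
  zmin <- tapply(mcols(hits)$zhp[S4Vectors::queryHits(ov)], ri,
                 function(z) if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE))
  rmax <- tapply(mcols(hits)$rod[S4Vectors::queryHits(ov)], ri,
                 function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  nw <- tapply(ri, ri, length)
  mcols(regions)$zhp <- as.numeric(zmin[as.character(seq_along(regions))])
  mcols(regions)$n_windows <- as.integer(nw[as.character(seq_along(regions))])
  mcols(regions)$max_rod <- as.numeric(rmax[as.character(seq_along(regions))])
  regions
}

#' Overlap called sweep regions with gene models
#'
#' Reports every gene whose interval overlaps a called region by at least
#' 1 bp, annotated with its in-gene SNP count and the ZHp of the region it
#' falls in (the minimum over overlapped regions when a gene spans
#' several). Output order is deterministic: (chrom, start).
#'
#' @param regions `GRanges` from [callSweepRegions()] (merged).
#' @param genes `GRanges` of gene models with metadata columns `ID` and
#'   optionally `description` (see [readGeneModels()]).
#' @param gm optional [GenotypeMatrix-class]; when given, `n_snps_in_gene`
#'   counts the SNPs inside each gene, otherwise it is `NA`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`, `n_snps_in_gene`, `zhp_of_region`,
#'   `description` — the candidate-gene report shape.
#' @export
genesInRegions <- function(regions, genes, gm = NULL) {
  ov <- findOverlaps(genes, regions, minoverlap = 1L)
  idx <- unique(S4Vectors::queryHits(ov))
  if (!length(idx))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_snps_in_gene = integer(),
                      zhp_of_region = numeric(), description = character(),
                      stringsAsFactors = FALSE))
  regZ <- if (!is.null(mcols(regions)$zhp)) mcols(regions)$zhp
          else rep(NA_real_, length(regions))
  zByGene <- tapply(regZ[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(z) if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE))
  sel <- genes[idx]
  nSnp <- if (is.null(gm)) rep(NA_integer_, length(sel))
          else countOverlaps(sel, snpRanges(gm))
  desc <- if (!is.null(mcols(sel)$description)) mcols(sel)$description
          else rep(NA_character_, length(sel))
  out <- data.frame(
    gene_id = as.character(mcols(sel)$ID),
    chrom = as.character(seqnames(sel)),
    start = start(sel), end = end(sel),
    strand = as.character(strand(sel)),
    n_snps_in_gene = as.integer(nSnp),
    zhp_of_region = as.numeric(zByGene[as.character(idx)]),
    description = desc, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}
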