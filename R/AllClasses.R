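#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   strand<- findOverlaps countOverlaps reduce
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqnames<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
NULL

.VALID_BASES <- c("A", "C", "G", "T")
.GROUP_LEVELS <- c("high", "none")

#' GenotypeMatrix: diploid genotypes for a two-group accession panel
#'
#' Container for the per-site diploid genotypes of all samples together with
#' the two-group sample partition that all population statistics contrast.
#' It extends \linkS4class{RangedSummarizedExperiment}: rows are bi-allelic
#' SNP sites (a \link[GenomicRanges]{GRanges} with \code{ref}/\code{alt}
#' metadata columns), columns are samples, and the single \code{"dosage"}
#' assay holds the alternate-allele dosage (0, 1, 2, or \code{NA} for a
#' missing genotype).
#'
#' @slot .. inherited from \code{RangedSummarizedExperiment}; sample groups
#'   live in \code{colData(x)$group} with levels \code{"high"} and
#'   \code{"none"}.
#'
#' @seealso [GenotypeMatrix()] for construction, [readVcfGenotypes()] to
#'   build one from a VCF plus a sample-group table, [genotypeCounts()] and
#'   [alleleCounts()] for the summaries the statistics consume.
#' @export
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  if (!"group" %in% names(colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  else {
    grp <- colData(object)$group
    if (!all(as.character(grp) %in% .GROUP_LEVELS))
      msg <- c(msg, "sample groups must be 'high' or 'none'")
  }
  rr <- rowRanges(object)
  if (length(rr)) {
    if (!all(c("ref", "alt") %in% names(mcols(rr))))
      msg <- c(msg, "rowRanges need 'ref' and 'alt' metadata columns")
    else {
      ref <- mcols(rr)$ref; alt <- mcols(rr)$alt
      if (!all(ref %in% .VALID_BASES) || !all(alt %in% .VALID_BASES))
        msg <- c(msg, "ref and alt must be single bases in {A,C,G,T}")
      else if (any(ref == alt))
        msg <- c(msg, "ref and alt must differ at every site")
    }
    if (any(width(rr) != 1L))
      msg <- c(msg, "SNP sites must have width 1")
    if (is.unsorted(order(as.integer(seqnames(rr)), start(rr))))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
    d <- assays(object)$dosage
    if (!all(d %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param ranges `GRanges` of SNP positions (width 1) with metadata columns
#'   `ref` and `alt` (single bases).
#' @param dosage integer matrix, sites x samples, of alternate-allele
#'   dosages in 0:2; `NA` marks a missing genotype.
#' @param group character or factor of length `ncol(dosage)` with values
#'   `"high"` / `"none"` assigning each sample to an accession group.
#' @param sampleNames optional sample names; defaults to
#'   `colnames(dosage)`.
#' @return A [GenotypeMatrix-class] object, sites sorted by (chrom, pos).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1),
#'                              ref = c("A", "C"), alt = c("G", "T"))
#' d <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' gm <- GenotypeMatrix(gr, d, group = c("high", "none"))
#' @export
GenotypeMatrix <- function(ranges, dosage, group, sampleNames = colnames(dosage)) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sampleNames))
    sampleNames <- paste0("sample", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(NULL, sampleNames)
  group <- factor(as.character(group), levels = .GROUP_LEVELS)
  if (anyNA(group))
    stop("sample groups must be 'high' or 'none'")
  o <- order(as.integer(seqnames(ranges)), start(ranges))
  se <- SummarizedExperiment(
    assays = list(dosage = dosage[o, , drop = FALSE]),
    rowRanges = ranges[o],
    colData = DataFrame(group = group, row.names = sampleNames))
  new("GenotypeMatrix", se)
}

#' Sweep-calling configuration
#'
#' Window scheme and thresholds of the selective-sweep scan. Defaults follow
#' the two-group anthocyanin screen: 100-kb windows sliding by 20 kb, at
#' least 30 SNPs per scored window, ZHp cutoff -1.5, ROD screened at the
#' empirical 99th percentile with a per-bp diversity ceiling of 0.005 in the
#' high group.
#'
#' @slot windowSize window size in bp.
#' @slot step slide step in bp (`step == windowSize` gives tiled windows).
#' @slot minSnpsPerWindow windows with fewer SNPs are left unscored.
#' @slot zhpThreshold call a window when its ZHp is at or below this.
#' @slot rodQuantileAlpha upper-tail mass defining the ROD screen quantile.
#' @slot piMaxForCandidate per-bp diversity ceiling on the high group for
#'   ROD-route candidates.
#' @slot dropShortWindows score clipped terminal windows (`FALSE`, default;
#'   they are flagged) or exclude them.
#' @slot pooledHp compute Hp/ZHp on the pooled sample instead of the high
#'   group.
#' @export
setClass("SweepCallConfig", representation(
  windowSize = "integer", step = "integer", minSnpsPerWindow = "integer",
  zhpThreshold = "numeric", rodQuantileAlpha = "numeric",
  piMaxForCandidate = "numeric", dropShortWindows = "logical",
  pooledHp = "logical"))

setValidity("SweepCallConfig", function(object) {
  msg <- character()
  if (object@windowSize <= 0L) msg <- c(msg, "windowSize must be positive")
  if (object@step <= 0L || object@step > object@windowSize)
    msg <- c(msg, "step must satisfy 0 < step <= windowSize")
  if (object@minSnpsPerWindow < 0L) msg <- c(msg, "minSnpsPerWindow must be >= 0")
  if (!is.finite(object@zhpThreshold)) msg <- c(msg, "zhpThreshold must be finite")
  if (object@rodQuantileAlpha <= 0 || object@rodQuantileAlpha >= 1)
    msg <- c(msg, "rodQuantileAlpha must be in (0, 1)")
  if (object@piMaxForCandidate < 0) msg <- c(msg, "piMaxForCandidate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SweepCallConfig-class
#' @param windowSize,step,minSnpsPerWindow,zhpThreshold,rodQuantileAlpha,piMaxForCandidate,dropShortWindows,pooledHp see slots.
#' @return A `SweepCallConfig`.
#' @export
SweepCallConfig <- function(windowSize = 100000L, step = 20000L,
                            minSnpsPerWindow = 30L, zhpThreshold = -1.5,
                            rodQuantileAlpha = 0.01, piMaxForCandidate = 0.005,
                            dropShortWindows = FALSE, pooledHp = FALSE) {
  new("SweepCallConfig", windowSize = as.integer(windowSize),
      step = as.integer(step), minSnpsPerWindow = as.integer(minSnpsPerWindow),
      zhpThreshold = zhpThreshold, rodQuantileAlpha = rodQuantileAlpha,
      piMaxForCandidate = piMaxForCandidate,
      dropShortWindows = dropShortWindows, pooledHp = pooledHp)
}

#' SNP quality-control configuration
#'
#' Thresholds of the bi-allelic -> HWE -> MAF filter stage. Sites are
#' RETAINED when the pooled Hardy-Weinberg goodness-of-fit p-value is at
#' least `hweAlpha` and the pooled minor-allele frequency is at least
#' `mafMin`; sites with more than `maxMissing` missing genotypes are
#' dropped first.
#'
#' @slot hweAlpha HWE p-value floor (default 0.001).
#' @slot mafMin minor-allele-frequency floor (default 0.1).
#' @slot maxMissing maximum tolerated fraction of missing genotypes per
#'   site (default 0.5).
#' @slot perGroupHwe apply the HWE test within each group (both must pass)
#'   instead of pooled.
#' @slot exactHwe use the exact conditional HWE test instead of the
#'   1-df chi-square.
#' @export
setClass("QcConfig", representation(
  hweAlpha = "numeric", mafMin = "numeric", maxMissing = "numeric",
  perGroupHwe = "logical", exactHwe = "logical"))

setValidity("QcConfig", function(object) {
  msg <- character()
  if (object@hweAlpha <= 0 || object@hweAlpha >= 1)
    msg <- c(msg, "hweAlpha must be in (0, 1)")
  if (object@mafMin < 0 || object@mafMin >= 0.5)
    msg <- c(msg, "mafMin must be in [0, 0.5)")
  if (object@maxMissing < 0 || object@maxMissing > 1)
    msg <- c(msg, "maxMissing must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname QcConfig-class
#' @param hweAlpha,mafMin,maxMissing,perGroupHwe,exactHwe see slots.
#' @return A `QcConfig`.
#' @export
QcConfig <- function(hweAlpha = 0.001, mafMin = 0.1, maxMissing = 0.5,
                     perGroupHwe = FALSE, exactHwe = FALSE) {
  new("QcConfig", hweAlpha = hweAlpha, mafMin = mafMin,
      maxMissing = maxMissing, perGroupHwe = perGroupHwe, exactHwe = exactHwe)
}

#' Expression-screen configuration
#'
#' Parameters of the staged FPKM fold-change screen and its term-set
#' enrichment. A transcript's per-time-point ratio is
#' `(mean FPKM high + pseudocount) / (mean FPKM none + pseudocount)`; a
#' time point passes at `ratio >= foldThreshold` (up) or
#' `ratio <= 1/foldThreshold` (down).
#'
#' @slot foldThreshold fold-change cutoff (default 2).
#' @slot minTimepointsStage2 time points required by the intermediate stage
#'   (default 2 of 3).
#' @slot nTimepoints number of time points (default 3).
#' @slot pseudocount FPKM pseudocount protecting zero denominators
#'   (default 0.01).
#' @slot enrichmentAlpha per-term one-sided Fisher significance level
#'   (default 0.05).
#' @slot nRandomizations label permutations behind the FDR (default 100).
#' @slot fdrAlpha FDR cutoff for reporting (default 0.05).
#' @slot strictDirection require every passing time point to agree in
#'   direction for the staged screens (default TRUE).
#' @slot groupSummary `"mean"` (default) or `"median"` FPKM summary over
#'   the accessions of a group.
#' @export
setClass("ScreenConfig", representation(
  foldThreshold = "numeric", minTimepointsStage2 = "integer",
  nTimepoints = "integer", pseudocount = "numeric",
  enrichmentAlpha = "numeric", nRandomizations = "integer",
  fdrAlpha = "numeric", strictDirection = "logical",
  groupSummary = "character"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@foldThreshold <= 1) msg <- c(msg, "foldThreshold must exceed 1")
  if (object@minTimepointsStage2 > object@nTimepoints)
    msg <- c(msg, "minTimepointsStage2 cannot exceed nTimepoints")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (object@nRandomizations < 1L) msg <- c(msg, "nRandomizations must be >= 1")
  if (!object@groupSummary %in% c("mean", "median"))
    msg <- c(msg, "groupSummary must be 'mean' or 'median'")
  if (length(msg)) msg else TRUE
})

#' @rdname ScreenConfig-class
#' @param foldThreshold,minTimepointsStage2,nTimepoints,pseudocount,enrichmentAlpha,nRandomizations,fdrAlpha,strictDirection,groupSummary see slots.
#' @return A `ScreenConfig`.
#' @export
ScreenConfig <- function(foldThreshold = 2, minTimepointsStage2 = 2L,
                         nTimepoints = 3L, pseudocount = 0.01,
                         enrichmentAlpha = 0.05, nRandomizations = 100L,
                         fdrAlpha = 0.05, strictDirection = TRUE,
                         groupSummary = "mean") {
  new("ScreenConfig", foldThreshold = foldThreshold,
      minTimepointsStage2 = as.integer(minTimepointsStage2),
      nTimepoints = as.integer(nTimepoints), pseudocount = pseudocount,
      enrichmentAlpha = enrichmentAlpha,
      nRandomizations = as.integer(nRandomizations), fdrAlpha = fdrAlpha,
      strictDirection = strictDirection, groupSummary = groupSummary)
}

#' Synthetic-genome configuration
#'
#' Describes the simulated two-group diploid panel: a multi-chromosome
#' genome carrying independently drawn bi-allelic SNPs, with optional
#' planted low-diversity ("sweep") regions in which the high group's
#' minor-allele frequency is scaled down by `reduction`.
#'
#' @slot nChrom number of chromosomes.
#' @slot chromLength chromosome length in bp (all chromosomes equal).
#' @slot nHigh,nNone diploid sample counts per group (each >= 2).
#' @slot nSnpsPerChrom SNP sites drawn per chromosome.
#' @slot mafLower,mafUpper bounds of the uniform distribution the per-site
#'   minor-allele frequency is drawn from.
#' @slot sweepRegions data.frame with columns chrom, start, end (1-based
#'   inclusive bp) and reduction in [0, 1]; reduction 1 makes the high
#'   group monomorphic in the region.
#' @slot tsProb probability a site is a transition (A<->G / C<->T).
#' @slot seed mandatory RNG seed; equal seeds give byte-identical output.
#' @export
setClass("SimGenomeConfig", representation(
  nChrom = "integer", chromLength = "integer", nHigh = "integer",
  nNone = "integer", nSnpsPerChrom = "integer", mafLower = "numeric",
  mafUpper = "numeric", sweepRegions = "data.frame", tsProb = "numeric",
  seed = "integer"))

setValidity("SimGenomeConfig", function(object) {
  msg <- character()
  if (object@nHigh < 2L || object@nNone < 2L)
    msg <- c(msg, "need at least 2 samples per group")
  if (object@mafLower <= 0 || object@mafUpper > 0.5 ||
      object@mafLower >= object@mafUpper)
    msg <- c(msg, "require 0 < mafLower < mafUpper <= 0.5")
  if (object@tsProb < 0 || object@tsProb > 1)
    msg <- c(msg, "tsProb must be in [0, 1]")
  sr <- object@sweepRegions
  if (nrow(sr)) {
    need <- c("chrom", "start", "end", "reduction")
    if (!all(need %in% names(sr)))
      msg <- c(msg, "sweepRegions needs columns chrom, start, end, reduction")
    else {
      chroms <- paste0("chr", seq_len(object@nChrom))
      for (i in seq_len(nrow(sr))) {
        r <- sr[i, ]
        if (!(r$chrom %in% chroms) || r$start < 1 ||
            r$end > object@chromLength || r$end < r$start)
          msg <- c(msg, sprintf(
            "sweep region %s:%d-%d lies outside the genome",
            r$chrom, as.integer(r$start), as.integer(r$end)))
        if (r$reduction < 0 || r$reduction > 1)
          msg <- c(msg, sprintf(
            "sweep region %s:%d-%d has reduction outside [0, 1]",
            r$chrom, as.integer(r$start), as.integer(r$end)))
      }
      o <- sr[order(sr$chrom, sr$start), ]
      same <- which(o$chrom[-1] == o$chrom[-nrow(o)])
      if (any(o$start[same + 1L] <= o$end[same]))
        msg <- c(msg, "sweep regions must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimGenomeConfig-class
#' @param nChrom,chromLength,nHigh,nNone,nSnpsPerChrom,mafLower,mafUpper,sweepRegions,tsProb,seed see slots.
#' @return A `SimGenomeConfig`.
#' @examples
#' cfg <- SimGenomeConfig(nChrom = 2, chromLength = 1e6, seed = 1,
#'                        sweepRegions = data.frame(chrom = "chr1",
#'                          start = 4e5, end = 6e5, reduction = 0.9))
#' @export
SimGenomeConfig <- function(nChrom = 2L, chromLength = 1000000L, nHigh = 8L,
                            nNone = 9L, nSnpsPerChrom = 2000L,
                            mafLower = 0.05, mafUpper = 0.5,
                            sweepRegions = data.frame(), tsProb = 0.7,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory for SimGenomeConfig")
  new("SimGenomeConfig", nChrom = as.integer(nChrom),
      chromLength = as.integer(chromLength), nHigh = as.integer(nHigh),
      nNone = as.integer(nNone), nSnpsPerChrom = as.integer(nSnpsPerChrom),
      mafLower = mafLower, mafUpper = mafUpper,
      sweepRegions = as.data.frame(sweepRegions), tsProb = tsProb,
      seed = as.integer(seed))
}
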