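#' @describeIn GenotypeMatrix-class SNP positions as a `GRanges` with
#'   `ref`/`alt` metadata columns.
#' @export
setMethod("snpRanges", "GenotypeMatrix", function(x) rowRanges(x))

#' @describeIn GenotypeMatrix-class factor of sample groups
#'   (`high`/`none`), named by sample.
#' @export
setMethod("sampleGroups", "GenotypeMatrix", function(x) {
  g <- colData(x)$group
  names(g) <- rownames(colData(x))
  g
})

#' @describeIn GenotypeMatrix-class integer matrix of alternate-allele
#'   dosages (sites x samples).
#' @export
setMethod("genoDosage", "GenotypeMatrix", function(x) assays(x)$dosage)

.groupCols <- function(x, group) {
  group <- match.arg(group, c("pooled", "high", "none"))
  if (group == "pooled") seq_len(ncol(x))
  else which(as.character(colData(x)$group) == group)
}

#' Per-site genotype counts
#'
#' Tallies diploid genotype classes per site for one group or the pooled
#' panel, excluding missing genotypes site-wise.
#'
#' @param x a [GenotypeMatrix-class].
#' @param group `"pooled"` (default), `"high"`, or `"none"`.
#' @return Integer matrix with one row per site and columns `n_homref`,
#'   `n_het`, `n_homalt`.
#' @export
setMethod("genotypeCounts", "GenotypeMatrix", function(x, group = "pooled") {
  d <- genoDosage(x)[, .groupCols(x, group), drop = FALSE]
  cbind(n_homref = rowSums(d == 0L, na.rm = TRUE),
        n_het    = rowSums(d == 1L, na.rm = TRUE),
        n_homalt = rowSums(d == 2L, na.rm = TRUE))
})

#' Per-site allele counts
#'
#' @param x a [GenotypeMatrix-class].
#' @param group `"pooled"` (default), `"high"`, or `"none"`.
#' @return Integer matrix with columns `n_alt` (alternate-allele count) and
#'   `n_alleles` (total called alleles, i.e. twice the non-missing
#'   genotypes).
#' @export
setMethod("alleleCounts", "GenotypeMatrix", function(x, group = "pooled") {
  d <- genoDosage(x)[, .groupCols(x, group), drop = FALSE]
  cbind(n_alt = rowSums(d, na.rm = TRUE),
        n_alleles = 2L * rowSums(!is.na(d)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  g <- table(colData(object)$group)
  cat("GenotypeMatrix with", nrow(object), "SNP sites x",
      ncol(object), "samples\n")
  cat("  groups: high =", g[["high"]], ", none =", g[["none"]], "\n")
  cat("  seqnames:", paste(seqlevels(rowRanges(object)), collapse = ", "),
      "\n")
})

setMethod("show", "SweepCallConfig", function(object) {
  cat("SweepCallConfig\n",
      sprintf("  windows: %d bp, step %d bp; min SNPs/window: %d\n",
              object@windowSize, object@step, object@minSnpsPerWindow),
      sprintf("  ZHp <= %.3g; ROD upper %.3g quantile with pi_high <= %.3g\n",
              object@zhpThreshold, object@rodQuantileAlpha,
              object@piMaxForCandidate),
      sprintf("  Hp on %s group\n",
              if (object@pooledHp) "pooled" else "high"), sep = "")
})

setMethod("show", "QcConfig", function(object) {
  cat(sprintf(
    "QcConfig: keep HWE p >= %g (%s%s), MAF >= %g, missingness <= %g\n",
    object@hweAlpha, if (object@exactHwe) "exact" else "chi-square",
    if (object@perGroupHwe) ", per group" else ", pooled",
    object@mafMin, object@maxMissing))
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: fold >= %g at %d/%d (stage 2) time points, pseudocount %g\n",
    object@foldThreshold, object@minTimepointsStage2, object@nTimepoints,
    object@pseudocount))
  cat(sprintf("  enrichment: one-sided Fisher p <= %g, FDR from %d randomizations\n",
              object@enrichmentAlpha, object@nRandomizations))
})

setMethod("show", "SimGenomeConfig", function(object) {
  cat(sprintf(
    "SimGenomeConfig: %d chrom x %d bp, %d SNPs/chrom, %d high + %d none samples\n",
    object@nChrom, object@chromLength, object@nSnpsPerChrom,
    object@nHigh, object@nNone))
  cat(sprintf("  MAF ~ U(%g, %g); %d planted sweep region(s); seed %d\n",
              object@mafLower, object@mafUpper, nrow(object@sweepRegions),
              object@seed))
})
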