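#' Keep only simple bi-allelic SNPs
#'
#' First stage of the SNP filter: retains records with exactly one
#' alternate allele where both alleles are single nucleotides, preserving
#' record order. Multi-allelic records and indels are dropped and counted.
#'
#' @param vcf a `CollapsedVCF` from [VariantAnnotation::readVcf()].
#' @return list with `vcf` (the filtered object) and `summary` — a
#'   data.frame `(stage, n_in, n_out, n_dropped)`.
#' @export
filterBiallelic <- function(vcf) {
  ref <- VariantAnnotation::ref(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(alt)
  keep <- nAlt == 1L & BiocGenerics::width(ref) == 1L
  altChar <- rep(NA_character_, length(vcf))
  altChar[keep] <- as.character(unlist(alt[keep]))
  keep <- keep & !is.na(altChar) & altChar %in% .VALID_BASES &
    as.character(ref) %in% .VALID_BASES
  list(vcf = vcf[keep],
       summary = data.frame(stage = "biallelic",
                            n_in = length(keep),
                            n_out = sum(keep),
                            n_dropped = sum(!keep),
                            stringsAsFactors = FALSE))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square comparison of observed diploid
#' genotype counts to the proportions expected at the sample allele
#' frequency. Monomorphic sites return p = 1. With `exact = TRUE` the
#' exact conditional test (probability of a heterozygote count at least as
#' improbable as observed, given the allele counts) is used instead.
#'
#' @param counts numeric vector `(n_homref, n_het, n_homalt)` or a matrix
#'   with those three columns (one row per site).
#' @param exact use the exact conditional test.
#' @return p-value(s), one per site.
#' @examples
#' hweTest(c(25, 50, 25))  # exact HWE proportions -> 1
#' hweTest(c(50, 0, 50))   # no heterozygotes -> ~0
#' @export
hweTest <- function(counts, exact = FALSE) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  if (ncol(counts) != 3L) stop("counts must have 3 columns")
  if (any(counts < 0, na.rm = TRUE)) stop("genotype counts must be >= 0")
  if (exact)
    return(vapply(seq_len(nrow(counts)),
                  function(i) .hweExactOne(counts[i, ]), numeric(1)))
  n <- rowSums(counts)
  if (any(n < 1)) stop("each site needs at least one called genotype")
  p <- (counts[, 2L] + 2 * counts[, 3L]) / (2 * n)
  e <- cbind(n * (1 - p)^2, n * 2 * p * (1 - p), n * p^2)
  chi2 <- numeric(nrow(counts))
  for (j in 1:3) {
    ok <- e[, j] > 0
    chi2[ok] <- chi2[ok] + (counts[ok, j] - e[ok, j])^2 / e[ok, j]
  }
  out <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  out
}

# Exact conditional HWE p-value for one site (sum of the probabilities of
# all heterozygote counts no more likely than the observed one, at fixed
# allele counts).
.hweExactOne <- function(cnt) {
  nA <- 2L * cnt[1L] + cnt[2L]   # reference alleles
  nB <- 2L * cnt[3L] + cnt[2L]
  n <- cnt[1L] + cnt[2L] + cnt[3L]
  if (nA == 0L || nB == 0L) return(1)
  rare <- min(nA, nB)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # P(h | nA, nB) = n! 2^h nA! nB! / (nAA! h! nBB! (2n)!)
  logp <- vapply(hets, function(h) {
    nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(cnt[2L], hets)]
  min(1, sum(prob[prob <= obs + 1e-12]))
}

#' Pooled minor-allele frequency per site
#'
#' @param gm a [GenotypeMatrix-class].
#' @param group `"pooled"` (default), `"high"` or `"none"`.
#' @return numeric vector of per-site MAF in `[0, 0.5]`.
#' @export
siteMaf <- function(gm, group = "pooled") {
  ac <- alleleCounts(gm, group)
  p <- ifelse(ac[, "n_alleles"] > 0, ac[, "n_alt"] / ac[, "n_alleles"], NA)
  pmin(p, 1 - p)
}

#' Apply the HWE/MAF quality-control stage
#'
#' Reduces a bi-allelic SNP set to the analysis set: drops sites with more
#' than `maxMissing` missing genotypes, then RETAINS sites whose HWE
#' p-value is at least `hweAlpha` and whose pooled minor-allele frequency
#' is at least `mafMin`. The per-filter loss summary uses sequential
#' accounting (missingness, then HWE, then MAF) although retention itself
#' is a conjunction, so the retained set does not depend on filter order.
#'
#' @param gm a [GenotypeMatrix-class] of bi-allelic SNPs.
#' @param cfg a [QcConfig-class].
#' @return list with `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `summary` (`stage`, `n_in`, `n_out`, `n_dropped`).
#' @export
applyQc <- function(gm, cfg = QcConfig()) {
  stopifnot(is(gm, "GenotypeMatrix"), is(cfg, "QcConfig"))
  n0 <- nrow(gm)
  missFrac <- rowMeans(is.na(genoDosage(gm)))
  keepMiss <- missFrac <= cfg@maxMissing
  gm1 <- gm[keepMiss, ]
  if (cfg@perGroupHwe) {
    pH <- hweTest(genotypeCounts(gm1, "high"), exact = cfg@exactHwe)
    pN <- hweTest(genotypeCounts(gm1, "none"), exact = cfg@exactHwe)
    hweP <- pmin(pH, pN)
  } else {
    hweP <- hweTest(genotypeCounts(gm1, "pooled"), exact = cfg@exactHwe)
  }
  keepHwe <- hweP >= cfg@hweAlpha
  maf <- siteMaf(gm1)
  keepMaf <- !is.na(maf) & maf >= cfg@mafMin
  keep <- keepHwe & keepMaf
  summary <- data.frame(
    stage = c("missingness", "hwe", "maf"),
    n_in = c(n0, nrow(gm1), sum(keepHwe)),
    n_out = c(nrow(gm1), sum(keepHwe), sum(keep)),
    n_dropped = c(n0 - nrow(gm1), sum(!keepHwe), sum(keepHwe) - sum(keep)),
    stringsAsFactors = FALSE)
  list(genotypes = gm1[keep, ], summary = summary)
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G and C<->T); the four other base pairs are transversions. The
#' classification is symmetric in its arguments.
#'
#' @param ref,alt single bases in `{A, C, G, T}` (vectorized).
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classifySubstitution("A", "G")  # transition
#' classifySubstitution("A", "T")  # transversion
#' @export
classifySubstitution <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt lengths differ")
  if (!all(ref %in% .VALID_BASES) || !all(alt %in% .VALID_BASES))
    stop("bases must be in {A, C, G, T}")
  if (any(ref == alt)) stop("ref and alt must differ (not a substitution)")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ifelse(purine[ref] == purine[alt], "transition", "transversion")
}

#' Transition/transversion ratio from category counts
#'
#' @param nTs,nTv transition and transversion counts.
#' @return `nTs / nTv`, or `NA` when there are no transversions.
#' @examples
#' tsTvRatio(557573, 232492)  # ~2.398
#' @export
tsTvRatio <- function(nTs, nTv) {
  if (nTs < 0 || nTv < 0) stop("counts must be >= 0")
  if (nTv == 0) return(NA_real_)
  nTs / nTv
}

#' Transition/transversion summary of a SNP set
#'
#' @param gm a [GenotypeMatrix-class].
#' @return list with `n_ts`, `n_tv`, and `ratio` (NA when `n_tv` is 0).
#' @export
tstvSummary <- function(gm) {
  gr <- snpRanges(gm)
  cls <- classifySubstitution(mcols(gr)$ref, mcols(gr)$alt)
  nTs <- sum(cls == "transition")
  nTv <- sum(cls == "transversion")
  list(n_ts = nTs, n_tv = nTv, ratio = tsTvRatio(nTs, nTv))
}
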