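test_that("window schemes tile and slide as specified", {
  w <- makeWindows(c(chr1 = 250000L), size = 100000L, step = 20000L)
  expect_length(w, 13L)
  expect_equal(GenomicRanges::start(w)[1], 1L)
  expect_equal(GenomicRanges::end(w)[1], 100000L)
  expect_equal(GenomicRanges::start(w)[13], 240001L)
  expect_equal(GenomicRanges::end(w)[13], 250000L)  # clipped terminal
  expect_true(S4Vectors::mcols(w)$short[13])
  expect_length(makeWindows(c(chr1 = 100000L), 100000L, 100000L), 1L)
  expect_length(makeWindows(c(chr1 = 1000000L), 5000L), 200L)
  expect_error(makeWindows(c(chr1 = 1e5), 1000L, 2000L), "step")
})

test_that("per-site diversity equals the pairwise-difference oracle", {
  expect_equal(sitePi(1, 2), 1.0)
  expect_equal(sitePi(0, 10), 0.0)
  expect_error(sitePi(1, 1), "at least 2")
  expect_error(sitePi(5, 4), "altAlleleCount")
  set.seed(2)
  for (i in 1:20) {
    n <- 10L
    ac <- sample(0:n, 1)
    alleles <- c(rep(1, ac), rep(0, n - ac))
    diffs <- outer(alleles, alleles, "!=")
    oracle <- sum(diffs[upper.tri(diffs)]) / choose(n, 2)
    expect_equal(sitePi(ac, n), oracle)
  }
})

test_that("windowed diversity matches hand arithmetic and the haplotype oracle", {
  # one site, p = 0.5 among 4 alleles, span 1000 bp
  gm1 <- makeGm(500L, matrix(c(1L, 1L, 0L, 0L), nrow = 1),
                group = c("high", "high", "none", "none"),
                chromLength = 1000L)
  w1 <- makeWindows(c(chr1 = 1000L), 1000L)
  expect_equal(windowPi(gm1, w1, "high"), (2 * 0.25 * 4 / 3) / 1000,
               tolerance = 1e-12)
  expect_equal(windowPi(gm1, w1, "none"), 0)  # monomorphic in none
  # empty window
  empty <- GenomicRanges::GRanges("chr1", IRanges::IRanges(601L, 900L))
  expect_equal(windowPi(gm1, empty, "high"), 0)
  # 5-site toy vs brute-force allele-pair comparison, per group and pooled
  set.seed(8)
  dos <- matrix(sample(0:2, 5 * 6, replace = TRUE), nrow = 5)
  gm <- makeGm(c(50L, 120L, 300L, 410L, 990L), dos,
               group = rep(c("high", "none"), each = 3),
               chromLength = 1000L)
  w <- makeWindows(c(chr1 = 1000L), 1000L)
  grp <- sampleGroups(gm)
  for (g in c("high", "none")) {
    oracle <- bruteForcePi(genoDosage(gm)[, grp == g, drop = FALSE], 1000)
    expect_equal(windowPi(gm, w, g), oracle, tolerance = 1e-12)
  }
  expect_equal(windowPi(gm, w, "pooled"),
               bruteForcePi(genoDosage(gm), 1000), tolerance = 1e-12)
})

test_that("ROD follows its defining arithmetic and is scale-invariant", {
  expect_equal(rod(0.002, 0.002), 0)
  expect_equal(rod(0, 0.004), 1)
  expect_equal(rod(0.001, 0.004), 0.75)
  expect_true(is.na(rod(0.001, 0)))
  expect_error(rod(-0.1, 0.2), ">= 0")
  set.seed(5)
  for (i in 1:20) {
    x <- stats::runif(2, 0, 0.01); cc <- stats::runif(1, 0.1, 10)
    expect_equal(rod(x[1], x[2]), rod(cc * x[1], cc * x[2]),
                 tolerance = 1e-12)
    expect_lte(rod(x[1], x[2]), 1)
  }
})

test_that("pooled heterozygosity matches the allele-count formula", {
  w <- makeWindows(c(chr1 = 1000L), 1000L)
  # every SNP at 50/50 -> maximum Hp = 0.5
  gmMax <- makeGm(c(100L, 200L), rbind(c(1L, 1L), c(1L, 1L)),
                  group = c("high", "none"), chromLength = 1000L)
  expect_equal(windowHp(gmMax, w, "pooled"), 0.5)
  # monomorphic in the group -> 0
  gmMono <- makeGm(c(100L, 200L), rbind(c(0L, 2L), c(0L, 2L)),
                   group = c("high", "none"), chromLength = 1000L)
  expect_equal(windowHp(gmMono, w, "high"), 0)
  # 3-SNP toy with (major, minor) counts (9,1), (8,2), (7,3) -> 0.32
  dos <- rbind(c(1L, 0L, 0L, 0L, 0L),
               c(2L, 0L, 0L, 0L, 0L),
               c(2L, 1L, 0L, 0L, 0L))
  gm <- makeGm(c(10L, 20L, 30L), dos, group = rep("high", 5),
               chromLength = 1000L)
  expect_error(validObject(gm), NA)
  expect_equal(windowHp(gm, w, "high"), 2 * 24 * 6 / 30^2)
  # no SNPs in window -> NA
  empty <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 900L))
  expect_true(is.na(windowHp(gm, empty, "high")))
})

test_that("ZHp standardizes scored windows and rejects degenerate scans", {
  hp <- c(0.1, 0.2, NA, 0.3, 0.4, 0.15)
  z <- zhpScores(hp)
  ok <- !is.na(hp)
  expect_equal(mean(z[ok]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z[ok]), 1, tolerance = 1e-12)
  expect_true(is.na(z[3]))
  # hand-computed z-scores for a 5-value toy
  hp5 <- c(0.10, 0.20, 0.30, 0.40, 0.50)
  expect_equal(zhpScores(hp5),
               (hp5 - 0.30) / sqrt(sum((hp5 - 0.30)^2) / 4))
  expect_error(zhpScores(c(0.2, 0.2, 0.2)), "degenerate")
  expect_error(zhpScores(c(0.2, NA)), "at least 2")
})

test_that("Hudson FST hits its landmarks and the hand formula", {
  w <- makeWindows(c(chr1 = 1000L), 1000L)
  # complete differentiation
  gmFix <- makeGm(c(100L), matrix(c(2L, 2L, 0L, 0L), nrow = 1),
                  group = c("high", "high", "none", "none"),
                  chromLength = 1000L)
  expect_equal(windowFst(gmFix, w), 1)
  # identical frequencies -> ~0 (estimator is unbiased, small negative ok)
  set.seed(3)
  dos <- t(vapply(stats::runif(40, 0.2, 0.5),
                  function(p) stats::rbinom(20, 2, p), numeric(20)))
  gmEq <- makeGm(seq_len(40) * 20L, dos, group = rep(c("high", "none"), 10),
                 chromLength = 1000L)
  expect_lt(abs(windowFst(gmEq, w)), 0.1)
  # single-site toy: p1 = 0.2 (n1 = 20 alleles), p2 = 0.8 (n2 = 20)
  dos1 <- matrix(c(rep(0L, 6), rep(1L, 4), rep(2L, 6), rep(1L, 4)), nrow = 1)
  gm1 <- makeGm(100L, dos1, group = rep(c("high", "none"), each = 10),
                chromLength = 1000L)
  num <- (0.2 - 0.8)^2 - 0.2 * 0.8 / 19 - 0.8 * 0.2 / 19
  den <- 0.2 * 0.2 + 0.8 * 0.8
  expect_equal(windowFst(gm1, w), num / den, tolerance = 1e-12)
  # no scorable sites -> NA
  empty <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 900L))
  expect_true(is.na(windowFst(gm1, empty)))
})

test_that("non-overlapping windows partition the SNPs", {
  sim <- simulateGenotypes(SimGenomeConfig(nChrom = 2, chromLength = 3e5,
                                           nSnpsPerChrom = 500L, seed = 27))
  cfg <- SweepCallConfig(windowSize = 50000L, step = 50000L,
                         minSnpsPerWindow = 0L)
  st <- windowStats(sim$genotypes, cfg)
  byChrom <- tapply(S4Vectors::mcols(st)$n_snps,
                    as.character(GenomicRanges::seqnames(st)), sum)
  expect_equal(as.vector(byChrom[c("chr1", "chr2")]), c(500, 500))
})

test_that("hit windows merge into maximal regions with min member ZHp", {
  stats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1L, 20001L, 300001L), width = 100000L))
  S4Vectors::mcols(stats) <- S4Vectors::DataFrame(
    short = FALSE, n_snps = 50L, pi_high = c(0.001, 0.001, 0.004),
    pi_none = 0.004, rod = c(0.75, 0.75, 0), hp = 0.1,
    zhp = c(-2.0, -1.8, 0.5), fst = 0.1, scored = TRUE)
  cfg <- SweepCallConfig(minSnpsPerWindow = 0L)
  reg <- callSweepRegions(stats, cfg)
  expect_length(reg, 1L)
  expect_equal(GenomicRanges::start(reg), 1L)
  expect_equal(GenomicRanges::end(reg), 120000L)
  expect_equal(S4Vectors::mcols(reg)$zhp, -2.0)
  expect_equal(S4Vectors::mcols(reg)$n_windows, 2L)
  # nothing passes either rule -> empty
  S4Vectors::mcols(stats)$zhp <- 0
  S4Vectors::mcols(stats)$rod <- NA_real_
  expect_length(callSweepRegions(stats, cfg), 0L)
})

test_that("unscored windows cannot seed sweep calls", {
  stats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1L, 100001L), width = 100000L))
  S4Vectors::mcols(stats) <- S4Vectors::DataFrame(
    short = FALSE, n_snps = c(5L, 50L), pi_high = 0.001, pi_none = 0.004,
    rod = c(NA_real_, 0.2), hp = c(NA_real_, 0.1),
    zhp = c(NA_real_, -3), fst = 0.1, scored = c(FALSE, TRUE))
  reg <- callSweepRegions(stats, SweepCallConfig(minSnpsPerWindow = 30L))
  expect_equal(GenomicRanges::start(reg), 100001L)
})

test_that("gene overlap reports genes in called regions with SNP tallies", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 5000L),
                                    zhp = -2.1)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(500L, 4800L, 9000L), width = 1000L),
    strand = c("+", "-", "+"),
    ID = c("gA", "gB", "gC"),
    description = c("inside-left", "spans-right-edge", "outside"))
  pos <- c(600L, 1200L, 4900L, 5600L, 9500L)
  gm <- makeGm(pos, matrix(1L, length(pos), 4),
               group = rep(c("high", "none"), 2), chromLength = 10000L)
  rep <- genesInRegions(regions, genes, gm)
  expect_equal(rep$gene_id, c("gA", "gB"))   # gC absent
  expect_equal(rep$zhp_of_region, c(-2.1, -2.1))
  # brute-force containment count
  for (i in seq_len(nrow(rep))) {
    g <- genes[match(rep$gene_id[i], S4Vectors::mcols(genes)$ID)]
    expect_equal(rep$n_snps_in_gene[i],
                 sum(pos >= GenomicRanges::start(g) &
                       pos <= GenomicRanges::end(g)))
  }
  # deterministic order by (chrom, start)
  expect_true(!is.unsorted(rep$start))
})

test_that("a planted sweep is recovered by the full scan", {
  cfg <- SimGenomeConfig(
    nChrom = 2, chromLength = 1000000L, nSnpsPerChrom = 1500L, seed = 77,
    sweepRegions = data.frame(chrom = "chr1", start = 400001,
                              end = 600000, reduction = 0.9))
  sim <- simulateGenotypes(cfg)
  scfg <- SweepCallConfig(minSnpsPerWindow = 10L)
  st <- windowStats(sim$genotypes, scfg)
  reg <- callSweepRegions(st, scfg)
  truth <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400001L, 600000L))
  expect_true(length(reg) >= 1L)
  expect_true(any(GenomicRanges::countOverlaps(truth, reg) > 0))
})
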