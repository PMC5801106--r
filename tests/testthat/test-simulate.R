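test_that("equal seeds give byte-identical VCF output", {
  cfg <- SimGenomeConfig(nChrom = 1, chromLength = 200000L,
                         nSnpsPerChrom = 200L, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateGenotypes(cfg, dir = d1)
  simulateGenotypes(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "panel.vcf")),
                   readLines(file.path(d2, "panel.vcf")))
})

test_that("a complete sweep leaves the high group monomorphic reference", {
  cfg <- SimGenomeConfig(
    nChrom = 1, chromLength = 500000L, nSnpsPerChrom = 500L, seed = 3,
    sweepRegions = data.frame(chrom = "chr1", start = 100001,
                              end = 300000, reduction = 1.0))
  sim <- simulateGenotypes(cfg)
  gm <- sim$genotypes
  gr <- snpRanges(gm)
  inRegion <- GenomicRanges::start(gr) >= 100001 &
    GenomicRanges::start(gr) <= 300000
  highDos <- genoDosage(gm)[, sampleGroups(gm) == "high", drop = FALSE]
  expect_true(all(highDos[inRegion, ] == 0L))
  # pi_high = 0 there, so ROD = 1 on any in-region window with none-group SNPs
  w <- makeWindows(c(chr1 = 500000L), 100000L)
  piH <- windowPi(gm, w, "high")
  piN <- windowPi(gm, w, "none")
  inner <- GenomicRanges::start(w) >= 100001 & GenomicRanges::end(w) <= 300000
  expect_true(all(piH[inner] == 0))
  expect_true(all(rod(piH, piN)[inner] == 1))
})

test_that("zero diversity reduction is indistinguishable from no sweep", {
  # "sweep" region with reduction 0: windowed ROD inside vs outside should
  # not differ (two-sample test at ~50 windows)
  cfg <- SimGenomeConfig(
    nChrom = 1, chromLength = 1000000L, nSnpsPerChrom = 2000L, seed = 41,
    sweepRegions = data.frame(chrom = "chr1", start = 200001,
                              end = 450000, reduction = 0.0))
  sim <- simulateGenotypes(cfg)
  w <- makeWindows(c(chr1 = 1000000L), 20000L)
  rodv <- rod(windowPi(sim$genotypes, w, "high"),
              windowPi(sim$genotypes, w, "none"))
  inside <- GenomicRanges::start(w) >= 200001 &
    GenomicRanges::end(w) <= 450000
  expect_gt(stats::wilcox.test(rodv[inside], rodv[!inside])$p.value, 0.01)
})

test_that("drawn minor-allele frequencies follow the configured distribution", {
  mafs <- unlist(lapply(1:10, function(s) {
    cfg <- SimGenomeConfig(nChrom = 1, chromLength = 100000L,
                           nSnpsPerChrom = 100L, seed = s)
    simulateGenotypes(cfg)$truth$sites$maf
  }))
  ks <- suppressWarnings(stats::ks.test(mafs, "punif", 0.05, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("realized heterozygosity matches 2p(1-p) outside sweeps", {
  cfg <- SimGenomeConfig(nChrom = 1, chromLength = 500000L, nHigh = 20L,
                         nNone = 20L, nSnpsPerChrom = 2000L, seed = 13)
  sim <- simulateGenotypes(cfg)
  hetFreq <- rowMeans(genoDosage(sim$genotypes) == 1L)
  expected <- 2 * sim$truth$sites$maf * (1 - sim$truth$sites$maf)
  # Monte-Carlo error of the mean over 2000 sites x 40 samples
  expect_lt(abs(mean(hetFreq) - mean(expected)), 0.005)
})

test_that("planted sweep regions are recoverable from the VCF header", {
  regions <- data.frame(chrom = c("chr1", "chr2"),
                        start = c(10001L, 50001L),
                        end = c(60000L, 90000L),
                        reduction = c(0.9, 0.5))
  cfg <- SimGenomeConfig(nChrom = 2, chromLength = 100000L,
                         nSnpsPerChrom = 50L, sweepRegions = regions,
                         seed = 5)
  d <- withr::local_tempdir()
  simulateGenotypes(cfg, dir = d)
  rec <- sweepRegionsFromVcf(file.path(d, "panel.vcf"))
  expect_equal(rec$chrom, regions$chrom)
  expect_equal(rec$start, regions$start)
  expect_equal(rec$end, regions$end)
  expect_equal(rec$reduction, regions$reduction)
})

test_that("invalid sweep regions are rejected naming the region", {
  expect_error(
    SimGenomeConfig(nChrom = 1, chromLength = 100000L, seed = 1,
                    sweepRegions = data.frame(chrom = "chr1", start = 50000,
                                              end = 200000, reduction = 0.5)),
    "chr1:50000-200000")
  expect_error(
    SimGenomeConfig(nChrom = 1, chromLength = 100000L, seed = 1,
                    sweepRegions = data.frame(chrom = "chr9", start = 1,
                                              end = 10, reduction = 0.5)),
    "outside the genome")
  expect_error(SimGenomeConfig(nChrom = 1, chromLength = 1e5), "seed")
})

test_that("simulated annotation places genes as requested", {
  cfg <- SimGenomeConfig(
    nChrom = 1, chromLength = 100000L, nSnpsPerChrom = 10L, seed = 2,
    sweepRegions = data.frame(chrom = "chr1", start = 40001, end = 60000,
                              reduction = 0.8))
  # a single gene must land inside the single sweep region
  g1 <- simulateGff(cfg, nGenes = 1, seed = 9)
  expect_gte(GenomicRanges::start(g1), 40001)
  expect_lte(GenomicRanges::end(g1), 60000)
  # gene count and GFF round-trip
  d <- withr::local_tempdir()
  path <- file.path(d, "genes.gff3")
  g <- simulateGff(cfg, nGenes = 12, seed = 9, path = path)
  expect_length(g, 12)
  g2 <- readGeneModels(path)
  expect_equal(GenomicRanges::start(g2), GenomicRanges::start(g))
  expect_equal(GenomicRanges::end(g2), GenomicRanges::end(g))
  expect_equal(as.character(GenomicRanges::strand(g2)),
               as.character(GenomicRanges::strand(g)))
  expect_equal(S4Vectors::mcols(g2)$ID, S4Vectors::mcols(g)$ID)
  # impossible placement errors out
  tiny <- SimGenomeConfig(nChrom = 1, chromLength = 10000L,
                          nSnpsPerChrom = 5L, seed = 2)
  expect_error(simulateGff(tiny, nGenes = 100, seed = 1,
                           geneLength = c(2000L, 6000L)),
               "too small")
})

test_that("noiseless expression simulation separates DE from null exactly", {
  ex <- simulateExpression(nTranscripts = 120, deFraction = 0.25,
                           noiseCv = 0, seed = 17)
  rec <- summarizeExpression(ex$fpkm, ex$groups, ScreenConfig())
  hits <- screenStage(rec, "all", ScreenConfig())$transcript_id
  expect_setequal(hits, ex$truth$transcript_id[ex$truth$de])
  # planted direction is recovered too
  reg <- classifyRegulation(rec[match(hits, rec$transcript_id), ],
                            ScreenConfig())
  expect_equal(reg, ex$truth$direction[match(hits, ex$truth$transcript_id)])
})

test_that("deFraction 0 yields an empty noiseless DEG list", {
  ex <- simulateExpression(nTranscripts = 60, deFraction = 0, noiseCv = 0,
                           seed = 8)
  rec <- summarizeExpression(ex$fpkm, ex$groups, ScreenConfig())
  expect_equal(nrow(screenStage(rec, "any", ScreenConfig())), 0L)
  expect_error(simulateExpression(10, deFraction = 1.2, seed = 1),
               "deFraction")
  expect_error(simulateExpression(10, deFraction = 0.5,
                                  foldRange = c(1.5, 3), seed = 1),
               "foldRange")
  # expressed transcripts never report exactly zero
  ex2 <- simulateExpression(nTranscripts = 50, deFraction = 0.1,
                            noiseCv = 1.5, seed = 4)
  expect_true(all(ex2$fpkm$fpkm > 0))
})
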