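#' End-to-end pipeline configuration
#'
#' Bundles the input paths, the per-stage configurations, and the seed of
#' one screening run. The object round-trips losslessly through its
#' on-disk JSON form ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @slot vcf,groups,gff,fpkm,rnaGroups,terms,outdir file paths; `gff`,
#'   `fpkm`, `terms` may be empty strings to skip the corresponding arm.
#'   `rnaGroups` defaults to `groups`.
#' @slot qc a [QcConfig-class].
#' @slot sweep a [SweepCallConfig-class].
#' @slot screen a [ScreenConfig-class].
#' @slot seed integer seed for the randomized steps (permutation FDR).
#' @slot trackWindow track export window size in bp (default 5000).
#' @export
setClass("PipelineConfig", representation(
  vcf = "character", groups = "character", gff = "character",
  fpkm = "character", rnaGroups = "character", terms = "character",
  outdir = "character", qc = "QcConfig", sweep = "SweepCallConfig",
  screen = "ScreenConfig", seed = "integer", trackWindow = "integer"))

#' @rdname PipelineConfig-class
#' @param vcf,groups,gff,fpkm,rnaGroups,terms,outdir,qc,sweep,screen,seed,trackWindow see slots.
#' @return A `PipelineConfig`.
#' @export
PipelineConfig <- function(vcf, groups, gff = "", fpkm = "",
                           rnaGroups = groups, terms = "", outdir,
                           qc = QcConfig(), sweep = SweepCallConfig(),
                           screen = ScreenConfig(), seed = 1L,
                           trackWindow = 5000L) {
  new("PipelineConfig", vcf = vcf, groups = groups, gff = gff,
      fpkm = fpkm, rnaGroups = rnaGroups, terms = terms, outdir = outdir,
      qc = qc, sweep = sweep, screen = screen, seed = as.integer(seed),
      trackWindow = as.integer(trackWindow))
}

.slotsToList <- function(obj) {
  out <- lapply(slotNames(obj), function(s) {
    v <- slot(obj, s)
    if (isVirtualClass(class(v)) || is(v, "QcConfig") ||
        is(v, "SweepCallConfig") || is(v, "ScreenConfig"))
      .slotsToList(v)
    else v
  })
  names(out) <- slotNames(obj)
  out
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [PipelineConfig-class].
#' @param path JSON file.
#' @return `path` invisibly (write) or a [PipelineConfig-class] (read).
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(.slotsToList(config), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  PipelineConfig(
    vcf = x$vcf, groups = x$groups, gff = x$gff, fpkm = x$fpkm,
    rnaGroups = x$rnaGroups, terms = x$terms, outdir = x$outdir,
    qc = do.call(QcConfig, x$qc),
    sweep = do.call(SweepCallConfig, x$sweep),
    screen = do.call(ScreenConfig, x$screen),
    seed = x$seed, trackWindow = x$trackWindow)
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full two-arm screen
#'
#' Executes QC, the sweep scan, and (when an FPKM table is configured) the
#' staged expression screen with enrichment, writing every report plus a
#' JSON run manifest under `outdir`. Reports are deterministic given the
#' same inputs, configuration, and seed.
#'
#' Outputs: `qc_summary.tsv`, `window_stats.tsv`, `regions.bed`,
#' `candidate_genes.tsv`, `tstv.tsv`, track files under `tracks/`,
#' `deg_stage_*.tsv`, `deg_report.tsv`, `enrichment.tsv`, and
#' `manifest.json`.
#'
#' @param config a [PipelineConfig-class].
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  outdir <- config@outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  counts <- list()
  inputs <- c(vcf = config@vcf, groups = config@groups)

  gm <- .stage("read_vcf", readVcfGenotypes(config@vcf, config@groups))
  counts$sites_biallelic <- nrow(gm)

  qcRes <- .stage("qc", applyQc(gm, config@qc))
  gmQc <- qcRes$genotypes
  counts$sites_after_qc <- nrow(gmQc)
  qcSummary <- rbind(metadata(gm)$filter_summary, qcRes$summary)
  writeReport(qcSummary, file.path(outdir, "qc_summary.tsv"),
              convention = "counts")
  ts <- tstvSummary(gmQc)
  writeReport(data.frame(n_ts = ts$n_ts, n_tv = ts$n_tv,
                         ratio = round(ts$ratio, 3)),
              file.path(outdir, "tstv.tsv"), convention = "counts")

  stats <- .stage("scan", windowStats(gmQc, config@sweep))
  writeWindowStats(stats, file.path(outdir, "window_stats.tsv"))
  regions <- .stage("scan", callSweepRegions(stats, config@sweep))
  counts$sweep_regions <- length(regions)
  writeRegionsBed(regions, file.path(outdir, "regions.bed"))
  .stage("tracks", exportTracks(gmQc, file.path(outdir, "tracks"),
                                size = config@trackWindow))

  if (nzchar(config@gff)) {
    inputs["gff"] <- config@gff
    genes <- .stage("genes", readGeneModels(config@gff))
    report <- .stage("genes", genesInRegions(regions, genes, gmQc))
    counts$candidate_genes <- nrow(report)
    writeReport(report, file.path(outdir, "candidate_genes.tsv"))
  }

  if (nzchar(config@fpkm)) {
    inputs["fpkm"] <- config@fpkm
    fpkm <- .stage("degs", readFpkm(config@fpkm))
    rnaGroups <- .stage("degs", readGroups(config@rnaGroups))
    records <- .stage("degs",
                      summarizeExpression(fpkm, rnaGroups, config@screen))
    s1 <- screenStage(records, "any", config@screen)
    s2 <- screenStage(records, "at_least_k", config@screen)
    s3 <- screenStage(records, "all", config@screen)
    counts$deg_stage_any <- nrow(s1)
    counts$deg_stage_at_least_k <- nrow(s2)
    counts$deg_stage_all <- nrow(s3)
    writeReport(s1, file.path(outdir, "deg_stage_any.tsv"),
                convention = "ratios high/none")
    writeReport(s2, file.path(outdir, "deg_stage_at_least_k.tsv"),
                convention = "ratios high/none")
    ratios <- .ratioMatrix(s3)
    report <- data.frame(
      transcript_id = s3$transcript_id,
      regulation = classifyRegulation(s3, config@screen),
      stringsAsFactors = FALSE)
    report <- cbind(report, as.data.frame(ratios))
    report$ratio_geom_mean <- exp(rowMeans(log(ratios)))
    writeReport(report, file.path(outdir, "deg_report.tsv"),
                convention = "ratios high/none")
    counts$deg_up <- sum(report$regulation == "up")
    counts$deg_down <- sum(report$regulation == "down")

    if (nzchar(config@terms)) {
      inputs["terms"] <- config@terms
      terms <- .stage("enrichment", readTermTable(config@terms))
      universe <- records$transcript_id
      enr <- .stage("enrichment",
                    termEnrichment(s2$transcript_id, terms, universe))
      enr <- .stage("enrichment",
                    permutationFdr(enr, terms, universe,
                                   config@screen@nRandomizations,
                                   seed = config@seed))
      counts$terms_tested <- nrow(enr)
      counts$terms_enriched <- sum(
        enr$p <= config@screen@enrichmentAlpha &
          enr$fdr <= config@screen@fdrAlpha)
      writeReport(enr, file.path(outdir, "enrichment.tsv"),
                  convention = "counts")
    }
  }

  manifest <- list(
    tool = "sweepscreen",
    version = as.character(utils::packageVersion("sweepscreen")),
    config_md5 = .md5OfObject(.slotsToList(config)),
    input_md5 = as.list(tools::md5sum(inputs)),
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
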