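# Readers and writers for the formats the pipeline touches. Reports carry
# a comment line stating their coordinate convention; BED is 0-based
# half-open, everything else 1-based inclusive.

#' Read a sample-group assignment table
#'
#' @param path two-column TSV with header `sample_id`, `group`; groups
#'   must be `high` or `none`.
#' @return data.frame with those columns.
#' @export
readGroups <- function(path) {
  df <- readTsv(path)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("group file needs columns sample_id and group: ", path)
  bad <- setdiff(unique(df$group), .GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df
}

# "0/1"-style GT strings -> alt dosage (NA for missing / half-calls).
.gtToDosage <- function(gt) {
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  d <- map[gt]
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Read a VCF plus group table into a GenotypeMatrix
#'
#' Parses a VCF 4.2 file, keeps simple bi-allelic SNPs (see
#' [filterBiallelic()]), and attaches the two-group sample partition.
#' Every VCF sample must appear in the group table and vice versa;
#' mismatches are an error listing the offending samples. The bi-allelic
#' filter summary is stored in `metadata(x)$filter_summary`.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param groupsPath sample-group TSV (see [readGroups()]).
#' @return a [GenotypeMatrix-class], sites sorted per chromosome.
#' @export
readVcfGenotypes <- function(path, groupsPath) {
  vcf <- VariantAnnotation::readVcf(path)
  groups <- readGroups(groupsPath)
  samples <- colnames(vcf)
  missingFromGroups <- setdiff(samples, groups$sample_id)
  if (length(missingFromGroups))
    stop("VCF sample(s) absent from the group file: ",
         paste(missingFromGroups, collapse = ", "))
  unknown <- setdiff(groups$sample_id, samples)
  if (length(unknown))
    stop("group-file sample(s) absent from the VCF: ",
         paste(unknown, collapse = ", "))
  fb <- filterBiallelic(vcf)
  vcf <- fb$vcf
  gr <- granges(SummarizedExperiment::rowRanges(vcf))
  mcols(gr) <- NULL
  mcols(gr)$ref <- as.character(VariantAnnotation::ref(vcf))
  mcols(gr)$alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  names(gr) <- NULL
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotypes: ", path)
  gm <- GenotypeMatrix(gr, .gtToDosage(gt),
                       group = groups$group[match(samples, groups$sample_id)],
                       sampleNames = samples)
  metadata(gm)$filter_summary <- fb$summary
  gm
}

#' Read gene models from a GFF3 file
#'
#' Imports the file, keeps `gene`-type features, and sorts by
#' (chrom, start). Each gene needs an `ID` attribute; a `description`
#' attribute is carried through when present.
#'
#' @param path GFF3 file.
#' @return `GRanges` of genes with metadata columns `ID`, `description`.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(mcols(gr)))
    gr <- gr[as.character(mcols(gr)$type) == "gene"]
  if (length(gr) && is.null(mcols(gr)$ID))
    stop("gene features need an ID attribute: ", path)
  if (any(end(gr) < start(gr))) stop("gene with end < start in ", path)
  desc <- if (!is.null(mcols(gr)$description)) as.character(mcols(gr)$description)
          else rep(NA_character_, length(gr))
  id <- as.character(mcols(gr)$ID)
  mcols(gr) <- NULL
  mcols(gr)$ID <- id
  mcols(gr)$description <- desc
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write gene models as GFF3
#'
#' @param genes `GRanges` with an `ID` metadata column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  if (is.null(mcols(genes)$type)) mcols(genes)$type <- "gene"
  rtracklayer::export(genes, path, format = "gff3")
  invisible(path)
}

#' Read a long-format FPKM table
#'
#' @param path TSV with columns `transcript_id`, `sample_id`,
#'   `timepoint`, `fpkm`.
#' @return data.frame.
#' @export
readFpkm <- function(path) {
  df <- readTsv(path)
  need <- c("transcript_id", "sample_id", "timepoint", "fpkm")
  if (!all(need %in% names(df)))
    stop("FPKM table needs columns ", paste(need, collapse = ", "),
         ": ", path)
  df
}

#' Read a gene-to-term membership table
#'
#' @param path TSV with columns `gene_id`, `term_id`.
#' @return data.frame.
#' @export
readTermTable <- function(path) {
  df <- readTsv(path)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("term table needs columns gene_id and term_id: ", path)
  df
}

# Report TSVs: a leading comment line states the coordinate convention.
writeReport <- function(df, path, convention = "1-based inclusive") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coordinates: %s", convention), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readReport <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Write the per-window statistics table
#'
#' @param stats `GRanges` from [windowStats()].
#' @param path output TSV (1-based inclusive coordinates).
#' @return `path`, invisibly.
#' @export
writeWindowStats <- function(stats, path) {
  df <- data.frame(chrom = as.character(seqnames(stats)),
                   start = start(stats), end = end(stats),
                   as.data.frame(mcols(stats)),
                   stringsAsFactors = FALSE)
  writeReport(df, path)
}

#' Write called sweep regions as BED
#'
#' BED is 0-based half-open; the region's minimum member ZHp goes in the
#' score-like fifth column.
#'
#' @param regions `GRanges` from [callSweepRegions()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  bed <- grangesToBed(regions)
  bed$name <- sprintf("sweep_region_%d", seq_len(nrow(bed)))
  bed$zhp <- if (!is.null(mcols(regions)$zhp)) mcols(regions)$zhp else NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open (BED)", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sweep-region BED file back into a GRanges
#'
#' @param path BED written by [writeRegionsBed()].
#' @return `GRanges` with a `zhp` metadata column when present.
#' @export
readRegionsBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(GRanges())
  df <- utils::read.table(text = lines, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  gr <- bedToGRanges(df)
  if (ncol(df) >= 5L) mcols(gr)$zhp <- as.numeric(df[[5L]])
  gr
}

#' Export per-window value tracks for Circos-style plotting
#'
#' Computes per-group per-bp diversity and ROD over fixed windows
#' (default 5 kb, the plotting resolution) and writes one
#' `(chrom, start, end, value)` TSV per track.
#'
#' @param gm a filtered [GenotypeMatrix-class].
#' @param dir output directory (`track_pi_high.tsv`, `track_pi_none.tsv`,
#'   `track_rod.tsv`).
#' @param size track window size in bp (default 5000).
#' @param chromLengths optional named lengths; defaults to the object's
#'   `seqlengths`.
#' @return named character vector of the files written.
#' @export
exportTracks <- function(gm, dir, size = 5000L, chromLengths = NULL) {
  if (is.null(chromLengths)) chromLengths <- seqlengths(snpRanges(gm))
  if (anyNA(chromLengths)) stop("chromosome lengths are required for tracks")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- makeWindows(chromLengths, size)
  piH <- windowPi(gm, w, "high")
  piN <- windowPi(gm, w, "none")
  vals <- list(pi_high = piH, pi_none = piN, rod = rod(piH, piN))
  paths <- character(0)
  for (nm in names(vals)) {
    df <- data.frame(chrom = as.character(seqnames(w)),
                     start = start(w), end = end(w),
                     value = vals[[nm]], stringsAsFactors = FALSE)
    p <- file.path(dir, sprintf("track_%s.tsv", nm))
    writeReport(df, p)
    paths[nm] <- p
  }
  paths
}
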