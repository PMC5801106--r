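#' Pseudocounted expression fold change
#'
#' `(fpkmHigh + pseudocount) / (fpkmNone + pseudocount)`. Swapping the
#' arguments inverts the ratio; with pseudocount 0 and both inputs 0 the
#' ratio is undefined (`NA`).
#'
#' @param fpkmHigh,fpkmNone non-negative FPKM values (vectorized).
#' @param pseudocount non-negative FPKM offset (default 0.01).
#' @return numeric ratio(s).
#' @examples
#' foldChange(36, 1, 0)    # 36, an upregulated candidate
#' foldChange(0.01, 1, 0)  # 0.01, downregulated
#' @export
foldChange <- function(fpkmHigh, fpkmNone, pseudocount = 0.01) {
  if (any(fpkmHigh < 0, na.rm = TRUE) || any(fpkmNone < 0, na.rm = TRUE))
    stop("FPKM values must be >= 0")
  if (any(pseudocount < 0)) stop("pseudocount must be >= 0")
  num <- fpkmHigh + pseudocount
  den <- fpkmNone + pseudocount
  ifelse(den == 0, ifelse(num == 0, NA_real_, Inf), num / den)
}

#' Summarize an FPKM table into per-transcript expression records
#'
#' Collapses a long FPKM table (transcript_id, sample_id, timepoint, fpkm)
#' to group summaries (mean or median over the accessions of each group)
#' and high/none ratios per time point. Transcripts missing any time point
#' in either group are excluded and reported.
#'
#' @param fpkm long-format data.frame with columns `transcript_id`,
#'   `sample_id`, `timepoint`, `fpkm`.
#' @param groups data.frame with columns `sample_id`, `group`
#'   (`high`/`none`).
#' @param cfg a [ScreenConfig-class].
#' @return data.frame with one row per complete transcript: columns
#'   `transcript_id`, `fpkm_high_<t>`, `fpkm_none_<t>`, `ratio_<t>` for
#'   each time point, plus attribute `"excluded"` naming dropped
#'   transcripts.
#' @export
summarizeExpression <- function(fpkm, groups, cfg = ScreenConfig()) {
  need <- c("transcript_id", "sample_id", "timepoint", "fpkm")
  if (!all(need %in% names(fpkm)))
    stop("fpkm table needs columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(fpkm$sample_id), groups$sample_id)
  if (length(unknown))
    stop("samples missing from the group table: ",
         paste(unknown, collapse = ", "))
  fpkm$group <- groups$group[match(fpkm$sample_id, groups$sample_id)]
  summarize <- if (cfg@groupSummary == "median") stats::median else mean
  agg <- stats::aggregate(fpkm ~ transcript_id + timepoint + group,
                          data = fpkm, FUN = summarize)
  tps <- sort(unique(agg$timepoint))
  if (length(tps) != cfg@nTimepoints)
    warning("table has ", length(tps), " time points; config expects ",
            cfg@nTimepoints)
  tx <- sort(unique(agg$transcript_id))
  out <- data.frame(transcript_id = tx, stringsAsFactors = FALSE)
  complete <- rep(TRUE, length(tx))
  for (tp in tps) {
    for (grp in c("high", "none")) {
      v <- agg$fpkm[agg$timepoint == tp & agg$group == grp]
      id <- agg$transcript_id[agg$timepoint == tp & agg$group == grp]
      col <- v[match(tx, id)]
      complete <- complete & !is.na(col)
      out[[sprintf("fpkm_%s_%s", grp, tp)]] <- col
    }
    out[[sprintf("ratio_%s", tp)]] <- foldChange(
      out[[sprintf("fpkm_high_%s", tp)]],
      out[[sprintf("fpkm_none_%s", tp)]], cfg@pseudocount)
  }
  excluded <- tx[!complete]
  if (length(excluded))
    message(length(excluded), " transcript(s) excluded: missing time points")
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.ratioMatrix <- function(records) {
  cols <- grep("^ratio_", names(records), value = TRUE)
  if (!length(cols)) stop("records carry no ratio_* columns")
  as.matrix(records[, cols, drop = FALSE])
}

# Per-record count of passing time points under the direction policy.
# Strict: any opposite-direction passing time point disqualifies the
# record (count 0); relaxed: passes in both directions all count.
.passCounts <- function(records, cfg) {
  r <- .ratioMatrix(records)
  up <- rowSums(r >= cfg@foldThreshold, na.rm = TRUE)
  down <- rowSums(r <= 1 / cfg@foldThreshold, na.rm = TRUE)
  n <- up + down
  if (cfg@strictDirection) n[up > 0 & down > 0] <- 0L
  list(n = n, up = up, down = down)
}

#' Staged fold-change screen over time points
#'
#' A time point passes when the transcript's high/none ratio reaches the
#' fold threshold up (`>= fold`) or down (`<= 1/fold`). Stage `"any"`
#' keeps transcripts passing at least one time point, `"at_least_k"` at
#' least `minTimepointsStage2` of them, and `"all"` every time point. By
#' default passing time points must agree in direction (a transcript both
#' up and down at different time points fails the staged screens).
#'
#' @param records output of [summarizeExpression()].
#' @param stage `"any"`, `"at_least_k"`, or `"all"`.
#' @param cfg a [ScreenConfig-class].
#' @return the subset of `records` passing the stage.
#' @export
screenStage <- function(records, stage = c("any", "at_least_k", "all"),
                        cfg = ScreenConfig()) {
  stage <- match.arg(stage)
  pc <- .passCounts(records, cfg)
  k <- switch(stage, any = 1L, at_least_k = cfg@minTimepointsStage2,
              all = ncol(.ratioMatrix(records)))
  records[pc$n >= k, , drop = FALSE]
}

#' Classify transcript regulation
#'
#' `"up"` when every time point's ratio is at or above the fold threshold,
#' `"down"` when every ratio is at or below its reciprocal, `"none"`
#' otherwise — so up and down are mutually exclusive by construction.
#'
#' @param records output of [summarizeExpression()] (typically after the
#'   `"all"` stage).
#' @param cfg a [ScreenConfig-class].
#' @return character vector (`up`/`down`/`none`), one value per record.
#' @export
classifyRegulation <- function(records, cfg = ScreenConfig()) {
  r <- .ratioMatrix(records)
  allUp <- rowSums(r >= cfg@foldThreshold, na.rm = TRUE) == ncol(r) &
    !apply(is.na(r), 1L, any)
  allDown <- rowSums(r <= 1 / cfg@foldThreshold, na.rm = TRUE) == ncol(r) &
    !apply(is.na(r), 1L, any)
  unname(ifelse(allUp, "up", ifelse(allDown, "down", "none")))
}

#' One-sided Fisher (hypergeometric) enrichment p-value
#'
#' Upper-tail probability `P[X >= k]` of drawing at least `k` term members
#' in a selection of size `n` from a universe of `N` genes of which `m`
#' belong to the term.
#'
#' @param k selected genes in the term.
#' @param n selection size.
#' @param m term size in the universe.
#' @param N universe size.
#' @return one-sided p-value.
#' @examples
#' fisherEnrichment(5, 10, 10, 100)
#' fisherEnrichment(0, 10, 10, 100)  # upper tail includes all mass -> 1
#' @export
fisherEnrichment <- function(k, n, m, N) {
  if (any(k < 0 | n < 0 | m < 0 | N < 0)) stop("counts must be >= 0")
  if (any(k > pmin(n, m)) || any(n > N) || any(m > N))
    stop("inconsistent 2x2 margins")
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Term-set enrichment of a gene selection
#'
#' @param selected character vector of selected gene ids.
#' @param terms data.frame with columns `gene_id`, `term_id` (membership
#'   table).
#' @param universe character vector of all screened gene ids; defaults to
#'   the genes in `terms`.
#' @return data.frame `(term_id, k, n, m, N, p)`, one row per term,
#'   ordered by p.
#' @export
termEnrichment <- function(selected, terms,
                           universe = unique(terms$gene_id)) {
  if (!nrow(terms)) stop("empty term table")
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  selected <- intersect(selected, universe)
  N <- length(universe)
  n <- length(selected)
  tid <- sort(unique(terms$term_id))
  m <- vapply(tid, function(t)
    length(unique(terms$gene_id[terms$term_id == t])), integer(1))
  k <- vapply(tid, function(t)
    length(intersect(selected, terms$gene_id[terms$term_id == t])),
    integer(1))
  out <- data.frame(term_id = tid, k = k, n = n, m = m, N = N,
                    p = fisherEnrichment(k, n, m, N),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Permutation false-discovery rate for term enrichment
#'
#' Re-draws the selection labels at random over the universe
#' `nRandomizations` times, recomputing every term's one-sided p-value
#' each time. A term's FDR is the mean number of null p-values at or
#' below its observed p (across randomizations) divided by the observed
#' number of terms at or below that p, clipped to `[0, 1]`.
#'
#' @param observed data.frame from [termEnrichment()].
#' @param terms the membership table used for `observed`.
#' @param universe the gene universe used for `observed`.
#' @param nRandomizations number of label permutations (default 100).
#' @param seed mandatory RNG seed; equal seeds give identical FDR values.
#' @return `observed` with an extra `fdr` column.
#' @export
permutationFdr <- function(observed, terms, universe,
                           nRandomizations = 100L, seed) {
  if (missing(seed)) stop("a seed is mandatory for permutationFdr")
  if (!nrow(terms)) stop("empty term table")
  n <- observed$n[1L]
  nullP <- withSeed(seed, {
    vapply(seq_len(nRandomizations), function(i) {
      sel <- sample(universe, n)
      termEnrichment(sel, terms, universe)$p
    }, numeric(nrow(observed)))
  })
  if (is.null(dim(nullP))) nullP <- matrix(nullP, nrow = 1L)
  fdr <- vapply(observed$p, function(p) {
    meanNull <- mean(colSums(nullP <= p))
    nObs <- sum(observed$p <= p)
    min(1, max(0, meanNull / nObs))
  }, numeric(1))
  observed$fdr <- fdr
  observed
}
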