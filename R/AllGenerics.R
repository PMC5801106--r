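#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix`.
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genoDosage", function(x) standardGeneric("genoDosage"))

#' @rdname genotypeCounts
#' @export
setGeneric("genotypeCounts", function(x, group = "pooled")
  standardGeneric("genotypeCounts"))

#' @rdname alleleCounts
#' @export
setGeneric("alleleCounts", function(x, group = "pooled")
  standardGeneric("alleleCounts"))
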