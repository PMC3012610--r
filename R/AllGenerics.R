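#' @rdname CypRegistry-class
#' @param x a `CypRegistry`.
#' @export
setGeneric("registryTable", function(x) standardGeneric("registryTable"))

#' @rdname CypRegistry-class
#' @export
setGeneric("registryProvenance",
           function(x) standardGeneric("registryProvenance"))

#' @rdname CypRegistry-class
#' @export
setGeneric("registryRanges", function(x, ...) standardGeneric("registryRanges"))

#' @rdname countGenes
#' @export
setGeneric("countGenes", function(x, ...) standardGeneric("countGenes"))

#' @rdname countGenes
#' @export
setGeneric("countFamilies", function(x, ...) standardGeneric("countFamilies"))

#' @rdname tandemClusters
#' @export
setGeneric("tandemClusters", function(x, ...) standardGeneric("tandemClusters"))

#' @rdname exportRegistry
#' @export
setGeneric("exportRegistry",
           function(x, path, format = c("tsv", "bed", "gff3"), ...)
             standardGeneric("exportRegistry"))

#' @rdname NormalizationModel-class
#' @param x a `NormalizationModel`.
#' @export
setGeneric("baselineArray", function(x) standardGeneric("baselineArray"))

#' @rdname NormalizationModel-class
#' @export
setGeneric("normalizationCurves",
           function(x) standardGeneric("normalizationCurves"))

#' @rdname NormalizationModel-class
#' @export
setGeneric("invariantProbes", function(x) standardGeneric("invariantProbes"))

#' @rdname QCReport-class
#' @param x a `QCReport`.
#' @export
setGeneric("qcCounts", function(x) standardGeneric("qcCounts"))
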