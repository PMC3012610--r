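#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

REQUIRED_REGISTRY_COLUMNS <- c(
  "gene_name", "family", "subfamily", "chromosome",
  "tx_start", "tx_end", "strand", "exon_count", "flags"
)

KNOWN_FLAGS <- c(
  "pseudogene", "assembly_duplicate", "missing_from_assembly", "on_array"
)

#' Registry of zebrafish cytochrome P450 genes
#'
#' A `CypRegistry` holds one record per genomic CYP locus: gene symbol,
#' CYP family and subfamily, chromosome (or scaffold), transcript
#' coordinates (1-based inclusive), strand, exon count and status flags.
#' Loci absent from the genome assembly carry the `missing_from_assembly`
#' flag and no coordinates.  Assembly artifact copies of a gene (names
#' suffixed `c1`/`c2`) are kept as separate records but collapse to one
#' gene in all counting operations.
#'
#' @slot records a [S4Vectors::DataFrame] with one row per locus.
#' @slot provenance character vector describing the source file.
#' @seealso [loadRegistry()], [countGenes()], [tandemClusters()]
#' @exportClass CypRegistry
setClass("CypRegistry",
  slots = c(records = "DFrame", provenance = "character")
)

setValidity("CypRegistry", function(object) {
  rec <- object@records
  missing_cols <- setdiff(REQUIRED_REGISTRY_COLUMNS, colnames(rec))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(rec$gene_name))
    return("gene names must be unique")
  absent <- vapply(rec$flags, function(f) "missing_from_assembly" %in% f,
                   logical(1))
  has_coord <- !is.na(rec$tx_start) & !is.na(rec$tx_end)
  if (any(absent & has_coord))
    return("missing_from_assembly records must not carry coordinates")
  if (any(!absent & !has_coord))
    return("records with coordinates absent must be flagged missing_from_assembly")
  bad <- has_coord & rec$tx_start > rec$tx_end
  if (any(bad))
    return(paste0("tx_start > tx_end for: ",
                  paste(rec$gene_name[bad], collapse = ", ")))
  fam_from_name <- suppressWarnings(
    as.integer(sub("^CYP([0-9]+).*$", "\\1", rec$gene_name)))
  if (any(is.na(fam_from_name)) || any(fam_from_name != rec$family))
    return("family field must match the family parsed from the gene name")
  if (any(!is.na(rec$strand) & !(rec$strand %in% c(-1L, 1L))))
    return("strand must be +1 or -1")
  TRUE
})

#' Spot-level microarray intensities
#'
#' An `IntensityExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are probe-spot
#' instances (each probe is printed in `spotsPerProbe` replicate spots),
#' columns are arrays (one per timepoint x biological replicate).  The
#' mandatory assays are the linear-scale fluorescence `signal` plus the
#' scanner-level `saturated` and `above_background` flags.  Normalization
#' adds `normlog2` and `normsignal` assays.
#'
#' @exportClass IntensityExperiment
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
  need_assays <- c("signal", "saturated", "above_background")
  if (!all(need_assays %in% SummarizedExperiment::assayNames(object)))
    return(paste("assays required:", paste(need_assays, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("probe_id", "spot_index") %in% colnames(rd)))
    return("rowData must contain probe_id and spot_index")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("timepoint_hpf", "replicate") %in% colnames(cd)))
    return("colData must contain timepoint_hpf and replicate")
  sig <- SummarizedExperiment::assay(object, "signal")
  if (any(sig < 0, na.rm = TRUE))
    return("signal must be non-negative")
  if (anyDuplicated(paste(rd$probe_id, rd$spot_index)))
    return("(probe_id, spot_index) rows must be unique")
  TRUE
})

#' Rank-invariant normalization model
#'
#' Fitted state of the baseline-referenced normalization: the identity of
#' the baseline array (the array whose median signal is the median of all
#' per-array medians), and, for every other array, the rank-invariant
#' feature set and the piecewise-linear running-median curve mapping
#' observed log2 signal to the baseline scale.
#'
#' @slot baseline baseline array id.
#' @slot curves named list (per non-baseline array) of data frames with
#'   control points `x` (observed log2) and `y` (corrected log2).
#' @slot invariant named list of rank-invariant feature ids per array.
#' @slot params list echoing the fitting parameters.
#' @exportClass NormalizationModel
setClass("NormalizationModel",
  slots = c(baseline = "character", curves = "list",
            invariant = "list", params = "list")
)

setValidity("NormalizationModel", function(object) {
  for (nm in names(object@curves)) {
    cv <- object@curves[[nm]]
    if (!all(c("x", "y") %in% colnames(cv)))
      return("curves must have columns x and y")
    if (nrow(cv) > 1L) {
      if (any(diff(cv$x) <= 0))
        return(sprintf("curve for array '%s': x must be strictly increasing", nm))
      if (any(diff(cv$y) < 0))
        return(sprintf("curve for array '%s': y must be non-decreasing", nm))
    }
  }
  TRUE
})

#' Probe quality-control report
#'
#' Bookkeeping for the probe filter: probes saturated in any instance
#' (across arrays and duplicate spots) are removed first; of the rest,
#' probes whose signal is above background in no instance are removed;
#' the remainder is retained.  The categories are disjoint by this
#' precedence, so the counts always balance.
#'
#' @slot nInput,nSaturated,nBackground,nRetained integer counts.
#' @exportClass QCReport
setClass("QCReport",
  slots = c(nInput = "integer", nSaturated = "integer",
            nBackground = "integer", nRetained = "integer")
)

setValidity("QCReport", function(object) {
  if (object@nRetained !=
      object@nInput - object@nSaturated - object@nBackground)
    return("retained must equal input - saturated - background")
  if (any(c(object@nInput, object@nSaturated, object@nBackground,
            object@nRetained) < 0L))
    return("counts must be non-negative")
  TRUE
})

#' Microarray design description
#'
#' Describes the time-course layout used by the simulator: ordered
#' sampling times in hours post-fertilization, biological replicate
#' labels, the number of duplicate spots per probe, and the number of
#' probes on the array.
#'
#' @slot timepoints numeric, ordered sampling times (hpf).
#' @slot replicates character, biological replicate labels.
#' @slot spotsPerProbe integer, duplicate spots per probe.
#' @slot nProbes integer, probes on the array.
#' @exportClass ArrayDesign
setClass("ArrayDesign",
  slots = c(timepoints = "numeric", replicates = "character",
            spotsPerProbe = "integer", nProbes = "integer")
)

setValidity("ArrayDesign", function(object) {
  if (length(object@timepoints) < 2L) return("need at least 2 timepoints")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    return("timepoints must be strictly increasing")
  if (length(object@replicates) < 2L) return("need at least 2 replicates")
  if (object@spotsPerProbe < 1L) return("spotsPerProbe must be >= 1")
  if (object@nProbes < 1L) return("nProbes must be >= 1")
  TRUE
})
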