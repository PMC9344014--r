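#' @include AllClasses.R
NULL

#' Extract the underlying igraph object
#' @param x a graph-backed MMInet object.
#' @return an \pkg{igraph} graph.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Per-type node counts
#' @param x a [LayeredNetwork] (or subclass).
#' @return named integer vector of node counts by type, plus "Total".
#' @export
setGeneric("nodeCounts", function(x) standardGeneric("nodeCounts"))

#' Per-type edge counts
#' @param x a [LayeredNetwork] (or subclass).
#' @return named integer vector of edge counts by edge type, plus "Total".
#' @export
setGeneric("edgeCounts", function(x) standardGeneric("edgeCounts"))

#' Project one node layer onto another
#'
#' @param x a [LayeredNetwork].
#' @param from source node type (e.g. "TAXON").
#' @param to feature node type (e.g. "GOISP").
#' @param ... further arguments passed to methods.
#' @return a named list mapping each source entity to its character vector
#'   of features, with attributes `from` and `to`.
#' @export
setGeneric("projectLayers",
           function(x, from, to, ...) standardGeneric("projectLayers"))

#' Significant term identifiers of an enrichment result
#' @param x an [EnrichmentResult].
#' @return character vector of significant term ids.
#' @export
setGeneric("significantTerms",
           function(x) standardGeneric("significantTerms"))

#' Tabular view of a result object
#' @param x a result object with a tabular representation.
#' @return a data.frame.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Are two entities in the same cluster at the chosen cut?
#' @param x a [DendrogramResult].
#' @param a,b entity labels.
#' @return TRUE iff both entities carry the same cut label.
#' @export
setGeneric("coClustered", function(x, a, b) standardGeneric("coClustered"))

#' Rewiring score accessor
#' @param x a [RewiringReport].
#' @return the scalar score in [0, 1].
#' @export
setGeneric("rewiringScore", function(x) standardGeneric("rewiringScore"))

#' @describeIn networkGraph method for LayeredNetwork
#' @export
setMethod("networkGraph", "LayeredNetwork", function(x) x@graph)

#' @describeIn networkGraph method for CommonalityGraph
#' @export
setMethod("networkGraph", "CommonalityGraph", function(x) x@graph)

#' @describeIn networkGraph method for VirusHostNetwork
#' @export
setMethod("networkGraph", "VirusHostNetwork", function(x) x@graph)

#' @describeIn networkGraph method for IntegratedVirusDiseaseNetwork
#' @export
setMethod("networkGraph", "IntegratedVirusDiseaseNetwork",
          function(x) x@graph)
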