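#' @include AllClasses.R AllGenerics.R
NULL

setMethod("show", "LayeredNetwork", function(object) {
  nc <- nodeCounts(object)
  cat("LayeredNetwork with", nc[["Total"]], "nodes and",
      igraph::ecount(object@graph), "edges\n")
  present <- nc[setdiff(names(nc), "Total")]
  present <- present[present > 0]
  if (length(present))
    cat("  nodes:", paste(names(present), present, sep = "=",
                          collapse = ", "), "\n")
})

setMethod("show", "MmdiNetwork", function(object) {
  callNextMethod()
  cat("  disease:", object@disease, "|",
      length(object@intersectionNodes), "intersection node(s),",
      length(object@ispIntersectionNodes), "immune-term-associated\n")
})

setMethod("show", "CommonalityGraph", function(object) {
  g <- object@graph
  cat("CommonalityGraph with", igraph::vcount(g), "entities and",
      igraph::ecount(g), "weighted edges (minShared =",
      object@minShared, ")\n")
})

setMethod("show", "VirusHostNetwork", function(object) {
  ct <- virusHostCounts(object)
  cat("VirusHostNetwork:", ct[["viral_proteins"]], "viral proteins,",
      ct[["human_targets"]], "human targets,", ct[["edges"]], "edges\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  tb <- object@table
  cat("EnrichmentResult:", sum(tb$significant), "of", nrow(tb),
      "terms significant at adjusted p <=", object@alpha, "\n")
})

setMethod("show", "TermGrouping", function(object) {
  cat("TermGrouping:", nrow(object@membership), "terms in",
      nrow(object@groups), "group(s) at kappa >=", object@threshold, "\n")
})

setMethod("show", "DendrogramResult", function(object) {
  cat("DendrogramResult:", length(object@labels), "entities,",
      object@k, "clusters,", object@method, "linkage",
      sprintf("(cophenetic r = %.3f)\n",
              object@copheneticCor[[object@method]]))
})

setMethod("show", "RewiringReport", function(object) {
  cat("RewiringReport", paste(object@networkNames, collapse = " vs "),
      sprintf("- score %.3f\n", object@score))
  print(resultTable(object))
})
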