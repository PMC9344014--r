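## Central S4 containers. Graph-backed classes keep an igraph object in @graph
## with a `type` vertex attribute and (where relevant) an `edge_type` edge
## attribute; accessors in the module files mediate all slot access.

NODE_TYPES <- c("TAXON", "METABOLITE", "GENE", "GOISP")
BIOFLUIDS <- c("FECES", "SERUM", "CSF")
KINGDOMS <- c("BACTERIA", "FUNGI")
SENTINEL_TAXA <- c("Unnamed bacteria", "Unnamed fungi")

#' Typed multipartite network
#'
#' An undirected simple graph whose vertices carry a `type` attribute
#' (one of TAXON, METABOLITE, GENE, GOISP) and whose edges carry an
#' `edge_type` attribute of the form "TYPE1-TYPE2" with the two endpoint
#' types in that order.
#'
#' @slot graph an \pkg{igraph} graph with `type` vertex and `edge_type`
#'   edge attributes.
#' @export
setClass("LayeredNetwork", representation(graph = "ANY"))

setValidity("LayeredNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("@graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::vcount(g) == 0L) return(TRUE)
  tp <- igraph::V(g)$type
  if (is.null(tp) || any(!tp %in% NODE_TYPES))
    return("every vertex needs a `type` attribute in TAXON/METABOLITE/GENE/GOISP")
  if (anyDuplicated(igraph::V(g)$name))
    return("vertex names must be unique")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    return("graph must be simple (no loops, no duplicate edges)")
  if (igraph::ecount(g) > 0L) {
    et <- igraph::E(g)$edge_type
    if (is.null(et)) return("every edge needs an `edge_type` attribute")
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    t1 <- tp[ends[, 1L]]; t2 <- tp[ends[, 2L]]
    want <- paste(pmin(t1, t2), pmax(t1, t2), sep = "-")
    have <- vapply(strsplit(et, "-", fixed = TRUE), function(p)
      paste(sort(p), collapse = "-"), character(1))
    if (any(want != have))
      return("edge_type must match the types of the edge's endpoints")
  }
  TRUE
})

#' Disease-overlaid multipartite network
#'
#' A [LayeredNetwork] restricted to one disease: microbiota and metabolites
#' that reach the disease gene set, the intersection genes themselves, their
#' intra-set protein interactions and the disease-enriched immune terms.
#'
#' @slot disease disease name.
#' @slot intersectionNodes disease genes also targeted by >=1 metabolite.
#' @slot ispIntersectionNodes the subset annotated to >=1 significant
#'   disease immune term.
#' @slot diseaseGoisps all significant immune terms of the disease gene set.
#' @export
setClass("MmdiNetwork", contains = "LayeredNetwork",
         representation(disease = "character",
                        intersectionNodes = "character",
                        ispIntersectionNodes = "character",
                        diseaseGoisps = "character"))

setValidity("MmdiNetwork", function(object) {
  if (length(object@disease) != 1L) return("disease must be a single name")
  if (!all(object@ispIntersectionNodes %in% object@intersectionNodes))
    return("ispIntersectionNodes must be a subset of intersectionNodes")
  TRUE
})

#' Weighted shared-item commonality graph
#'
#' Entities are vertices; an undirected edge joins two entities iff they
#' share at least `minShared` items, weighted by the number of shared items.
#'
#' @slot graph an undirected weighted igraph; isolated entities are kept.
#' @slot minShared integer threshold used at construction.
#' @export
setClass("CommonalityGraph",
         representation(graph = "ANY", minShared = "integer"))

setValidity("CommonalityGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("@graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    return("graph must be simple")
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    if (is.null(w) || any(w < object@minShared))
      return("every edge needs weight >= minShared")
  }
  TRUE
})

#' Bipartite virus-host interaction network
#'
#' Viral proteins (with a `strain` vertex attribute) on one side, human
#' gene products on the other; edges are deduplicated physical interactions.
#'
#' @slot graph igraph with vertex attribute `side` in c("viral", "human");
#'   viral vertices carry `strain`.
#' @export
setClass("VirusHostNetwork", representation(graph = "ANY"))

setValidity("VirusHostNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("@graph must be an igraph object")
  if (igraph::vcount(g) == 0L) return(TRUE)
  side <- igraph::V(g)$side
  if (is.null(side) || any(!side %in% c("viral", "human")))
    return("vertices need a `side` attribute in viral/human")
  if (igraph::ecount(g) > 0L) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    if (any(side[ends[, 1L]] == side[ends[, 2L]]))
      return("every edge must join one viral and one human vertex")
  }
  if (igraph::any_multiple(g)) return("edges must be deduplicated")
  TRUE
})

#' Virus-host network merged with a disease gene set
#'
#' @slot graph igraph whose vertices carry `side` ("viral"/"human"); human
#'   vertices may be disease genes, viral targets or both.
#' @slot disease the disease name merged in.
#' @export
setClass("IntegratedVirusDiseaseNetwork",
         representation(graph = "ANY", disease = "character"))

#' Over-representation analysis result
#'
#' One row per annotation term with the hypergeometric upper-tail p-value of
#' the query/term overlap and its Benjamini-Hochberg adjustment.
#'
#' @slot table data.frame with columns term_id, term_name, k, K, n, N,
#'   raw_p, adjusted_p, significant, ordered by adjusted_p then term_id.
#' @slot alpha significance level applied to adjusted p-values.
#' @slot query the effective query gene set (after universe intersection).
#' @export
setClass("EnrichmentResult",
         representation(table = "data.frame", alpha = "numeric",
                        query = "character"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  need <- c("term_id", "term_name", "k", "K", "n", "N",
            "raw_p", "adjusted_p", "significant")
  if (!all(need %in% names(tb))) return("missing enrichment columns")
  if (nrow(tb)) {
    if (any(tb$k > pmin(tb$K, tb$n))) return("k must be <= min(K, n)")
    if (any(tb$adjusted_p < tb$raw_p - 1e-12))
      return("adjusted p cannot be below raw p")
    if (any(tb$significant != (tb$adjusted_p <= object@alpha)))
      return("significance flags inconsistent with alpha")
  }
  TRUE
})

#' Kappa-based grouping of significant terms
#'
#' @slot membership data.frame (term_id, group) — a hard partition of the
#'   significant terms into connected components of the kappa graph.
#' @slot groups data.frame (group, leading_term, n_terms, percent_of_terms).
#' @slot kappaEdges data.frame (term_a, term_b, kappa) of edges at or above
#'   the threshold.
#' @slot threshold the kappa threshold used.
#' @export
setClass("TermGrouping",
         representation(membership = "data.frame", groups = "data.frame",
                        kappaEdges = "data.frame", threshold = "numeric"))

setValidity("TermGrouping", function(object) {
  if (anyDuplicated(object@membership$term_id))
    return("each term may belong to exactly one group")
  if (nrow(object@groups) &&
      abs(sum(object@groups$percent_of_terms) - 100) > 0.01)
    return("group percentages must sum to 100")
  TRUE
})

#' Agglomerative clustering result with linkage validation
#'
#' @slot hclust the selected merge tree (a stats::hclust object).
#' @slot method linkage method selected by cophenetic correlation.
#' @slot copheneticCor named correlations, one per candidate method.
#' @slot labels named integer cluster labels for the requested cut.
#' @slot k number of clusters in the cut.
#' @export
setClass("DendrogramResult",
         representation(hclust = "ANY", method = "character",
                        copheneticCor = "numeric", labels = "integer",
                        k = "integer"))

setValidity("DendrogramResult", function(object) {
  if (length(unique(object@labels)) != object@k)
    return("cut must produce exactly k distinct labels")
  TRUE
})

#' Pairwise network rewiring report
#'
#' Set algebra on node identifiers and canonicalised undirected edges of two
#' networks, with a scalar rewiring score (Jaccard distance of edge sets).
#'
#' @slot networkNames names of the left and right networks.
#' @slot nodes list(common, left_only, right_only) of node ids.
#' @slot edges list(common, left_only, right_only) of canonical edge keys.
#' @slot score rewiring score in [0, 1]; 0 iff identical edge sets.
#' @export
setClass("RewiringReport",
         representation(networkNames = "character", nodes = "list",
                        edges = "list", score = "numeric"))

setValidity("RewiringReport", function(object) {
  for (sl in list(object@nodes, object@edges))
    if (!all(c("common", "left_only", "right_only") %in% names(sl)))
      return("nodes/edges must have common/left_only/right_only classes")
  if (object@score < 0 || object@score > 1)
    return("score must lie in [0, 1]")
  TRUE
})
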