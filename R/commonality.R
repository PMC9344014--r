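## Shared-item commonality graph: entities joined by the number of items
## (metabolites) they have in common, with degree/strength/articulation
## topology.

#' Build a commonality graph from entity item sets
#'
#' An edge joins two entities iff they share at least `minShared` items;
#' the edge weight is the number of shared items. Entities sharing nothing
#' are retained as isolated (degree-0) nodes.
#'
#' @param entity_items named list mapping each entity to a non-empty
#'   character vector of items.
#' @param minShared minimum shared-item count for an edge (default 1).
#' @return a [CommonalityGraph-class].
#' @export
buildCommonality <- function(entity_items, minShared = 1L) {
  if (length(entity_items) == 0L) stop("entity_items must be non-empty")
  if (is.null(names(entity_items)) || any(!nzchar(names(entity_items))))
    stop("entity_items must be a named list")
  if (any(lengths(entity_items) == 0L))
    stop("every entity needs at least one item")
  items <- sort(unique(unlist(entity_items)))
  m <- matrix(0L, length(entity_items), length(items),
              dimnames = list(names(entity_items), items))
  for (e in names(entity_items))
    m[e, unique(entity_items[[e]])] <- 1L
  w <- tcrossprod(m)
  w[lower.tri(w, diag = TRUE)] <- 0L
  idx <- which(w >= minShared, arr.ind = TRUE)
  edges <- data.frame(from = rownames(w)[idx[, 1L]],
                      to = colnames(w)[idx[, 2L]],
                      weight = w[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = names(entity_items))
  methods::new("CommonalityGraph", graph = g,
               minShared = as.integer(minShared))
}

#' Topology report of a commonality graph
#'
#' Degree and strength (sum of incident weights) per node, articulation
#' points (linear-time biconnectivity), connected-component modules, and
#' top-N rankings by degree and by strength with a deterministic tie-break
#' (higher value first, then lexicographic node name).
#'
#' @param x a [CommonalityGraph-class].
#' @param top_n ranking length (default 10).
#' @return a list with elements `nodes` (data.frame: node, degree,
#'   strength, is_articulation, module), `articulation_points`,
#'   `top_degree`, `top_strength` and `n_modules`.
#' @export
topologyReport <- function(x, top_n = 10L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  g <- x@graph
  deg <- igraph::degree(g)
  str <- igraph::strength(g)
  str[is.na(str)] <- 0
  art <- sort(igraph::articulation_points(g)$name)
  comp <- igraph::components(g)$membership
  nodes <- data.frame(node = igraph::V(g)$name,
                      degree = as.integer(deg),
                      strength = as.integer(str),
                      is_articulation = igraph::V(g)$name %in% art,
                      module = unname(comp[igraph::V(g)$name]),
                      stringsAsFactors = FALSE)
  rank <- function(value) {
    o <- order(-value, nodes$node)
    utils::head(nodes$node[o], top_n)
  }
  list(nodes = nodes,
       articulation_points = art,
       top_degree = rank(nodes$degree),
       top_strength = rank(nodes$strength),
       n_modules = max(comp))
}

#' Export a commonality graph
#'
#' @param x a [CommonalityGraph-class].
#' @param graphml optional GraphML path.
#' @param edges_tsv optional weighted edge-list TSV path.
#' @param report_tsv optional per-node topology report TSV path.
#' @param top_n ranking length for the report.
#' @return invisibly, the list of written paths.
#' @export
exportCommonality <- function(x, graphml = NULL, edges_tsv = NULL,
                              report_tsv = NULL, top_n = 10L) {
  g <- x@graph
  written <- list()
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
    written$graphml <- graphml
  }
  if (!is.null(edges_tsv)) {
    ends <- igraph::ends(g, igraph::E(g))
    written$edges <- writeTsv(data.frame(
      from = ends[, 1L], to = ends[, 2L],
      weight = igraph::E(g)$weight), edges_tsv)
  }
  if (!is.null(report_tsv))
    written$report <- writeTsv(topologyReport(x, top_n)$nodes, report_tsv)
  invisible(written)
}
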