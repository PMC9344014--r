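## Tripartite microbiota-metabolite-immune (MMI) network and its projections.

#' Build the microbiota-metabolite-immune network
#'
#' Links each taxon (including the unnamed-kingdom sentinels) to its
#' metabolites, and each metabolite to every significant immune term for
#' which the metabolite targets at least one query gene annotated to the
#' term (existential rule, unweighted). Term-term edges are the kappa edges
#' of the supplied grouping. Metabolites with no term edge, and taxa left
#' without metabolites, are pruned; the fixed point is independent of
#' pruning order.
#'
#' @param taxon_metabolite data.frame (taxon, kingdom, metabolite_id).
#' @param gene_table metabolite-to-gene table.
#' @param enrichment an [EnrichmentResult-class] computed on the metabolite
#'   target genes.
#' @param ann the annotation used for the enrichment.
#' @param grouping optional [TermGrouping-class] supplying term-term edges.
#' @param records optional metabolite record collection; when supplied,
#'   every metabolite_id referenced by either table must exist in it.
#' @return a [LayeredNetwork-class] with TAXON, METABOLITE and GOISP nodes.
#' @export
buildMmi <- function(taxon_metabolite, gene_table, enrichment, ann,
                     grouping = NULL, records = NULL) {
  if (!is.null(records)) {
    dangling <- setdiff(unique(c(taxon_metabolite$metabolite_id,
                                 gene_table$metabolite_id)),
                        records$metabolite_id)
    if (length(dangling))
      stop("metabolite id(s) not found in records: ",
           paste(utils::head(dangling, 5), collapse = ", "))
  }
  sig <- significantTerms(enrichment)
  if (length(sig) == 0L)
    return(makeLayeredNetwork(data.frame(name = character(0),
                                         type = character(0)),
                              data.frame(from = character(0),
                                         to = character(0))))
  query <- enrichment@query
  termGenes <- lapply(ann$terms[sig], intersect, query)
  byMet <- split(gene_table$gene_symbol, gene_table$metabolite_id)
  metTerm <- do.call(rbind, lapply(names(byMet), function(m) {
    hits <- sig[vapply(termGenes, function(g)
      length(intersect(g, byMet[[m]])) > 0L, logical(1))]
    if (length(hits) == 0L) return(NULL)
    data.frame(from = m, to = hits, stringsAsFactors = FALSE)
  }))
  if (is.null(metTerm))
    metTerm <- data.frame(from = character(0), to = character(0))
  keptMet <- unique(metTerm$from)
  tm <- taxon_metabolite[taxon_metabolite$metabolite_id %in% keptMet, ,
                         drop = FALSE]
  taxMet <- data.frame(from = tm$taxon, to = tm$metabolite_id,
                       stringsAsFactors = FALSE)
  termTerm <- data.frame(from = character(0), to = character(0))
  if (!is.null(grouping) && nrow(grouping@kappaEdges)) {
    ke <- grouping@kappaEdges
    ke <- ke[ke$term_a %in% sig & ke$term_b %in% sig, , drop = FALSE]
    termTerm <- data.frame(from = ke$term_a, to = ke$term_b,
                           stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    nodeDf(unique(tm$taxon), "TAXON"),
    nodeDf(keptMet, "METABOLITE"),
    nodeDf(sig, "GOISP"))
  net <- makeLayeredNetwork(nodes, rbind(taxMet, metTerm, termTerm))
  methods::validObject(net)
  net
}

#' @describeIn nodeCounts node counts by type
#' @export
setMethod("nodeCounts", "LayeredNetwork", function(x) {
  g <- x@graph
  out <- stats::setNames(integer(length(NODE_TYPES)), NODE_TYPES)
  if (igraph::vcount(g)) {
    tab <- table(igraph::V(g)$type)
    out[names(tab)] <- as.integer(tab)
  }
  c(out, Total = igraph::vcount(g))
})

#' @describeIn edgeCounts edge counts by edge type
#' @export
setMethod("edgeCounts", "LayeredNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0L) return(c(Total = 0L))
  tab <- table(igraph::E(g)$edge_type)
  c(stats::setNames(as.integer(tab), names(tab)), Total = igraph::ecount(g))
})

#' @describeIn projectLayers projections of a layered network
#'
#' Supported pairs: any directly edged pair (e.g. TAXON->METABOLITE,
#' METABOLITE->GOISP), and TAXON->GOISP via the union over the taxon's
#' metabolites of their term neighbours. Unnamed sentinel taxa are excluded
#' from TAXON-sourced projections by default.
#'
#' @param includeUnnamed keep the "Unnamed bacteria"/"Unnamed fungi"
#'   sentinels in TAXON-sourced projections (default FALSE).
#' @export
setMethod("projectLayers", "LayeredNetwork",
          function(x, from, to, includeUnnamed = FALSE) {
  stopifnot(from %in% NODE_TYPES, to %in% NODE_TYPES)
  g <- x@graph
  if (igraph::vcount(g) == 0L)
    return(structure(stats::setNames(list(), character(0)),
                     from = from, to = to))
  tp <- igraph::V(g)$type
  nms <- igraph::V(g)$name
  src <- nms[tp == from]
  if (from == "TAXON" && !includeUnnamed) src <- setdiff(src, SENTINEL_TAXA)
  neighborsOfType <- function(v, type) {
    nb <- igraph::neighbors(g, v)
    nb$name[nb$type == type]
  }
  if (from == "TAXON" && to == "GOISP") {
    feats <- lapply(src, function(v) {
      mets <- neighborsOfType(v, "METABOLITE")
      sort(unique(unlist(lapply(mets, neighborsOfType, type = "GOISP"))))
    })
  } else {
    direct <- paste(sort(c(from, to)), collapse = "-")
    present <- unique(vapply(strsplit(unique(
      igraph::edge_attr(g, "edge_type") %||% character(0)), "-"),
      function(p) paste(sort(p), collapse = "-"), character(1)))
    if (!direct %in% present)
      stop("unsupported projection pair: ", from, " -> ", to)
    feats <- lapply(src, function(v) sort(neighborsOfType(v, to)))
  }
  names(feats) <- src
  feats <- feats[lengths(feats) > 0L]
  structure(feats, from = from, to = to)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a layered network
#'
#' @param x a [LayeredNetwork-class].
#' @param graphml optional GraphML output path.
#' @param nodes_tsv,edges_tsv optional TSV output paths (node_type /
#'   edge_type attributes included).
#' @return invisibly, a list of written paths.
#' @export
exportLayeredNetwork <- function(x, graphml = NULL, nodes_tsv = NULL,
                                 edges_tsv = NULL) {
  g <- x@graph
  written <- list()
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
    written$graphml <- graphml
  }
  if (!is.null(nodes_tsv)) {
    written$nodes <- writeTsv(data.frame(
      name = igraph::V(g)$name, node_type = igraph::V(g)$type), nodes_tsv)
  }
  if (!is.null(edges_tsv)) {
    ends <- igraph::ends(g, igraph::E(g))
    written$edges <- writeTsv(data.frame(
      from = ends[, 1L], to = ends[, 2L],
      edge_type = igraph::E(g)$edge_type), edges_tsv)
  }
  invisible(written)
}
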