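## Disease overlays: per-disease multipartite networks joining microbiota,
## metabolites, disease genes targeted by metabolites ("intersection
## nodes"), their intra-set protein interactions and disease-enriched
## immune terms.

#' Select a disease gene set with filtered intra-set interactions
#'
#' Keeps the `top_n` highest-scoring genes (boundary ties broken
#' lexicographically and reported via a message) and the intra-set
#' interaction edges at or above the confidence cutoff whose endpoints both
#' survive.
#'
#' @param scored data.frame (gene, score).
#' @param top_n number of genes to keep (default 200).
#' @param ppi_edges data.frame (gene_a, gene_b, confidence) with confidence
#'   in [0, 1].
#' @param confidence_cutoff minimum confidence (default 0.8).
#' @param disease disease name attached to the set.
#' @return a list (disease, genes data.frame with rank, ppi data.frame).
#' @export
selectDiseaseGenes <- function(scored, top_n = 200L, ppi_edges = NULL,
                               confidence_cutoff = 0.8,
                               disease = "disease") {
  if (nrow(scored) < top_n)
    stop("need at least top_n = ", top_n, " scored genes, got ",
         nrow(scored))
  scored$gene <- toupper(scored$gene)
  o <- order(-scored$score, scored$gene)
  cut <- scored$score[o][top_n]
  if (sum(scored$score == cut) > 1L &&
      top_n < nrow(scored) && scored$score[o][top_n + 1L] == cut)
    message("score tie at rank ", top_n,
            " broken lexicographically by gene symbol")
  genes <- scored[o[seq_len(top_n)], , drop = FALSE]
  genes$rank <- seq_len(top_n)
  rownames(genes) <- NULL
  if (is.null(ppi_edges))
    ppi_edges <- data.frame(gene_a = character(0), gene_b = character(0),
                            confidence = numeric(0))
  if (nrow(ppi_edges) && (any(ppi_edges$confidence < 0) ||
                          any(ppi_edges$confidence > 1)))
    stop("confidence values must lie in [0, 1]")
  ppi <- ppi_edges[ppi_edges$confidence >= confidence_cutoff &
                   toupper(ppi_edges$gene_a) %in% genes$gene &
                   toupper(ppi_edges$gene_b) %in% genes$gene, ,
                   drop = FALSE]
  rownames(ppi) <- NULL
  list(disease = disease, genes = genes, ppi = ppi)
}

#' Build a disease-overlaid multipartite network
#'
#' Intersection nodes are the disease genes targeted by at least one
#' metabolite. Metabolites are retained iff they target a disease gene;
#' taxa iff they keep a retained metabolite. Gene-term edges come from the
#' enrichment of the disease gene set (gene annotated to a significant
#' term); gene-gene edges are the confidence-filtered intra-set
#' interactions between intersection nodes; term-term edges are optional
#' kappa edges. Only significant terms annotated to an intersection node
#' become nodes; the full significant set is kept in `diseaseGoisps` for
#' coverage accounting.
#'
#' @param disease a disease gene set from [selectDiseaseGenes()].
#' @param gene_table metabolite-to-gene table.
#' @param taxon_metabolite data.frame (taxon, kingdom, metabolite_id).
#' @param disease_enrichment [EnrichmentResult-class] on the disease genes.
#' @param ann the annotation used for the enrichment.
#' @param grouping optional [TermGrouping-class] for term-term edges.
#' @return an [MmdiNetwork-class]; empty (with a warning) when no disease
#'   gene is targeted.
#' @export
buildMmdi <- function(disease, gene_table, taxon_metabolite,
                      disease_enrichment, ann, grouping = NULL) {
  dg <- disease$genes$gene
  inter <- sort(intersect(dg, unique(gene_table$gene_symbol)))
  if (length(inter) == 0L) {
    warning("no disease gene is targeted by any metabolite; empty overlay")
    empty <- makeLayeredNetwork(
      data.frame(name = character(0), type = character(0)),
      data.frame(from = character(0), to = character(0)))
    return(methods::new("MmdiNetwork", graph = empty@graph,
                        disease = disease$disease,
                        intersectionNodes = character(0),
                        ispIntersectionNodes = character(0),
                        diseaseGoisps = significantTerms(disease_enrichment)))
  }
  gt <- gene_table[gene_table$gene_symbol %in% inter, , drop = FALSE]
  mets <- unique(gt$metabolite_id)
  tm <- taxon_metabolite[taxon_metabolite$metabolite_id %in% mets, ,
                         drop = FALSE]
  sig <- significantTerms(disease_enrichment)
  geneTerm <- do.call(rbind, lapply(sig, function(t) {
    hits <- intersect(ann$terms[[t]], inter)
    if (length(hits) == 0L) return(NULL)
    data.frame(from = hits, to = t, stringsAsFactors = FALSE)
  }))
  if (is.null(geneTerm))
    geneTerm <- data.frame(from = character(0), to = character(0))
  ispInter <- sort(unique(geneTerm$from))
  terms <- sort(unique(geneTerm$to))
  ppi <- disease$ppi
  ppi <- ppi[toupper(ppi$gene_a) %in% inter &
             toupper(ppi$gene_b) %in% inter &
             toupper(ppi$gene_a) != toupper(ppi$gene_b), , drop = FALSE]
  termTerm <- data.frame(from = character(0), to = character(0))
  if (!is.null(grouping) && nrow(grouping@kappaEdges)) {
    ke <- grouping@kappaEdges
    ke <- ke[ke$term_a %in% terms & ke$term_b %in% terms, , drop = FALSE]
    termTerm <- data.frame(from = ke$term_a, to = ke$term_b)
  }
  nodes <- rbind(
    nodeDf(unique(tm$taxon), "TAXON"),
    nodeDf(mets, "METABOLITE"),
    nodeDf(inter, "GENE"),
    nodeDf(terms, "GOISP"))
  edges <- rbind(
    data.frame(from = tm$taxon, to = tm$metabolite_id),
    data.frame(from = gt$metabolite_id, to = gt$gene_symbol),
    geneTerm,
    if (nrow(ppi)) data.frame(from = toupper(ppi$gene_a),
                              to = toupper(ppi$gene_b)) else NULL,
    termTerm)
  net <- makeLayeredNetwork(nodes, edges)
  methods::new("MmdiNetwork", graph = net@graph,
               disease = disease$disease,
               intersectionNodes = inter,
               ispIntersectionNodes = ispInter,
               diseaseGoisps = sig)
}

#' Intersection-node accessor
#' @param x an [MmdiNetwork-class].
#' @return character vector of intersection genes.
#' @export
intersectionNodes <- function(x) {
  stopifnot(methods::is(x, "MmdiNetwork"))
  x@intersectionNodes
}

#' Immune-term coverage of an overlay
#'
#' The terms reachable from the intersection nodes, out of all significant
#' disease terms (the pleiotropy accounting of the overlay).
#'
#' @param x an [MmdiNetwork-class].
#' @return named integer vector `covered` / `total`.
#' @export
goispCoverage <- function(x) {
  g <- x@graph
  covered <- if (igraph::vcount(g)) sum(igraph::V(g)$type == "GOISP") else 0L
  c(covered = as.integer(covered), total = length(x@diseaseGoisps))
}

#' Compare disease overlays
#'
#' Per entity class (taxa, metabolites, immune terms): the intersection
#' across all overlays and the pairwise overlap-count matrix.
#'
#' @param overlays list of [MmdiNetwork-class] objects with distinct
#'   disease names.
#' @return list with elements `common` (list of character vectors per
#'   class) and `pairwise` (list of named count matrices per class).
#' @export
compareOverlays <- function(overlays) {
  if (length(overlays) < 2L) stop("need at least two overlays")
  nms <- vapply(overlays, function(o) o@disease, character(1))
  if (anyDuplicated(nms)) stop("duplicate disease names")
  classSets <- function(o, type) {
    g <- o@graph
    if (igraph::vcount(g) == 0L) return(character(0))
    igraph::V(g)$name[igraph::V(g)$type == type]
  }
  classes <- c(taxa = "TAXON", metabolites = "METABOLITE", goisps = "GOISP")
  out <- lapply(classes, function(type) {
    sets <- lapply(overlays, classSets, type = type)
    names(sets) <- nms
    sets
  })
  common <- lapply(out, function(sets) sort(Reduce(intersect, sets)))
  pairwise <- lapply(out, function(sets) {
    m <- outer(seq_along(sets), seq_along(sets), Vectorize(function(i, j)
      length(intersect(sets[[i]], sets[[j]]))))
    dimnames(m) <- list(nms, nms)
    m
  })
  list(common = common, pairwise = pairwise)
}
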