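## Virus-host interactome overlay: bipartite virus-host network, merge with
## disease gene sets, viral-target (+ first neighbour) gene sets for
## enrichment, and comparison/joint clustering of virus- versus
## microbiota-modulated immune terms.

#' Load a virus-host interaction network
#'
#' Accepts one or more tables of rows (viral_protein, strain, human_gene);
#' rows with a missing endpoint are rejected with a warning and edges are
#' deduplicated across tables.
#'
#' @param tables a data.frame or list of data.frames.
#' @return a [VirusHostNetwork-class].
#' @export
loadVirusPpi <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t)
    data.frame(viral_protein = as.character(t$viral_protein),
               strain = as.character(t$strain),
               human_gene = toupper(as.character(t$human_gene)),
               stringsAsFactors = FALSE)))
  bad <- !nzchar(df$viral_protein) | is.na(df$viral_protein) |
    !nzchar(df$human_gene) | is.na(df$human_gene)
  if (any(bad)) {
    warning(sum(bad), " row(s) with a missing endpoint rejected")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable interaction rows")
  df <- df[!duplicated(df[, c("viral_protein", "human_gene")]), ,
           drop = FALSE]
  viral <- unique(df[, c("viral_protein", "strain")])
  if (anyDuplicated(viral$viral_protein))
    viral <- viral[!duplicated(viral$viral_protein), , drop = FALSE]
  human <- unique(df$human_gene)
  nodes <- rbind(
    data.frame(name = viral$viral_protein, side = "viral",
               strain = viral$strain, stringsAsFactors = FALSE),
    data.frame(name = human, side = "human", strain = NA_character_,
               stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    df[, c("viral_protein", "human_gene")], directed = FALSE,
    vertices = nodes)
  methods::new("VirusHostNetwork", graph = g)
}

#' Counts of a virus-host network
#' @param x a [VirusHostNetwork-class].
#' @return named integer vector: viral_proteins, human_targets, edges,
#'   total_nodes, plus per-strain viral protein counts (`strain_<name>`).
#' @export
virusHostCounts <- function(x) {
  g <- x@graph
  side <- igraph::V(g)$side
  strains <- table(igraph::V(g)$strain[side == "viral"])
  c(viral_proteins = sum(side == "viral"),
    human_targets = sum(side == "human"),
    edges = igraph::ecount(g),
    total_nodes = igraph::vcount(g),
    stats::setNames(as.integer(strains), paste0("strain_", names(strains))))
}

#' Merge a virus-host network with a disease gene set
#'
#' Adds the disease genes as human nodes and their confidence-filtered
#' intra-set interactions as human-human edges, keeping all virus-host
#' edges.
#'
#' @param vhn a [VirusHostNetwork-class].
#' @param disease a disease gene set from [selectDiseaseGenes()].
#' @return an [IntegratedVirusDiseaseNetwork-class].
#' @export
integrateVirusDisease <- function(vhn, disease) {
  g <- vhn@graph
  newGenes <- setdiff(disease$genes$gene, igraph::V(g)$name)
  if (length(newGenes))
    g <- igraph::add_vertices(g, length(newGenes), name = newGenes,
                              side = "human", strain = NA_character_)
  ppi <- disease$ppi
  if (nrow(ppi)) {
    a <- toupper(ppi$gene_a); b <- toupper(ppi$gene_b)
    keep <- a != b
    g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
    g <- igraph::simplify(g)
  }
  methods::new("IntegratedVirusDiseaseNetwork", graph = g,
               disease = disease$disease)
}

#' Viral targets plus their first human neighbours
#'
#' The direct human targets of the viral proteins, together with every
#' human node adjacent to a target in the integrated network (viral nodes
#' excluded from the result).
#'
#' @param x an [IntegratedVirusDiseaseNetwork-class] or
#'   [VirusHostNetwork-class].
#' @return sorted character vector of human gene symbols.
#' @export
targetsPlusNeighbors <- function(x) {
  g <- networkGraph(x)
  side <- igraph::V(g)$side
  viral <- igraph::V(g)[side == "viral"]
  if (length(viral) == 0L) return(character(0))
  targets <- unique(unlist(lapply(igraph::adjacent_vertices(g, viral),
                                  function(v) v$name)))
  targets <- intersect(targets, igraph::V(g)$name[side == "human"])
  if (length(targets) == 0L) return(character(0))
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(g, igraph::V(g)[targets]),
    function(v) v$name[v$side == "human"])))
  sort(unique(c(targets, nb)))
}

#' Immune terms modulated by both virus and microbiota
#'
#' The plain intersection of the two significant term sets; when the
#' taxon-to-term projection is supplied, also reports, per common term, the
#' taxa whose projection covers it.
#'
#' @param virus_terms significant terms of the viral-target enrichment.
#' @param microbiota_terms significant terms of the microbiota network.
#' @param projection optional taxon -> term projection.
#' @return list (`terms`, and `taxa_per_term` when a projection is given).
#' @export
commonIsps <- function(virus_terms, microbiota_terms, projection = NULL) {
  common <- sort(intersect(virus_terms, microbiota_terms))
  out <- list(terms = common)
  if (!is.null(projection)) {
    out$taxa_per_term <- lapply(stats::setNames(common, common), function(t)
      sort(names(projection)[vapply(projection, function(f) t %in% f,
                                    logical(1))]))
  }
  out
}

#' Cluster microbiota together with the virus over common terms
#'
#' Restricts the taxon-to-term projection to the common terms (taxa
#' covering none are dropped), appends the virus as one extra all-ones row
#' (the common terms are by construction exactly its significant terms
#' restricted to the microbiota set) and delegates to [clusterProfiles()].
#'
#' @param projection taxon -> term projection.
#' @param virus_terms the virus's significant terms.
#' @param k clusters for the cut.
#' @param virus_name entity label of the appended virus row.
#' @param ... passed to [clusterProfiles()].
#' @return a [DendrogramResult-class] with the virus as one entity.
#' @export
clusterWithVirus <- function(projection, virus_terms, k,
                             virus_name = "VIRUS1", ...) {
  common <- sort(intersect(virus_terms, unique(unlist(projection))))
  if (length(common) == 0L) stop("no common terms between virus and taxa")
  restricted <- lapply(projection, intersect, common)
  restricted <- restricted[lengths(restricted) > 0L]
  restricted[[virus_name]] <- common
  mat <- incidenceFromProjection(restricted)
  if (k > nrow(mat)) stop("k cannot exceed ", nrow(mat), " entities")
  clusterProfiles(jaccardDistance(mat), k = k, ...)
}
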