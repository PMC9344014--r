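#' Normalise a taxon name
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space and capitalises the first letter. Genus-only and
#' genus+species forms remain distinct entities.
#'
#' @param x character vector of raw taxon names.
#' @return normalised character vector.
#' @export
#' @examples
#' normalizeTaxonName("  escherichia   coli ")
normalizeTaxonName <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  has <- nzchar(x)
  x[has] <- paste0(toupper(substring(x[has], 1L, 1L)), substring(x[has], 2L))
  x
}

## canonical undirected edge keys: "<type>|<min endpoint>|<max endpoint>"
canonicalEdgeKeys <- function(g) {
  if (igraph::ecount(g) == 0L) return(character(0))
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  et <- igraph::edge_attr(g, "edge_type")
  if (is.null(et)) et <- rep("", nrow(ends))
  et <- vapply(strsplit(et, "-", fixed = TRUE),
               function(p) paste(sort(p), collapse = "-"), character(1))
  paste(et, pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]),
        sep = "|")
}

## assemble a LayeredNetwork from a node table (name, type) and an edge table
## (from, to); edge_type derived from endpoint types in declared order
makeLayeredNetwork <- function(nodes, edges) {
  stopifnot(all(c("name", "type") %in% names(nodes)))
  nodes <- unique(nodes[, c("name", "type")])
  if (anyDuplicated(nodes$name))
    stop("node name used with more than one type")
  if (nrow(edges)) {
    tp <- stats::setNames(nodes$type, nodes$name)
    missing <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(missing))
      stop("dangling edge endpoint(s): ", paste(utils::head(missing, 5), collapse = ", "))
    edges$edge_type <- paste(tp[edges$from], tp[edges$to], sep = "-")
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        edge_type = character(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  methods::new("LayeredNetwork", graph = g)
}

## zero-row-safe typed node table
nodeDf <- function(names, type) {
  data.frame(name = names, type = rep(type, length(names)),
             stringsAsFactors = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}
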