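## Pairwise network rewiring: common / left-only / right-only node and edge
## classes plus a scalar score. The score is this package's own summary —
## the Jaccard distance of the canonical edge sets — not the multi-network
## variance statistic of interactive rewiring tools.

#' Compare two networks element-wise
#'
#' Classifies node identifiers and canonicalised undirected edges (sorted
#' endpoint pair plus edge type; attributes and direction ignored) as
#' common, left-only or right-only, and scores rewiring as
#' `1 - |common edges| / |edge union|` (0 when both edge sets are empty).
#' Swapping the arguments swaps the left/right classes and preserves the
#' score.
#'
#' @param left,right [LayeredNetwork-class] objects (or subclasses) with a
#'   comparable node naming scheme.
#' @param names optional character(2) naming the two networks.
#' @return a [RewiringReport-class].
#' @export
compareNetworks <- function(left, right, names = c("left", "right")) {
  ln <- igraph::V(left@graph)$name %||% character(0)
  rn <- igraph::V(right@graph)$name %||% character(0)
  le <- canonicalEdgeKeys(left@graph)
  re <- canonicalEdgeKeys(right@graph)
  uni <- union(le, re)
  score <- if (length(uni) == 0L) 0 else
    1 - length(intersect(le, re)) / length(uni)
  methods::new("RewiringReport",
               networkNames = names,
               nodes = list(common = sort(intersect(ln, rn)),
                            left_only = sort(setdiff(ln, rn)),
                            right_only = sort(setdiff(rn, ln))),
               edges = list(common = sort(intersect(le, re)),
                            left_only = sort(setdiff(le, re)),
                            right_only = sort(setdiff(re, le))),
               score = score)
}

#' @describeIn rewiringScore the edge-set Jaccard distance
#' @export
setMethod("rewiringScore", "RewiringReport", function(x) x@score)

#' @describeIn resultTable class counts of a rewiring report
#' @export
setMethod("resultTable", "RewiringReport", function(x)
  data.frame(class = c("common", "left_only", "right_only"),
             nodes = lengths(x@nodes)[c("common", "left_only", "right_only")],
             edges = lengths(x@edges)[c("common", "left_only", "right_only")],
             row.names = NULL))

#' Score all network pairs
#'
#' @param networks named list of [LayeredNetwork-class] objects.
#' @return data.frame (network_a, network_b, score) over all unordered
#'   pairs, sorted by descending score then lexicographic name pair.
#' @export
rankPairs <- function(networks) {
  if (length(networks) < 2L) stop("need at least two networks")
  nms <- names(networks)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("networks must carry unique non-empty names")
  pairs <- utils::combn(sort(nms), 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(p)
    data.frame(network_a = p[1L], network_b = p[2L],
               score = rewiringScore(
                 compareNetworks(networks[[p[1L]]], networks[[p[2L]]], p)),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$score, out$network_a, out$network_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a rewiring report
#'
#' @param x a [RewiringReport-class].
#' @param json optional JSON summary path.
#' @param classes_tsv optional per-element class TSV path (id, kind, class).
#' @return invisibly, the list of written paths.
#' @export
writeRewiringReport <- function(x, json = NULL, classes_tsv = NULL) {
  written <- list()
  if (!is.null(json)) {
    jsonlite::write_json(list(
      networks = x@networkNames,
      score = x@score,
      node_counts = lapply(x@nodes, length),
      edge_counts = lapply(x@edges, length)),
      json, auto_unbox = TRUE, pretty = TRUE)
    written$json <- json
  }
  if (!is.null(classes_tsv)) {
    rows <- do.call(rbind, c(
      lapply(c("common", "left_only", "right_only"), function(cl)
        if (length(x@nodes[[cl]]))
          data.frame(id = x@nodes[[cl]], kind = "node", class = cl)),
      lapply(c("common", "left_only", "right_only"), function(cl)
        if (length(x@edges[[cl]]))
          data.frame(id = x@edges[[cl]], kind = "edge", class = cl))))
    if (is.null(rows))
      rows <- data.frame(id = character(0), kind = character(0),
                         class = character(0))
    written$classes <- writeTsv(rows, classes_tsv)
  }
  invisible(written)
}
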