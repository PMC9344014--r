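## Jaccard-distance agglomerative clustering of binary feature profiles,
## with linkage selection by cophenetic correlation.

#' Binary incidence matrix from a projection
#'
#' Rows are entities, columns the sorted union of their features; cell 1
#' iff the entity carries the feature. Projections never contain empty
#' feature sets, so no all-zero rows arise.
#'
#' @param projection a named list entity -> character vector of features
#'   (as returned by [projectLayers()]).
#' @return a binary integer matrix with dimnames.
#' @export
incidenceFromProjection <- function(projection) {
  if (length(projection) == 0L) stop("projection is empty")
  feats <- sort(unique(unlist(projection)))
  m <- matrix(0L, nrow = length(projection), ncol = length(feats),
              dimnames = list(names(projection), feats))
  for (e in names(projection)) m[e, projection[[e]]] <- 1L
  m
}

#' Jaccard distance between binary profiles
#'
#' d(a, b) = 1 - |A intersect B| / |A union B| on the row supports.
#'
#' @param mat binary matrix with >=2 rows and no all-zero rows.
#' @return a `dist` object.
#' @export
jaccardDistance <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least two rows")
  if (any(rowSums(mat) == 0)) stop("all-zero rows are not allowed")
  vegan::vegdist(mat, method = "jaccard", binary = TRUE)
}

#' Agglomerative clustering with cophenetic linkage validation
#'
#' Builds a merge tree with each candidate linkage, computes the Pearson
#' correlation between the cophenetic distances of the tree and the input
#' distances, selects the method with the highest correlation (ties broken
#' by candidate order) and cuts the selected tree into `k` clusters (or at
#' height `h`).
#'
#' @param d a `dist` object.
#' @param methods candidate linkages, passed to [stats::hclust()].
#' @param k number of clusters to cut (ignored if `h` given).
#' @param h optional cut height, alternative to `k`.
#' @return a [DendrogramResult-class].
#' @export
clusterProfiles <- function(d,
                            methods = c("average", "complete", "single",
                                        "ward.D2"),
                            k = 2L, h = NULL) {
  n <- attr(d, "Size")
  trees <- lapply(methods, function(m) stats::hclust(d, method = m))
  cors <- vapply(trees, function(tr) {
    cp <- stats::cophenetic(tr)
    ## a single pair (or constant distances) makes the correlation
    ## undefined; every linkage fits such data perfectly
    if (length(cp) < 2L || stats::sd(cp) == 0 || stats::sd(d) == 0)
      return(1)
    stats::cor(d, cp)
  }, numeric(1))
  names(cors) <- methods
  best <- which.max(cors)
  tree <- trees[[best]]
  if (!is.null(h)) {
    labels <- stats::cutree(tree, h = h)
    k <- length(unique(labels))
  } else {
    if (k > n) stop("k cannot exceed the number of entities (", n, ")")
    labels <- stats::cutree(tree, k = k)
  }
  methods::new("DendrogramResult", hclust = tree, method = methods[best],
               copheneticCor = cors,
               labels = stats::setNames(as.integer(labels), names(labels)),
               k = as.integer(k))
}

#' @describeIn coClustered TRUE iff the two entities share a cut label
#' @export
setMethod("coClustered", "DendrogramResult", function(x, a, b) {
  for (e in c(a, b)) if (!e %in% names(x@labels))
    stop("unknown entity: ", e)
  unname(x@labels[a] == x@labels[b])
})

#' @describeIn resultTable cluster labels as a data.frame
#' @export
setMethod("resultTable", "DendrogramResult", function(x)
  data.frame(entity = names(x@labels), cluster = unname(x@labels),
             stringsAsFactors = FALSE))

#' Export a dendrogram result
#'
#' @param x a [DendrogramResult-class].
#' @param newick optional Newick tree output path (via \pkg{ape}).
#' @param labels_tsv optional cluster-label TSV path.
#' @return invisibly, the list of written paths.
#' @export
exportDendrogram <- function(x, newick = NULL, labels_tsv = NULL) {
  written <- list()
  if (!is.null(newick)) {
    ape::write.tree(ape::as.phylo(x@hclust), file = newick)
    written$newick <- newick
  }
  if (!is.null(labels_tsv))
    written$labels <- writeTsv(resultTable(x), labels_tsv)
  invisible(written)
}
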