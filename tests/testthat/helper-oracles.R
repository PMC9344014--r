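## Independent oracles used across the suite. These deliberately use naive
## algorithms (enumeration, node deletion, O(n^2) loops) so they stay
## independent of the implementation paths they check.

## Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
## n-subsets of a universe of size N containing K marked elements.
enumHyperUpper <- function(N, K, n, k) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2L, function(s) sum(s %in% marked) >= k)
  mean(hits)
}

## Articulation points by brute force: a vertex is an articulation point
## iff deleting it increases the number of connected components.
bruteArticulation <- function(g) {
  base <- igraph::components(g)$no
  nms <- igraph::V(g)$name
  isolated <- igraph::degree(g) == 0
  out <- character(0)
  for (v in nms) {
    h <- igraph::delete_vertices(g, v)
    ## deleting an isolated vertex removes its own component
    delta <- igraph::components(h)$no - (base - as.integer(isolated[v == nms]))
    if (delta > 0) out <- c(out, v)
  }
  sort(out)
}

## Pairwise shared-item weights by an O(n^2) intersection loop.
bruteCommonalityEdges <- function(entity_items, minShared = 1L) {
  nms <- names(entity_items)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i >= j) next
    w <- length(intersect(entity_items[[i]], entity_items[[j]]))
    if (w >= minShared)
      rows[[length(rows) + 1L]] <- data.frame(
        from = min(nms[i], nms[j]), to = max(nms[i], nms[j]), weight = w)
  }
  if (length(rows) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      weight = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$from, out$to), , drop = FALSE]
}

## A deterministic random commonality instance.
randomEntityItems <- function(n_entities, n_items, mean_size = 4L) {
  items <- sprintf("i%02d", seq_len(n_items))
  out <- lapply(seq_len(n_entities), function(i)
    sample(items, sample(seq_len(min(mean_size * 2L, n_items)), 1L)))
  names(out) <- sprintf("e%02d", seq_len(n_entities))
  out
}

## Small annotation builder.
tinyAnnotation <- function(terms, universe = NULL)
  annotation(terms, universe = universe)

## A tiny valid record collection.
tinyRecords <- function() {
  metaboliteRecords(
    c("M1", "M2", "M3"),
    c("butyrate-like", "indole-like", "ergothioneine-like"),
    biofluids = list(c("FECES", "SERUM"), "FECES", c("SERUM", "CSF")),
    kingdoms = list("BACTERIA", "BACTERIA", "FUNGI"),
    source_taxa = list(c("Escherichia coli", "Lactobacillus"),
                       character(0), "Saccharomyces boulardii"))
}

sentinels <- c("Unnamed bacteria", "Unnamed fungi")

namedTaxonItems <- function(bundle) {
  tm <- bundle$taxon_metabolite
  tm <- tm[!tm$taxon %in% sentinels, , drop = FALSE]
  split(tm$metabolite_id, tm$taxon)
}
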