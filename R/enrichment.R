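## Over-representation analysis against a gene-set annotation (e.g. the
## immune-system-process branch of GO supplied as GMT), with BH control and
## Cohen's-kappa grouping of significant terms into functional groups.

#' Read a GMT annotation
#'
#' Lines of `term_id <tab> term_name <tab> gene1 <tab> gene2 ...`. The
#' universe defaults to the union of all annotated genes.
#'
#' @param path GMT file path.
#' @return an annotation: list with elements `terms` (named list of gene
#'   vectors), `termNames` (named character) and `universe`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("GMT lines need term_id, term_name and >=1 gene")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  terms <- lapply(parts, function(p) sort(unique(toupper(p[-(1:2)]))))
  names(terms) <- ids
  annotation(terms, vapply(parts, `[[`, character(1), 2L))
}

#' Construct an annotation object
#'
#' @param terms named list of gene character vectors (non-empty each).
#' @param termNames optional display names, recycled from ids.
#' @param universe optional reference gene set; defaults to the union of all
#'   term genes. Every term must be a subset of it.
#' @return annotation list (`terms`, `termNames`, `universe`).
#' @export
annotation <- function(terms, termNames = names(terms), universe = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  if (any(lengths(terms) == 0L)) stop("term gene sets must be non-empty")
  terms <- lapply(terms, function(g) sort(unique(toupper(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  else {
    universe <- sort(unique(toupper(universe)))
    if (!all(unlist(terms) %in% universe))
      stop("every term gene set must be contained in the universe")
  }
  list(terms = terms,
       termNames = stats::setNames(as.character(termNames), names(terms)),
       universe = universe)
}

#' Write an annotation as GMT
#' @param ann annotation (see [annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(ann, path) {
  lines <- vapply(names(ann$terms), function(id)
    paste(c(id, ann$termNames[[id]], ann$terms[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term with gene set of size K, tests the overlap k of
#' the query (size n, after intersection with the universe of size N) with
#' the one-sided upper tail P(X >= k) of the hypergeometric distribution,
#' then controls the FDR across terms with Benjamini-Hochberg. Terms with no
#' overlap receive p = 1.
#'
#' @param query character vector of gene symbols.
#' @param ann annotation (see [annotation()]).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param universe optional override of the annotation universe.
#' @return an [EnrichmentResult-class] with rows sorted by adjusted p, then
#'   term id.
#' @export
hypergeometricORA <- function(query, ann, alpha = 0.05, universe = NULL) {
  if (length(ann$terms) == 0L) stop("annotation has no terms")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  uni <- if (is.null(universe)) ann$universe else sort(unique(toupper(universe)))
  query <- intersect(unique(toupper(query)), uni)
  if (length(query) == 0L)
    stop("query is empty after intersecting with the universe")
  N <- length(uni)
  n <- length(query)
  K <- lengths(lapply(ann$terms, intersect, uni))
  k <- vapply(ann$terms, function(g) length(intersect(g, query)), integer(1))
  raw_p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  adjusted <- bhAdjust(raw_p)
  tb <- data.frame(term_id = names(ann$terms),
                   term_name = unname(ann$termNames[names(ann$terms)]),
                   k = unname(k), K = unname(K), n = n, N = N,
                   raw_p = unname(raw_p), adjusted_p = unname(adjusted),
                   significant = unname(adjusted <= alpha),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$adjusted_p, tb$term_id), , drop = FALSE]
  rownames(tb) <- NULL
  methods::new("EnrichmentResult", table = tb, alpha = alpha, query = query)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; input order preserved. Values must lie
#' in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @describeIn significantTerms significant term ids, in result order
#' @export
setMethod("significantTerms", "EnrichmentResult", function(x)
  x@table$term_id[x@table$significant])

#' @describeIn resultTable the per-term enrichment table
#' @export
setMethod("resultTable", "EnrichmentResult", function(x) x@table)

## Cohen's kappa on the 2x2 contingency of two membership vectors over the
## query; degenerate all-agree tables (chance agreement 1) map to 1/0.
cohenKappa <- function(inA, inB) {
  n <- length(inA)
  a <- sum(inA & inB); b <- sum(inA & !inB)
  c_ <- sum(!inA & inB); d <- sum(!inA & !inB)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Group significant terms by kappa similarity
#'
#' Computes Cohen's kappa between every pair of significant terms on the
#' 2x2 contingency of query-gene membership, links pairs with kappa at or
#' above the threshold and takes connected components as functional groups
#' (a hard partition). Each group is led by its smallest-adjusted-p term
#' (ties: larger term size K, then lexicographic term id) and reports its
#' percentage of all significant terms.
#'
#' @param result an [EnrichmentResult-class] with >=1 significant term.
#' @param ann the annotation used for the enrichment.
#' @param kappa_threshold linkage threshold in [-1, 1]; default 0.4.
#' @return a [TermGrouping-class].
#' @export
kappaGroupTerms <- function(result, ann, kappa_threshold = 0.4) {
  if (kappa_threshold < -1 || kappa_threshold > 1)
    stop("kappa_threshold must lie in [-1, 1]")
  tb <- resultTable(result)
  sig <- tb[tb$significant, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant terms to group")
  query <- result@query
  memb <- vapply(sig$term_id, function(t) query %in% ann$terms[[t]],
                 logical(length(query)))
  memb <- matrix(memb, nrow = length(query),
                 dimnames = list(NULL, sig$term_id))
  pairs <- utils::combn(sig$term_id, 2L, simplify = FALSE)
  if (nrow(sig) == 1L) pairs <- list()
  kap <- vapply(pairs, function(p) cohenKappa(memb[, p[1L]], memb[, p[2L]]),
                numeric(1))
  edges <- data.frame(
    term_a = vapply(pairs, `[[`, character(1), 1L),
    term_b = vapply(pairs, `[[`, character(1), 2L),
    kappa = kap, stringsAsFactors = FALSE)
  edges <- edges[edges$kappa >= kappa_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, 1:2],
                                     directed = FALSE,
                                     vertices = sig$term_id)
  comp <- igraph::components(g)$membership
  membership <- data.frame(term_id = names(comp),
                           group = unname(comp), stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(membership$term_id, membership$group),
    function(ts) {
      rows <- sig[match(ts, sig$term_id), , drop = FALSE]
      o <- order(rows$adjusted_p, -rows$K, rows$term_id)
      data.frame(leading_term = rows$term_id[o[1L]],
                 n_terms = length(ts),
                 percent_of_terms = 100 * length(ts) / nrow(sig),
                 stringsAsFactors = FALSE)
    }))
  groups$group <- as.integer(rownames(groups))
  groups <- groups[order(-groups$n_terms, groups$leading_term),
                   c("group", "leading_term", "n_terms", "percent_of_terms")]
  rownames(groups) <- NULL
  methods::new("TermGrouping", membership = membership, groups = groups,
               kappaEdges = edges, threshold = kappa_threshold)
}

#' @describeIn resultTable the per-group summary of a term grouping
#' @export
setMethod("resultTable", "TermGrouping", function(x) x@groups)

#' Write an enrichment report as TSV
#'
#' Columns: term, name, k, K, n, N, raw_p, adjusted_p and, when a grouping
#' is supplied, group and leading_term for the significant terms.
#'
#' @param result an [EnrichmentResult-class].
#' @param path output path.
#' @param grouping optional [TermGrouping-class].
#' @return `path`, invisibly.
#' @export
writeEnrichmentTsv <- function(result, path, grouping = NULL) {
  tb <- resultTable(result)
  if (!is.null(grouping)) {
    i <- match(tb$term_id, grouping@membership$term_id)
    tb$group <- grouping@membership$group[i]
    tb$leading_term <-
      grouping@groups$leading_term[match(tb$group, grouping@groups$group)]
  }
  writeTsv(tb, path)
}
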