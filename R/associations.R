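## Association tables. Both tables are plain data.frames:
##   metabolite->gene: (metabolite_id, gene_symbol, evidence)
##   taxon->metabolite: (taxon, kingdom, metabolite_id)
## Gene identity is the uppercased symbol string; no alias resolution.

#' Construct a metabolite-to-gene association table
#'
#' @param metabolite_id,gene_symbol,evidence equal-length vectors; evidence
#'   defaults to "SYNTH". Gene symbols are uppercased; rows with empty
#'   symbols are rejected with a warning; duplicate (metabolite, gene) pairs
#'   are collapsed (evidence tags concatenated with "+").
#' @return data.frame (metabolite_id, gene_symbol, evidence).
#' @export
geneAssociationTable <- function(metabolite_id, gene_symbol,
                                 evidence = "SYNTH") {
  df <- data.frame(metabolite_id = as.character(metabolite_id),
                   gene_symbol = toupper(trimws(as.character(gene_symbol))),
                   evidence = as.character(evidence),
                   stringsAsFactors = FALSE)
  bad <- !nzchar(df$gene_symbol)
  if (any(bad)) {
    warning(sum(bad), " row(s) with empty gene symbol rejected")
    df <- df[!bad, , drop = FALSE]
  }
  dedupGenePairs(df)
}

dedupGenePairs <- function(df) {
  key <- paste(df$metabolite_id, df$gene_symbol, sep = "\r")
  ev <- vapply(split(df$evidence, key), function(e)
    paste(sort(unique(unlist(strsplit(e, "+", fixed = TRUE)))),
          collapse = "+"), character(1))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$evidence <- ev[paste(out$metabolite_id, out$gene_symbol, sep = "\r")]
  out <- out[order(out$metabolite_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge metabolite-to-gene tables with pair-level deduplication
#'
#' The union of all rows, deduplicated on (metabolite_id, gene_symbol);
#' distinct evidence tags for the same pair are concatenated with "+". The
#' operation is commutative, associative and idempotent at the pair level.
#'
#' @param tables list of association tables (see [geneAssociationTable()]).
#' @return one merged table.
#' @export
mergeGeneAssociations <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  dedupGenePairs(do.call(rbind, tables))
}

#' Metabolite gene-coverage summary
#'
#' @param records merged metabolite record collection.
#' @param gene_table metabolite-to-gene association table.
#' @return named integer vector `with_associations` / `without_associations`;
#'   the two always sum to the number of records.
#' @export
coverageSummary <- function(records, gene_table) {
  with <- sum(records$metabolite_id %in% gene_table$metabolite_id)
  c(with_associations = with,
    without_associations = nrow(records) - with)
}

#' Taxon-to-metabolite table from metabolite records
#'
#' One row per (taxon, metabolite) pair. Metabolites whose record names a
#' kingdom but no source taxon are attributed to the sentinel entities
#' "Unnamed bacteria" / "Unnamed fungi", one row per kingdom, so that no
#' microbially derived metabolite silently leaves the analysis.
#'
#' @param records merged metabolite record collection.
#' @return data.frame (taxon, kingdom, metabolite_id), deduplicated.
#' @export
taxonMetaboliteTable <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    taxa <- records$source_taxa[[i]]
    kins <- records$kingdoms[[i]]
    if (length(taxa)) {
      data.frame(taxon = taxa, kingdom = kins[1L],
                 metabolite_id = records$metabolite_id[i],
                 stringsAsFactors = FALSE)
    } else {
      sent <- c(BACTERIA = "Unnamed bacteria", FUNGI = "Unnamed fungi")[kins]
      data.frame(taxon = unname(sent), kingdom = kins,
                 metabolite_id = records$metabolite_id[i],
                 stringsAsFactors = FALSE)
    }
  })
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$taxon, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname readAssociationTsv
#' @param df table to write.
#' @param path file path.
#' @export
writeAssociationTsv <- function(df, path) writeTsv(df, path)

#' Read/write association tables as TSV
#'
#' Plain tab-separated files with a header row; columns as produced by
#' [geneAssociationTable()] or [taxonMetaboliteTable()].
#'
#' @return the data.frame (reader) or `path` invisibly (writer).
#' @export
readAssociationTsv <- function(path) readTsv(path, colClasses = "character")
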