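## Metabolite record I/O: a compact XML dialect carrying the only fields the
## pipeline consumes from metabolome-database exports — accession, display
## name, biospecimen locations and microbial biological disposition:
##
##   <metabolites>
##     <metabolite>
##       <accession>M00001</accession>
##       <name>metabolite 1</name>
##       <biospecimen_locations>
##         <biospecimen>Feces</biospecimen>
##       </biospecimen_locations>
##       <biological_disposition>
##         <source kingdom="Bacteria">Escherichia coli</source>
##         <source kingdom="Bacteria"/>   <!-- kingdom known, taxon unnamed -->
##       </biological_disposition>
##     </metabolite>
##   </metabolites>
##
## Records are held in a data.frame with list-columns for the three set-valued
## fields; sets are stored sorted so equality is order-insensitive.

#' Construct a metabolite record collection
#'
#' @param metabolite_id character vector of unique accessions.
#' @param name display names.
#' @param biofluids list of character vectors, subsets of FECES/SERUM/CSF.
#' @param kingdoms list of character vectors, subsets of BACTERIA/FUNGI;
#'   must be non-empty per record.
#' @param source_taxa list of character vectors of taxon names (possibly
#'   empty); names are normalised with [normalizeTaxonName()].
#' @return a data.frame of records with list-columns.
#' @export
metaboliteRecords <- function(metabolite_id, name = metabolite_id,
                              biofluids, kingdoms,
                              source_taxa = rep(list(character(0)),
                                                length(metabolite_id))) {
  if (anyDuplicated(metabolite_id))
    stop("metabolite_id values must be unique")
  norm <- function(v, allowed = NULL) {
    v <- sort(unique(as.character(v)))
    if (!is.null(allowed) && any(!v %in% allowed))
      stop("unknown label(s): ", paste(setdiff(v, allowed), collapse = ", "))
    v
  }
  biofluids <- lapply(biofluids, norm, allowed = BIOFLUIDS)
  kingdoms <- lapply(kingdoms, norm, allowed = KINGDOMS)
  if (any(lengths(kingdoms) == 0L))
    stop("every record must have at least one kingdom")
  source_taxa <- lapply(source_taxa, function(v)
    sort(unique(normalizeTaxonName(as.character(v)))))
  df <- data.frame(metabolite_id = as.character(metabolite_id),
                   name = as.character(name), stringsAsFactors = FALSE)
  df$biofluids <- biofluids
  df$kingdoms <- kingdoms
  df$source_taxa <- source_taxa
  df
}

#' Write metabolite records to the XML dialect
#'
#' Emits one `<metabolite>` element per record; parsing the file with
#' [parseMetaboliteXml()] reproduces the records exactly (set fields are
#' order-insensitive).
#'
#' @param records a record collection from [metaboliteRecords()] or
#'   [parseMetaboliteXml()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetaboliteXml <- function(records, path) {
  if (nrow(records) == 0L) stop("records must be non-empty")
  doc <- xml2::xml_new_root("metabolites")
  fluidLabel <- c(FECES = "Feces", SERUM = "Serum",
                  CSF = "Cerebrospinal Fluid (CSF)")
  kingdomLabel <- c(BACTERIA = "Bacteria", FUNGI = "Fungi")
  for (i in seq_len(nrow(records))) {
    m <- xml2::xml_add_child(doc, "metabolite")
    xml2::xml_add_child(m, "accession", records$metabolite_id[i])
    xml2::xml_add_child(m, "name", records$name[i])
    bl <- xml2::xml_add_child(m, "biospecimen_locations")
    for (f in records$biofluids[[i]])
      xml2::xml_add_child(bl, "biospecimen", fluidLabel[[f]])
    bd <- xml2::xml_add_child(m, "biological_disposition")
    taxa <- records$source_taxa[[i]]
    ## kingdoms with no named taxon still get an empty <source/>
    namedKingdoms <- character(0)
    if (length(taxa)) {
      kg <- attr(records$source_taxa[[i]], "kingdom_of")
      for (t in taxa) {
        k <- if (!is.null(kg)) kg[[t]] else records$kingdoms[[i]][1L]
        src <- xml2::xml_add_child(bd, "source", t)
        xml2::xml_set_attr(src, "kingdom", kingdomLabel[[k]])
        namedKingdoms <- c(namedKingdoms, k)
      }
    }
    for (k in setdiff(records$kingdoms[[i]], namedKingdoms)) {
      src <- xml2::xml_add_child(bd, "source")
      xml2::xml_set_attr(src, "kingdom", kingdomLabel[[k]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## map a free-text biospecimen label onto FECES/SERUM/CSF; NA when unknown
.matchBiofluid <- function(label) {
  l <- tolower(trimws(label))
  if (grepl("feces|faeces|stool", l)) return("FECES")
  if (grepl("serum|blood", l)) return("SERUM")
  if (grepl("cerebrospinal|csf", l)) return("CSF")
  NA_character_
}

#' Parse metabolite XML, retaining microbially derived records
#'
#' Reads the documented XML dialect and keeps only records whose biological
#' disposition mentions bacteria and/or fungi (case-insensitive token match
#' on the `kingdom` attribute); all other records are dropped and their
#' count reported via a message. Named source taxa are extracted and
#' normalised when present. Unknown biospecimen labels raise a warning and
#' are ignored.
#'
#' @param path path to an XML file in the documented dialect.
#' @return a record collection data.frame (see [metaboliteRecords()]).
#' @export
parseMetaboliteXml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in '", path, "': ", conditionMessage(e)))
  mets <- xml2::xml_find_all(doc, ".//metabolite")
  ids <- nms <- character(0)
  bios <- kins <- taxa <- list()
  dropped <- 0L
  for (m in mets) {
    srcs <- xml2::xml_find_all(m, "./biological_disposition/source")
    kat <- tolower(xml2::xml_attr(srcs, "kingdom"))
    isBac <- grepl("bacteria", kat)
    isFun <- grepl("fungi", kat)
    kset <- c(if (any(isBac)) "BACTERIA", if (any(isFun)) "FUNGI")
    if (length(kset) == 0L) { dropped <- dropped + 1L; next }
    fl <- xml2::xml_text(
      xml2::xml_find_all(m, "./biospecimen_locations/biospecimen"))
    mapped <- vapply(fl, .matchBiofluid, character(1))
    if (anyNA(mapped))
      warning("ignoring unknown biospecimen label(s): ",
              paste(fl[is.na(mapped)], collapse = ", "))
    keep <- isBac | isFun
    tx <- trimws(xml2::xml_text(srcs[keep]))
    tx <- tx[nzchar(tx)]
    ids <- c(ids, xml2::xml_text(xml2::xml_find_first(m, "./accession")))
    nms <- c(nms, xml2::xml_text(xml2::xml_find_first(m, "./name")))
    bios <- c(bios, list(sort(unique(mapped[!is.na(mapped)]))))
    kins <- c(kins, list(sort(kset)))
    taxa <- c(taxa, list(tx))
  }
  if (dropped > 0L)
    message(dropped, " record(s) without microbial disposition dropped")
  if (length(ids) == 0L)
    return(metaboliteRecords(character(0), character(0), list(), list(),
                             list())[0, ])
  metaboliteRecords(ids, nms, bios, kins, taxa)
}

#' Merge per-biofluid record collections
#'
#' Records sharing a `metabolite_id` are merged by union of their biofluid,
#' kingdom and source-taxon sets. Conflicting display names keep the first
#' occurrence with a warning.
#'
#' @param ... record collections (e.g. parsed from the feces, serum and CSF
#'   exports).
#' @return one deduplicated record collection.
#' @export
mergeBiofluidCollections <- function(...) {
  all <- do.call(rbind, list(...))
  if (is.null(all) || nrow(all) == 0L) stop("nothing to merge")
  ids <- unique(all$metabolite_id)
  pick <- lapply(ids, function(id) {
    rows <- all[all$metabolite_id == id, , drop = FALSE]
    if (length(unique(rows$name)) > 1L)
      warning("conflicting names for ", id, "; keeping '", rows$name[1L], "'")
    list(id = id, name = rows$name[1L],
         biofluids = sort(unique(unlist(rows$biofluids))),
         kingdoms = sort(unique(unlist(rows$kingdoms))),
         taxa = sort(unique(unlist(rows$source_taxa))))
  })
  metaboliteRecords(
    vapply(pick, `[[`, character(1), "id"),
    vapply(pick, `[[`, character(1), "name"),
    lapply(pick, `[[`, "biofluids"),
    lapply(pick, `[[`, "kingdoms"),
    lapply(pick, `[[`, "taxa"))
}

#' Partition records by microbial kingdom
#'
#' @param records merged record collection.
#' @return named integer vector with elements `bacteria_only`, `fungi_only`,
#'   `both` and `total`; the first three always sum to the fourth.
#' @export
partitionByKingdom <- function(records) {
  hasB <- vapply(records$kingdoms, function(k) "BACTERIA" %in% k, logical(1))
  hasF <- vapply(records$kingdoms, function(k) "FUNGI" %in% k, logical(1))
  c(bacteria_only = sum(hasB & !hasF),
    fungi_only = sum(!hasB & hasF),
    both = sum(hasB & hasF),
    total = nrow(records))
}

#' Three-set biofluid overlap (Venn regions)
#'
#' Counts, for the kingdom-matching subset of the records, the seven Venn
#' regions of membership in feces, serum and CSF. Records with no biofluid
#' are excluded from the regions (and from the reported total).
#'
#' @param records merged record collection.
#' @param kingdom "BACTERIA", "FUNGI" or "ANY" (any retained record).
#' @return named integer vector of the seven region counts plus `total`.
#' @export
biofluidOverlap <- function(records, kingdom = c("ANY", "BACTERIA", "FUNGI")) {
  kingdom <- match.arg(kingdom)
  keep <- if (kingdom == "ANY") rep(TRUE, nrow(records)) else
    vapply(records$kingdoms, function(k) kingdom %in% k, logical(1))
  fl <- records$biofluids[keep]
  fl <- fl[lengths(fl) > 0L]
  key <- vapply(fl, function(v) paste(sort(v), collapse = "+"), character(1))
  regions <- c("FECES", "SERUM", "CSF", "FECES+SERUM", "CSF+FECES",
               "CSF+SERUM", "CSF+FECES+SERUM")
  out <- stats::setNames(integer(length(regions)), regions)
  tab <- table(key)
  out[names(tab)] <- as.integer(tab)
  names(out) <- c("feces_only", "serum_only", "csf_only", "feces_serum",
                  "feces_csf", "serum_csf", "all_three")
  c(out, total = length(fl))
}
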