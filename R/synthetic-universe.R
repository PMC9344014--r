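## Synthetic input universe with planted structure: block-model taxon
## clusters on the taxon x metabolite incidence, enrichment terms planted to
## overlap the metabolite target genes, one articulation taxon bridging two
## otherwise-disconnected clusters, configurable disease/viral overlap.
## Everything is drawn from a single seeded RNG stream, so a config plus
## seed fully determines the bundle.

#' Configuration of the synthetic universe
#'
#' @param seed RNG seed (integer).
#' @param n_taxa number of clustered taxa (one extra bridging taxon is
#'   appended when `k_clusters >= 2`).
#' @param n_metabolites total metabolites; at least
#'   `k_clusters * repertoire_size`.
#' @param n_genes gene universe size.
#' @param n_terms annotation terms.
#' @param k_clusters planted taxon clusters.
#' @param repertoire_size metabolites in each cluster's core repertoire.
#' @param noise_rate probability of flipping one taxon/metabolite
#'   membership, in [0, 1].
#' @param term_size_range integer (min, max) genes per term, within
#'   [1, n_genes].
#' @param n_enriched_terms terms planted to overlap the target genes.
#' @param planted_overlap fraction of a planted term's genes drawn from the
#'   metabolite target genes (default 0.9).
#' @param disease_overlap_frac fraction of each disease's genes drawn from
#'   metabolite-target genes, in [0, 1].
#' @param n_disease_genes genes per disease.
#' @param n_diseases number of diseases (default 4).
#' @param virus_target_frac fraction of viral targets drawn from disease
#'   genes, in [0, 1].
#' @param n_viral_proteins viral proteins of the single virus entity
#'   ("VIRUS1", with strain labels on proteins).
#' @return validated config list of class `UniverseConfig`.
#' @export
universeConfig <- function(seed = 1L, n_taxa = 60L, n_metabolites = 120L,
                           n_genes = 400L, n_terms = 30L, k_clusters = 3L,
                           repertoire_size = 12L, noise_rate = 0.05,
                           term_size_range = c(10L, 30L),
                           n_enriched_terms = 5L, planted_overlap = 0.9,
                           disease_overlap_frac = 0.5,
                           n_disease_genes = 40L, n_diseases = 4L,
                           virus_target_frac = 0.5,
                           n_viral_proteins = 20L) {
  cfg <- list(seed = seed, n_taxa = n_taxa, n_metabolites = n_metabolites,
              n_genes = n_genes, n_terms = n_terms, k_clusters = k_clusters,
              repertoire_size = repertoire_size, noise_rate = noise_rate,
              term_size_range = term_size_range,
              n_enriched_terms = n_enriched_terms,
              planted_overlap = planted_overlap,
              disease_overlap_frac = disease_overlap_frac,
              n_disease_genes = n_disease_genes, n_diseases = n_diseases,
              virus_target_frac = virus_target_frac,
              n_viral_proteins = n_viral_proteins)
  posInt <- c("n_taxa", "n_metabolites", "n_genes", "n_terms", "k_clusters",
              "repertoire_size", "n_enriched_terms", "n_disease_genes",
              "n_diseases", "n_viral_proteins")
  for (f in posInt) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("invalid config field '", f, "': must be a positive integer")
  }
  for (f in c("noise_rate", "disease_overlap_frac", "virus_target_frac",
              "planted_overlap")) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("invalid config field '", f, "': must lie in [0, 1]")
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("invalid config field 'seed': must be an integer")
  if (cfg$k_clusters > cfg$n_taxa)
    stop("invalid config field 'k_clusters': must not exceed n_taxa")
  tr <- cfg$term_size_range
  if (length(tr) != 2L || any(tr < 1) || any(tr > cfg$n_genes) ||
      tr[1L] > tr[2L])
    stop("invalid config field 'term_size_range': need 1 <= min <= max <= n_genes")
  if (cfg$k_clusters * cfg$repertoire_size > cfg$n_metabolites)
    stop("invalid config field 'repertoire_size': k_clusters * ",
         "repertoire_size exceeds n_metabolites")
  if (cfg$n_enriched_terms > cfg$n_terms)
    stop("invalid config field 'n_enriched_terms': must not exceed n_terms")
  if (cfg$n_disease_genes > cfg$n_genes)
    stop("invalid config field 'n_disease_genes': must not exceed n_genes")
  structure(cfg, class = "UniverseConfig")
}

#' Generate the synthetic input universe
#'
#' Deterministic given the config (same config, same seed: byte-identical
#' bundle). Ground truth records the planted cluster assignment of every
#' clustered taxon, the planted enriched terms, the planted articulation
#' taxon and the per-disease planted intersection genes.
#'
#' @param config a [universeConfig()].
#' @return a list (bundle) with elements `records`, `taxon_metabolite`,
#'   `gene_table`, `annotation`, `gene_universe`, `diseases`, `virus_ppi`
#'   and `truth`.
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "UniverseConfig"))
  set.seed(config$seed)
  k <- config$k_clusters

  ## --- taxa: mixed genus-only / genus+species names, mostly bacteria
  genus <- sprintf("Genusium%03d", seq_len(config$n_taxa))
  taxa <- ifelse(seq_len(config$n_taxa) %% 2L == 0L,
                 paste0(genus, " sp", seq_len(config$n_taxa)), genus)
  taxa <- normalizeTaxonName(taxa)
  kingdomOf <- stats::setNames(
    ifelse(stats::runif(config$n_taxa) < 0.85, "BACTERIA", "FUNGI"), taxa)
  clusters <- stats::setNames(sort(rep_len(seq_len(k), config$n_taxa)), taxa)
  bridge <- NA_character_
  if (k >= 2L) {
    bridge <- "Pontibacter articulans"
    kingdomOf[bridge] <- "BACTERIA"
  }
  allTaxa <- c(taxa, if (!is.na(bridge)) bridge)

  ## --- metabolites: disjoint core repertoire per cluster, rest free
  mets <- sprintf("M%05d", seq_len(config$n_metabolites))
  core <- split(mets[seq_len(k * config$repertoire_size)],
                rep(seq_len(k), each = config$repertoire_size))
  member <- matrix(FALSE, length(allTaxa), config$n_metabolites,
                   dimnames = list(allTaxa, mets))
  for (t in taxa) member[t, core[[clusters[[t]]]]] <- TRUE
  if (!is.na(bridge)) {
    nb <- max(1L, ceiling(config$repertoire_size / 3))
    member[bridge, c(core[[1L]][seq_len(nb)], core[[2L]][seq_len(nb)])] <- TRUE
  }
  if (config$noise_rate > 0) {
    flips <- matrix(stats::runif(length(member)) < config$noise_rate,
                    nrow = nrow(member))
    member <- xor(member, flips)
    empty <- rowSums(member) == 0L
    for (t in rownames(member)[empty]) {
      cl <- if (!is.na(bridge) && t == bridge) 1L else clusters[[t]]
      member[t, core[[cl]][1L]] <- TRUE
    }
  }
  tmRows <- which(member, arr.ind = TRUE)
  taxon_metabolite <- data.frame(
    taxon = rownames(member)[tmRows[, 1L]],
    kingdom = unname(kingdomOf[rownames(member)[tmRows[, 1L]]]),
    metabolite_id = colnames(member)[tmRows[, 2L]],
    stringsAsFactors = FALSE)

  ## orphan metabolites keep a kingdom through the unnamed sentinels
  orphan <- mets[colSums(member) == 0L]
  orphanKingdom <- stats::setNames(
    ifelse(stats::runif(length(orphan)) < 0.9, "BACTERIA", "FUNGI"), orphan)
  if (length(orphan)) {
    sent <- c(BACTERIA = "Unnamed bacteria", FUNGI = "Unnamed fungi")
    taxon_metabolite <- rbind(taxon_metabolite, data.frame(
      taxon = unname(sent[orphanKingdom]), kingdom = unname(orphanKingdom),
      metabolite_id = orphan, stringsAsFactors = FALSE))
  }
  taxon_metabolite <-
    taxon_metabolite[order(taxon_metabolite$taxon,
                           taxon_metabolite$metabolite_id), , drop = FALSE]
  rownames(taxon_metabolite) <- NULL

  ## --- metabolite records (biofluids skewed gut -> blood -> CSF)
  biofluids <- lapply(seq_along(mets), function(i) {
    fl <- c("FECES", "SERUM", "CSF")[stats::runif(3) <
                                       c(0.85, 0.65, 0.25)]
    if (length(fl) == 0L) fl <- "FECES"
    fl
  })
  metKingdoms <- lapply(mets, function(m) {
    tx <- taxon_metabolite$taxon[taxon_metabolite$metabolite_id == m]
    sort(unique(unname(
      c(kingdomOf[setdiff(tx, SENTINEL_TAXA)],
        if (m %in% orphan) orphanKingdom[[m]]))))
  })
  metTaxa <- lapply(mets, function(m)
    setdiff(taxon_metabolite$taxon[taxon_metabolite$metabolite_id == m],
            SENTINEL_TAXA))
  records <- metaboliteRecords(mets, paste0("metabolite ", seq_along(mets)),
                               biofluids, metKingdoms, metTaxa)

  ## --- metabolite -> gene associations from a coherent target pool
  genes <- sprintf("G%06d", seq_len(config$n_genes))
  pool <- genes[seq_len(max(10L, floor(0.35 * config$n_genes)))]
  covered <- sort(sample(mets, size = max(1L, floor(0.75 * length(mets)))))
  assoc <- do.call(rbind, lapply(covered, function(m) {
    ng <- sample(5:12, 1L)
    data.frame(metabolite_id = m,
               gene_symbol = sample(pool, min(ng, length(pool))),
               stringsAsFactors = FALSE)
  }))
  gene_table <- geneAssociationTable(assoc$metabolite_id,
                                     assoc$gene_symbol, evidence = "SYNTH")
  targeted <- sort(unique(gene_table$gene_symbol))

  ## --- annotation: planted terms overlap the targeted genes heavily
  termIds <- sprintf("GO:%07d", seq_len(config$n_terms))
  sizes <- sample(seq(config$term_size_range[1L], config$term_size_range[2L]),
                  config$n_terms, replace = TRUE)
  planted <- termIds[seq_len(config$n_enriched_terms)]
  terms <- lapply(seq_len(config$n_terms), function(i) {
    sz <- sizes[i]
    if (termIds[i] %in% planted) {
      nin <- min(ceiling(config$planted_overlap * sz), length(targeted))
      c(sample(targeted, nin),
        sample(setdiff(genes, targeted), sz - nin))
    } else {
      sample(genes, sz)
    }
  })
  names(terms) <- termIds
  ann <- annotation(terms,
                    termNames = paste("immune process", seq_len(config$n_terms)),
                    universe = genes)

  ## --- diseases: controlled overlap with the targeted genes
  ## disease genes overlap the metabolite targets by the configured
  ## fraction. The diseases emulated here are immune-associated, and a real
  ## disease gene set concentrates on specific processes, so each disease
  ## draws its overlapping genes preferentially from the (targeted) genes
  ## of two of the planted immune terms before falling back to the rest of
  ## the target pool
  diseaseNames <- paste0("ND", seq_len(config$n_diseases))
  nOver <- round(config$disease_overlap_frac * config$n_disease_genes)
  diseases <- lapply(diseaseNames, function(d) {
    own <- sample(planted, min(2L, length(planted)))
    focal <- intersect(sort(unique(unlist(terms[own]))), targeted)
    nImm <- min(nOver, length(focal))
    overlap <- c(sample(focal, nImm),
                 sample(setdiff(targeted, focal),
                        min(nOver, length(targeted)) - nImm))
    rest <- sample(setdiff(genes, targeted),
                   config$n_disease_genes - length(overlap))
    dg <- c(overlap, rest)
    scores <- round(sort(stats::runif(length(dg), 0.5, 1),
                         decreasing = TRUE), 4)
    nEdge <- 2L * config$n_disease_genes
    ends <- replicate(nEdge, sample(dg, 2L))
    ppi <- unique(data.frame(gene_a = pmin(ends[1L, ], ends[2L, ]),
                             gene_b = pmax(ends[1L, ], ends[2L, ]),
                             stringsAsFactors = FALSE))
    ppi$confidence <- round(stats::runif(nrow(ppi), 0.4, 1), 3)
    list(disease = d,
         scored = data.frame(gene = dg, score = scores,
                             stringsAsFactors = FALSE),
         ppi = ppi,
         planted_intersection = sort(overlap))
  })
  names(diseases) <- diseaseNames

  ## --- virus: one organism, strain labels on proteins
  vp <- sprintf("VP%03d", seq_len(config$n_viral_proteins))
  strains <- c("STRAIN-A", "STRAIN-B", "STRAIN-C", "STRAIN-D")
  strainOf <- sample(strains, config$n_viral_proteins, replace = TRUE)
  diseaseUnion <- sort(unique(unlist(lapply(diseases, function(d)
    d$scored$gene))))
  ## the virus targets the immune-relevant gene space: a configurable share
  ## of its targets are disease genes, most of the remainder come from the
  ## planted immune-term genes (so viral-target enrichment shares immune
  ## terms with the microbiota, as in the host-virus system this emulates)
  ## and the rest is random background
  plantedGenes <- sort(unique(unlist(terms[planted])))
  drawTargets <- function(nt) {
    nd <- min(round(config$virus_target_frac * nt), length(diseaseUnion))
    tg <- sample(diseaseUnion, nd)
    nimm <- min(round(0.8 * (nt - nd)),
                length(setdiff(plantedGenes, tg)))
    tg <- c(tg, sample(setdiff(plantedGenes, tg), nimm))
    rest <- setdiff(genes, tg)
    c(tg, sample(rest, min(nt - length(tg), length(rest))))
  }
  virus_ppi <- do.call(rbind, lapply(seq_along(vp), function(i) {
    data.frame(viral_protein = vp[i], strain = strainOf[i],
               human_gene = drawTargets(sample(3:8, 1L)),
               stringsAsFactors = FALSE)
  }))
  virus_ppi <- virus_ppi[!duplicated(
    virus_ppi[, c("viral_protein", "human_gene")]), , drop = FALSE]
  rownames(virus_ppi) <- NULL

  truth <- list(
    clusters = clusters,
    articulation_taxon = bridge,
    enriched_terms = planted,
    targeted_genes = targeted,
    coverage = c(with_associations = length(covered),
                 without_associations = length(mets) - length(covered)),
    disease_intersection = lapply(diseases, `[[`, "planted_intersection"),
    seed = config$seed)

  list(records = records, taxon_metabolite = taxon_metabolite,
       gene_table = gene_table, annotation = ann, gene_universe = genes,
       diseases = diseases, virus_ppi = virus_ppi, truth = truth,
       config = config)
}

#' Write a universe bundle to disk
#'
#' Emits the per-biofluid metabolite XML files (the dialect parsed by
#' [parseMetaboliteXml()]), the association TSVs, the GMT annotation, the
#' per-disease gene and interaction TSVs, the virus-host TSV, and the
#' ground truth as a JSON sidecar.
#'
#' @param bundle a bundle from [generateUniverse()].
#' @param dir output directory (created if needed).
#' @return invisibly, named list of written paths.
#' @export
writeUniverse <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  written <- list()
  for (fluid in BIOFLUIDS) {
    sel <- vapply(bundle$records$biofluids, function(b) fluid %in% b,
                  logical(1))
    if (any(sel)) {
      f <- p(paste0("metabolites_", tolower(fluid), ".xml"))
      writeMetaboliteXml(bundle$records[sel, , drop = FALSE], f)
      written[[paste0("xml_", tolower(fluid))]] <- f
    }
  }
  written$taxon_metabolite <- writeTsv(bundle$taxon_metabolite,
                                       p("taxon_metabolite.tsv"))
  written$gene_table <- writeTsv(bundle$gene_table,
                                 p("metabolite_gene.tsv"))
  written$gmt <- writeGmt(bundle$annotation, p("annotation.gmt"))
  writeLines(bundle$gene_universe, p("gene_universe.txt"))
  written$gene_universe <- p("gene_universe.txt")
  for (d in names(bundle$diseases)) {
    written[[paste0(d, "_genes")]] <-
      writeTsv(bundle$diseases[[d]]$scored, p(paste0(d, "_genes.tsv")))
    written[[paste0(d, "_ppi")]] <-
      writeTsv(bundle$diseases[[d]]$ppi, p(paste0(d, "_ppi.tsv")))
  }
  written$virus_ppi <- writeTsv(bundle$virus_ppi, p("virus_ppi.tsv"))
  jsonlite::write_json(bundle$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written$truth <- p("ground_truth.json")
  invisible(written)
}
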