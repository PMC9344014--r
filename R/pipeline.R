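## End-to-end orchestration: simulate (or load) inputs, then parse ->
## associations -> enrichment -> multipartite network -> projections ->
## clustering -> commonality -> per-disease overlays -> virus overlay ->
## pairwise rewiring, with a checksum manifest for reproducibility.

#' Assemble a pipeline configuration
#'
#' Either `simulate` (a [universeConfig()]) or `input_dir` (a directory
#' written by [writeUniverse()]) must be supplied.
#'
#' @param simulate optional [universeConfig()]; when given, inputs are
#'   generated in memory.
#' @param input_dir optional directory of previously written inputs.
#' @param alpha enrichment significance level.
#' @param kappa_threshold term-grouping kappa threshold.
#' @param linkage_methods candidate linkages for clustering.
#' @param k clusters for the taxon/metabolite cuts.
#' @param top_n ranking length for commonality topology.
#' @param confidence_cutoff disease interaction confidence cutoff.
#' @param virus_k clusters for the joint virus-taxon cut.
#' @return validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simulate = NULL, input_dir = NULL, alpha = 0.05,
                           kappa_threshold = 0.4,
                           linkage_methods = c("average", "complete",
                                               "single", "ward.D2"),
                           k = 3L, top_n = 10L, confidence_cutoff = 0.8,
                           virus_k = 3L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("config field missing: supply either 'simulate' or 'input_dir'")
  if (!is.null(simulate) && !inherits(simulate, "UniverseConfig"))
    stop("config field 'simulate' must be a universeConfig()")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("config field 'input_dir' does not exist: ", input_dir)
  if (alpha <= 0 || alpha >= 1) stop("config field 'alpha' outside (0, 1)")
  if (confidence_cutoff < 0 || confidence_cutoff > 1)
    stop("config field 'confidence_cutoff' outside [0, 1]")
  structure(list(simulate = simulate, input_dir = input_dir, alpha = alpha,
                 kappa_threshold = kappa_threshold,
                 linkage_methods = linkage_methods, k = as.integer(k),
                 top_n = as.integer(top_n),
                 confidence_cutoff = confidence_cutoff,
                 virus_k = as.integer(virus_k)),
            class = "PipelineConfig")
}

loadUniverseDir <- function(dir) {
  recs <- list()
  for (fluid in BIOFLUIDS) {
    f <- file.path(dir, paste0("metabolites_", tolower(fluid), ".xml"))
    if (file.exists(f)) recs[[fluid]] <- parseMetaboliteXml(f)
  }
  if (length(recs) == 0L) stop("no metabolite XML files in ", dir)
  records <- do.call(mergeBiofluidCollections, unname(recs))
  ann <- readGmt(file.path(dir, "annotation.gmt"))
  uniPath <- file.path(dir, "gene_universe.txt")
  universe <- if (file.exists(uniPath)) readLines(uniPath) else ann$universe
  ann <- annotation(ann$terms, ann$termNames, universe)
  gt <- readAssociationTsv(file.path(dir, "metabolite_gene.tsv"))
  tm <- readAssociationTsv(file.path(dir, "taxon_metabolite.tsv"))
  dFiles <- list.files(dir, pattern = "_genes\\.tsv$")
  diseases <- lapply(sub("_genes\\.tsv$", "", dFiles), function(d) {
    scored <- readTsv(file.path(dir, paste0(d, "_genes.tsv")))
    ppi <- readTsv(file.path(dir, paste0(d, "_ppi.tsv")))
    list(disease = d, scored = scored, ppi = ppi)
  })
  names(diseases) <- sub("_genes\\.tsv$", "", dFiles)
  list(records = records, taxon_metabolite = tm,
       gene_table = geneAssociationTable(gt$metabolite_id, gt$gene_symbol,
                                         gt$evidence),
       annotation = ann, gene_universe = ann$universe, diseases = diseases,
       virus_ppi = readTsv(file.path(dir, "virus_ppi.tsv")), truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or loaded inputs, writes per-stage
#' outputs under `output_dir` and returns a manifest with parameter values
#' and an MD5 checksum per output file. Re-running with the same config
#' reproduces identical checksums.
#'
#' @param config a [pipelineConfig()].
#' @param output_dir directory for stage outputs (created if needed).
#' @return invisibly, the manifest list (also written as manifest.json);
#'   with attribute `"results"` holding the in-memory stage objects.
#' @export
runPipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. inputs
  bundle <- stage("inputs", {
    if (!is.null(config$simulate)) generateUniverse(config$simulate)
    else loadUniverseDir(config$input_dir)
  })
  simdir <- out("inputs")
  if (!is.null(config$simulate)) stage("inputs", writeUniverse(bundle, simdir))

  ## 2. record accounting
  stage("records", {
    acc <- list(kingdom_partition = as.list(partitionByKingdom(bundle$records)),
                biofluid_overlap_bacteria =
                  as.list(biofluidOverlap(bundle$records, "BACTERIA")),
                biofluid_overlap_fungi =
                  as.list(biofluidOverlap(bundle$records, "FUNGI")),
                coverage = as.list(coverageSummary(bundle$records,
                                                   bundle$gene_table)))
    jsonlite::write_json(acc, out("record_accounting.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  ## 3. enrichment of metabolite target genes
  enr <- stage("enrichment", {
    e <- hypergeometricORA(unique(bundle$gene_table$gene_symbol),
                           bundle$annotation, alpha = config$alpha,
                           universe = bundle$gene_universe)
    if (length(significantTerms(e)) == 0L)
      stop("no significant terms at alpha = ", config$alpha)
    e
  })
  grouping <- stage("enrichment",
                    kappaGroupTerms(enr, bundle$annotation,
                                    config$kappa_threshold))
  stage("enrichment",
        writeEnrichmentTsv(enr, out("enrichment.tsv"), grouping))

  ## 4. multipartite network
  mmi <- stage("mmi", buildMmi(bundle$taxon_metabolite, bundle$gene_table,
                               enr, bundle$annotation, grouping,
                               records = bundle$records))
  stage("mmi", exportLayeredNetwork(mmi, graphml = out("mmi.graphml"),
                                    nodes_tsv = out("mmi_nodes.tsv"),
                                    edges_tsv = out("mmi_edges.tsv")))

  ## 5. projections
  projTG <- stage("projections", projectLayers(mmi, "TAXON", "GOISP"))
  projMG <- stage("projections", projectLayers(mmi, "METABOLITE", "GOISP"))
  projTM <- stage("projections", projectLayers(mmi, "TAXON", "METABOLITE"))

  ## 6. clustering (taxa and metabolites by immune-term profile)
  clustTaxa <- stage("clustering", {
    m <- incidenceFromProjection(projTG)
    clusterProfiles(jaccardDistance(m), methods = config$linkage_methods,
                    k = min(config$k, nrow(m)))
  })
  clustMet <- stage("clustering", {
    m <- incidenceFromProjection(projMG)
    clusterProfiles(jaccardDistance(m), methods = config$linkage_methods,
                    k = min(config$k, nrow(m)))
  })
  stage("clustering", {
    exportDendrogram(clustTaxa, newick = out("taxa_dendrogram.nwk"),
                     labels_tsv = out("taxa_clusters.tsv"))
    exportDendrogram(clustMet, newick = out("metabolite_dendrogram.nwk"),
                     labels_tsv = out("metabolite_clusters.tsv"))
  })

  ## 7. commonality graph over shared metabolites (named taxa only)
  commonal <- stage("commonality", {
    tm <- bundle$taxon_metabolite
    tm <- tm[!tm$taxon %in% SENTINEL_TAXA, , drop = FALSE]
    buildCommonality(split(tm$metabolite_id, tm$taxon))
  })
  topo <- stage("commonality", topologyReport(commonal, config$top_n))
  stage("commonality",
        exportCommonality(commonal, edges_tsv = out("commonality_edges.tsv"),
                          report_tsv = out("commonality_topology.tsv"),
                          top_n = config$top_n))

  ## 8. per-disease overlays
  overlays <- stage("disease_overlay", {
    lapply(bundle$diseases, function(d) {
      ds <- selectDiseaseGenes(d$scored, top_n = nrow(d$scored),
                               ppi_edges = d$ppi,
                               confidence_cutoff = config$confidence_cutoff,
                               disease = d$disease)
      denr <- hypergeometricORA(ds$genes$gene, bundle$annotation,
                                alpha = config$alpha,
                                universe = bundle$gene_universe)
      buildMmdi(ds, bundle$gene_table, bundle$taxon_metabolite, denr,
                bundle$annotation)
    })
  })
  stage("disease_overlay", {
    summ <- lapply(overlays, function(o) list(
      disease = o@disease,
      nodes = as.list(nodeCounts(o)), edges = as.list(edgeCounts(o)),
      intersection_nodes = length(o@intersectionNodes),
      isp_intersection_nodes = length(o@ispIntersectionNodes),
      goisp_coverage = as.list(goispCoverage(o))))
    if (length(overlays) >= 2L) {
      cmp <- compareOverlays(unname(overlays))
      summ$cross_disease_common <- lapply(cmp$common, length)
    }
    jsonlite::write_json(summ, out("overlay_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  ## 9. virus overlay
  virus <- stage("virus_overlay", {
    vhn <- loadVirusPpi(bundle$virus_ppi)
    venr <- hypergeometricORA(targetsPlusNeighbors(vhn), bundle$annotation,
                              alpha = config$alpha,
                              universe = bundle$gene_universe)
    ci <- commonIsps(significantTerms(venr), significantTerms(enr), projTG)
    joint <- if (length(ci$terms) >= 1L && length(projTG) >= 2L)
      clusterWithVirus(projTG, significantTerms(venr),
                       k = min(config$virus_k, length(projTG)))
    else NULL
    list(network = vhn, enrichment = venr, common = ci, joint = joint)
  })
  stage("virus_overlay", {
    jsonlite::write_json(list(
      counts = as.list(virusHostCounts(virus$network)),
      significant_terms = significantTerms(virus$enrichment),
      common_terms = virus$common$terms),
      out("virus_summary.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  })

  ## 10. pairwise rewiring of the disease overlays
  rewire <- stage("rewiring", {
    if (length(overlays) >= 2L) rankPairs(overlays) else NULL
  })
  if (!is.null(rewire))
    stage("rewiring", writeTsv(rewire, out("rewiring_pairs.tsv")))

  files <- sort(setdiff(list.files(output_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("MMInet")),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
    parameters = list(alpha = config$alpha,
                      kappa_threshold = config$kappa_threshold,
                      k = config$k, top_n = config$top_n,
                      confidence_cutoff = config$confidence_cutoff,
                      virus_k = config$virus_k),
    stages = c("inputs", "records", "enrichment", "mmi", "projections",
               "clustering", "commonality", "disease_overlay",
               "virus_overlay", "rewiring"),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(output_dir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(structure(manifest,
            results = list(bundle = bundle, enrichment = enr,
                           grouping = grouping, mmi = mmi,
                           projections = list(taxon_goisp = projTG,
                                              metabolite_goisp = projMG,
                                              taxon_metabolite = projTM),
                           clusters = list(taxa = clustTaxa,
                                           metabolites = clustMet),
                           commonality = commonal, topology = topo,
                           overlays = overlays, virus = virus,
                           rewiring = rewire)))
}
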