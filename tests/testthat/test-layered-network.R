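## small fixture shared by the construction tests
mmiFixture <- function() {
  uni <- sprintf("G%02d", 1:12)
  ann <- annotation(list(T1 = uni[1:4], T2 = uni[5:8], T3 = uni[9:12]),
                    universe = uni)
  gene_table <- geneAssociationTable(
    c("M1", "M1", "M2", "M3", "M4"),
    c("G01", "G05", "G05", "G09", "G12"))
  tm <- data.frame(
    taxon = c("Alpha", "Alpha", "Beta", "Gamma", "Unnamed bacteria"),
    kingdom = "BACTERIA",
    metabolite_id = c("M1", "M2", "M2", "M3", "M4"))
  query <- unique(gene_table$gene_symbol)
  enr <- hypergeometricORA(query, ann, alpha = 1 - 1e-6)
  list(ann = ann, gene_table = gene_table, tm = tm, enr = enr)
}

test_that("network construction links layers by the existential rule", {
  f <- mmiFixture()
  net <- buildMmi(f$tm, f$gene_table, f$enr, f$ann)
  g <- networkGraph(net)
  ## M1 targets G01 (T1) and G05 (T2); M2 targets G05 (T2) only
  expect_true(igraph::are_adjacent(g, "M1", "T1"))
  expect_true(igraph::are_adjacent(g, "M1", "T2"))
  expect_true(igraph::are_adjacent(g, "M2", "T2"))
  expect_false(igraph::are_adjacent(g, "M2", "T1"))
  ## taxa keep their surviving metabolites, sentinels included
  expect_true(igraph::are_adjacent(g, "Alpha", "M1"))
  expect_true(igraph::are_adjacent(g, "Unnamed bacteria", "M4"))

  nc <- nodeCounts(net)
  expect_equal(nc[["TAXON"]], 4L)
  expect_equal(nc[["METABOLITE"]], 4L)
  expect_equal(nc[["GOISP"]], 3L)
  expect_equal(nc[["Total"]], sum(nc[c("TAXON", "METABOLITE", "GENE",
                                       "GOISP")]))
  ec <- edgeCounts(net)
  expect_equal(ec[["Total"]],
               sum(ec[setdiff(names(ec), "Total")]))
})

test_that("metabolites without term links and orphaned taxa are pruned", {
  f <- mmiFixture()
  ## M5 targets a gene outside every term's significant overlap
  gt <- mergeGeneAssociations(list(
    f$gene_table, geneAssociationTable("M5", "G02")))
  tm <- rbind(f$tm, data.frame(taxon = "Delta", kingdom = "BACTERIA",
                               metabolite_id = "M5"))
  ## restrict enrichment so only T2 and T3 are significant
  ann2 <- annotation(list(T2 = sprintf("G%02d", 5:8),
                          T3 = sprintf("G%02d", 9:12)),
                     universe = sprintf("G%02d", 1:12))
  enr2 <- hypergeometricORA(unique(gt$gene_symbol), ann2, alpha = 1 - 1e-6)
  net <- buildMmi(tm, gt, enr2, ann2)
  g <- networkGraph(net)
  expect_false("M5" %in% igraph::V(g)$name)   # no significant-term gene
  expect_false("Delta" %in% igraph::V(g)$name)  # its only metabolite dropped
  expect_true("M1" %in% igraph::V(g)$name)    # M1 -> T2 via G05 survives
  expect_true("Alpha" %in% igraph::V(g)$name)
})

test_that("empty enrichment yields an empty network", {
  f <- mmiFixture()
  enr0 <- hypergeometricORA(f$enr@query, f$ann, alpha = 1e-12)
  expect_length(significantTerms(enr0), 0)
  net <- buildMmi(f$tm, f$gene_table, enr0, f$ann)
  expect_equal(igraph::vcount(networkGraph(net)), 0L)
})

test_that("referential failures name the dangling metabolite", {
  f <- mmiFixture()
  recs <- metaboliteRecords(c("M1", "M2", "M3"), c("a", "b", "c"),
                            rep(list("FECES"), 3), rep(list("BACTERIA"), 3))
  expect_error(buildMmi(f$tm, f$gene_table, f$enr, f$ann, records = recs),
               "M4")
})

test_that("projections follow direct edges and the two-step union", {
  f <- mmiFixture()
  net <- buildMmi(f$tm, f$gene_table, f$enr, f$ann)
  ## Alpha has M1 -> {T1, T2} and M2 -> {T2}
  ptg <- projectLayers(net, "TAXON", "GOISP")
  expect_equal(ptg$Alpha, c("T1", "T2"))
  ## sentinels are excluded from taxon-sourced projections by default
  expect_false("Unnamed bacteria" %in% names(ptg))
  expect_true("Unnamed bacteria" %in%
                names(projectLayers(net, "TAXON", "GOISP",
                                    includeUnnamed = TRUE)))
  pmg <- projectLayers(net, "METABOLITE", "GOISP")
  expect_equal(pmg$M1, c("T1", "T2"))
  expect_error(projectLayers(net, "GENE", "TAXON"), "unsupported")
})

test_that("taxon-term projection equals the boolean incidence product", {
  b <- generateUniverse(universeConfig(seed = 17, n_taxa = 20,
                                       n_metabolites = 60, noise_rate = 0.1))
  enr <- hypergeometricORA(unique(b$gene_table$gene_symbol), b$annotation,
                           alpha = 0.05, universe = b$gene_universe)
  net <- buildMmi(b$taxon_metabolite, b$gene_table, enr, b$annotation)
  ptg <- projectLayers(net, "TAXON", "GOISP", includeUnnamed = TRUE)
  ## oracle: boolean product of the two incidence matrices
  g <- networkGraph(net)
  taxa <- igraph::V(g)$name[igraph::V(g)$type == "TAXON"]
  mets <- igraph::V(g)$name[igraph::V(g)$type == "METABOLITE"]
  terms <- igraph::V(g)$name[igraph::V(g)$type == "GOISP"]
  A <- matrix(0L, length(taxa), length(mets), dimnames = list(taxa, mets))
  B <- matrix(0L, length(mets), length(terms), dimnames = list(mets, terms))
  ends <- igraph::ends(g, igraph::E(g))
  for (i in seq_len(nrow(ends))) {
    u <- ends[i, 1]; v <- ends[i, 2]
    if (u %in% taxa && v %in% mets) A[u, v] <- 1L
    if (v %in% taxa && u %in% mets) A[v, u] <- 1L
    if (u %in% mets && v %in% terms) B[u, v] <- 1L
    if (v %in% mets && u %in% terms) B[v, u] <- 1L
  }
  P <- (A %*% B) > 0
  for (t in names(ptg))
    expect_equal(ptg[[t]], sort(colnames(P)[P[t, ]]))
  ## per-type counts match a brute-force recount from the node table
  nc <- nodeCounts(net)
  expect_equal(nc[["TAXON"]], length(taxa))
  expect_equal(nc[["METABOLITE"]], length(mets))
  expect_equal(nc[["GOISP"]], length(terms))
})

test_that("network export writes GraphML and typed TSVs", {
  f <- mmiFixture()
  net <- buildMmi(f$tm, f$gene_table, f$enr, f$ann)
  gml <- withr::local_tempfile(fileext = ".graphml")
  nod <- withr::local_tempfile(fileext = ".tsv")
  edg <- withr::local_tempfile(fileext = ".tsv")
  exportLayeredNetwork(net, graphml = gml, nodes_tsv = nod, edges_tsv = edg)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), igraph::vcount(networkGraph(net)))
  ntab <- read.delim(nod)
  expect_setequal(ntab$node_type,
                  unique(igraph::V(networkGraph(net))$type))
})
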