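test_that("hypergeometric upper tail matches closed forms", {
  ## N=10, K=5, n=5, k=5: only 1 of C(10,5)=252 draws takes all marked genes
  uni <- sprintf("G%02d", 1:10)
  ann <- annotation(list(T1 = uni[1:5]), universe = uni)
  res <- hypergeometricORA(uni[1:5], ann, alpha = 0.05)
  expect_equal(resultTable(res)$raw_p, 1 / 252, tolerance = 1e-12)

  ## no overlap -> p = 1
  ann2 <- annotation(list(T1 = uni[1:5], T2 = uni[6:10]), universe = uni)
  res2 <- hypergeometricORA(uni[6:8], ann2)
  tb2 <- resultTable(res2)
  expect_equal(tb2$raw_p[tb2$term_id == "T1"], 1)

  ## query = universe -> k = K for every term and p = 1
  res3 <- hypergeometricORA(uni, ann2)
  tb3 <- resultTable(res3)
  expect_equal(tb3$k, tb3$K)
  expect_equal(tb3$raw_p, c(1, 1))
})

test_that("raw p equals exhaustive subset enumeration for small universes", {
  set.seed(21)
  for (rep in 1:6) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    uni <- sprintf("U%02d", seq_len(N))
    ann <- annotation(list(TT = uni[1:K]), universe = uni)
    query <- sample(uni, n)
    k <- length(intersect(query, uni[1:K]))
    got <- resultTable(hypergeometricORA(query, ann))$raw_p
    expect_equal(got, enumHyperUpper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("overlap monotonicity: larger k never increases raw p", {
  N <- 60L; K <- 20L; n <- 15L
  p <- stats::phyper(0:14, K, N - K, n, lower.tail = FALSE)
  ## same computation the package performs, asserted via the public surface
  uni <- sprintf("V%02d", seq_len(N))
  ann <- annotation(list(TT = uni[1:K]), universe = uni)
  ps <- vapply(1:10, function(k) {
    query <- c(uni[1:k], uni[(K + 1):(K + n - k)])
    resultTable(hypergeometricORA(query, ann))$raw_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bhAdjust(c(1e-4, 0.02, 0.03, 0.9)),
               c(4e-4, 0.04, 0.04, 0.9))
  expect_equal(bhAdjust(0.37), 0.37)                 # m = 1
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))   # all equal
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  ## adjusted >= raw, monotone along sorted raw p
  set.seed(8)
  p <- runif(40)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("ORA input contracts are enforced", {
  uni <- sprintf("G%02d", 1:10)
  ann <- annotation(list(T1 = uni[1:5]), universe = uni)
  expect_error(hypergeometricORA(c("ZZZ"), ann), "empty")
  expect_error(hypergeometricORA(uni[1:3], list(terms = list())), "no terms")
  expect_error(hypergeometricORA(uni[1:3], ann, alpha = 1.5), "alpha")
})

test_that("kappa grouping joins concordant terms and splits discordant ones", {
  uni <- sprintf("G%02d", 1:20)
  query <- uni[1:10]
  ## A and B identical; C disjoint from both within the query
  ann <- annotation(list(A = uni[1:5], B = uni[1:5], C = uni[6:10]),
                    universe = uni)
  res <- hypergeometricORA(query, ann, alpha = 1 - 1e-9)
  grp <- kappaGroupTerms(res, ann, kappa_threshold = 0.4)
  memb <- grp@membership
  expect_equal(memb$group[memb$term_id == "A"],
               memb$group[memb$term_id == "B"])      # kappa = 1
  expect_false(memb$group[memb$term_id == "C"] ==
                 memb$group[memb$term_id == "A"])    # kappa <= 0
  expect_equal(sum(resultTable(grp)$percent_of_terms), 100)
  ke <- grp@kappaEdges
  expect_equal(ke$kappa[ke$term_a == "A" & ke$term_b == "B"], 1)

  ## hand-computed 3-term fixture: only D-E crosses 0.4
  ## over query of 10 genes: D = {1..5}, E = {1..4,6}, F = {7..10}
  ## D vs E: a=4 b=1 c=1 d=4 -> po=.8, pe=.5, kappa=.6
  ann2 <- annotation(list(D = uni[1:5], E = uni[c(1:4, 6)], F = uni[7:10]),
                     universe = uni)
  res2 <- hypergeometricORA(query, ann2, alpha = 1 - 1e-9)
  grp2 <- kappaGroupTerms(res2, ann2, kappa_threshold = 0.4)
  ke2 <- grp2@kappaEdges
  expect_equal(nrow(ke2), 1L)
  expect_equal(sort(c(ke2$term_a, ke2$term_b)), c("D", "E"))
  expect_equal(ke2$kappa, 0.6, tolerance = 1e-12)
  m2 <- grp2@membership
  expect_equal(m2$group[m2$term_id == "D"], m2$group[m2$term_id == "E"])
  expect_equal(nrow(resultTable(grp2)), 2L)

  expect_error(kappaGroupTerms(res2, ann2, kappa_threshold = 2), "kappa")
})

test_that("planted terms are recovered and the FDR is controlled", {
  b <- generateUniverse(universeConfig(seed = 13))
  res <- hypergeometricORA(unique(b$gene_table$gene_symbol), b$annotation,
                           alpha = 0.05, universe = b$gene_universe)
  expect_true(all(b$truth$enriched_terms %in% significantTerms(res)))

  ## empirical FDR among non-planted terms over repeated random queries
  set.seed(31)
  fdrs <- replicate(60, {
    q <- sample(b$gene_universe, 150)
    tb <- resultTable(hypergeometricORA(q, b$annotation, alpha = 0.05,
                                        universe = b$gene_universe))
    disc <- tb$term_id[tb$significant]
    fp <- length(setdiff(disc, b$truth$enriched_terms))
    fp / max(1L, length(disc))
  })
  expect_lte(mean(fdrs), 0.10)
})

test_that("GMT files round-trip through the annotation object", {
  ann <- annotation(list(T1 = c("A", "B"), T2 = c("B", "C", "D")),
                    termNames = c("first", "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(ann, path)
  back <- readGmt(path)
  expect_equal(back$terms, ann$terms)
  expect_equal(back$termNames, ann$termNames)
  expect_equal(back$universe, ann$universe)
})
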