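test_that("incidence matrices mirror the projection memberships", {
  proj <- list(a = "f1", b = "f2")
  m <- incidenceFromProjection(proj)
  expect_equal(m, matrix(c(1L, 0L, 0L, 1L), 2,
                         dimnames = list(c("a", "b"), c("f1", "f2"))))
  proj2 <- list(x = c("f1", "f2", "f3"), y = "f2")
  m2 <- incidenceFromProjection(proj2)
  expect_equal(unname(m2["x", ]), c(1L, 1L, 1L))
  ## per-cell recount on a generated projection
  set.seed(5)
  proj3 <- lapply(setNames(1:8, paste0("e", 1:8)), function(i)
    sample(paste0("f", 1:6), sample(1:4, 1)))
  m3 <- incidenceFromProjection(proj3)
  for (e in names(proj3)) for (f in colnames(m3))
    expect_equal(m3[e, f], as.integer(f %in% proj3[[e]]))
})

test_that("Jaccard distances match direct set arithmetic", {
  m <- matrix(c(1, 1, 0,   # {x, y}
                0, 1, 1,   # {y, z}
                1, 1, 0),  # {x, y}
              nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  d <- as.matrix(jaccardDistance(m))
  expect_equal(d["a", "b"], 2 / 3)  # 1 - 1/3
  expect_equal(d["a", "c"], 0)      # identical rows
  m2 <- rbind(p = c(1, 1, 0, 0), q = c(0, 0, 1, 1))
  expect_equal(as.matrix(jaccardDistance(m2))["p", "q"], 1)  # disjoint
  expect_error(jaccardDistance(m[1, , drop = FALSE]), "two rows")
  expect_error(jaccardDistance(rbind(m, z = c(0, 0, 0))), "all-zero")
})

test_that("Jaccard distance behaves as a metric on random binary rows", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(rbinom(8 * 10, 1, 0.4), nrow = 8)
    m[rowSums(m) == 0, 1] <- 1
    rownames(m) <- paste0("r", 1:8)
    d <- as.matrix(jaccardDistance(m))
    expect_true(all(abs(d - t(d)) < 1e-12))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    for (i in 1:8) for (j in 1:8) for (l in 1:8)
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
  }
})

test_that("average linkage reproduces a hand-computed merge tree", {
  ## 5-point fixture; UPGMA worked by hand:
  ## merge {a,b} at .1; merge {c,d} at .2; d(cd,e)=mean(.5,.5)=.5 so
  ## merge {c,d,e} at .5; final merge at
  ## d(ab,cde)=mean(.8,.8,.6,.7,.9,.6)=4.4/6
  dm <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  dm["a", "b"] <- .1
  dm["a", "c"] <- .8; dm["a", "d"] <- .8
  dm["b", "c"] <- .7; dm["b", "d"] <- .9
  dm["a", "e"] <- .6; dm["b", "e"] <- .6
  dm["c", "d"] <- .2
  dm["c", "e"] <- .5; dm["d", "e"] <- .5
  dm <- dm + t(dm)
  res <- clusterProfiles(stats::as.dist(dm), methods = "average", k = 2)
  h <- res@hclust
  expect_equal(h$height, c(.1, .2, .5, 4.4 / 6), tolerance = 1e-12)
  expect_true(coClustered(res, "a", "b"))
  expect_true(coClustered(res, "c", "d"))
  expect_false(coClustered(res, "a", "c"))
})

test_that("linkage selection maximises cophenetic correlation", {
  set.seed(2)
  m <- matrix(rbinom(12 * 15, 1, 0.35), nrow = 12)
  m[rowSums(m) == 0, 1] <- 1
  rownames(m) <- paste0("t", 1:12)
  d <- jaccardDistance(m)
  res <- clusterProfiles(d, k = 3)
  cors <- res@copheneticCor
  expect_length(cors, 4)
  expect_equal(res@method, names(cors)[which.max(cors)])
  ## correlations independently recomputed
  for (meth in names(cors)) {
    tr <- stats::hclust(d, method = meth)
    expect_equal(cors[[meth]], stats::cor(d, stats::cophenetic(tr)),
                 tolerance = 1e-12)
  }
  expect_error(clusterProfiles(d, k = 50), "exceed")
})

test_that("two entities always split at k = 2 regardless of linkage ties", {
  m <- rbind(u = c(1, 0), v = c(0, 1))
  res <- clusterProfiles(jaccardDistance(m), k = 2)
  expect_false(coClustered(res, "u", "v"))
  expect_equal(res@method, "average")  # tie broken by candidate order
  res1 <- clusterProfiles(jaccardDistance(m), k = 1)
  expect_true(coClustered(res1, "u", "v"))
  expect_error(coClustered(res1, "u", "zz"), "unknown entity")
})

test_that("planted blocks are recovered exactly at zero noise", {
  b <- generateUniverse(universeConfig(seed = 3, noise_rate = 0,
                                       k_clusters = 3))
  items <- namedTaxonItems(b)
  m <- incidenceFromProjection(items)
  res <- clusterProfiles(jaccardDistance(m), k = 3)
  truth <- b$truth$clusters
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(res@labels[names(truth)], truth)
  expect_equal(ari, 1)
  ## entities with identical rows co-cluster at every k < n
  same <- names(truth)[truth == truth[[1]]]
  expect_true(coClustered(res, same[1], same[2]))
  ## entities in different planted blocks do not co-cluster
  other <- names(truth)[truth != truth[[1]]][1]
  expect_false(coClustered(res, same[1], other))
})

test_that("clustering is row-order equivariant on distinct profiles", {
  set.seed(14)
  m <- matrix(rbinom(10 * 12, 1, 0.4), nrow = 10)
  m[rowSums(m) == 0, 1] <- 1
  rownames(m) <- paste0("s", 1:10)
  m <- m[!duplicated(m), , drop = FALSE]
  res1 <- clusterProfiles(jaccardDistance(m), k = 3)
  perm <- sample(nrow(m))
  res2 <- clusterProfiles(jaccardDistance(m[perm, ]), k = 3)
  for (i in rownames(m)) for (j in rownames(m))
    expect_equal(coClustered(res1, i, j), coClustered(res2, i, j))
})

test_that("dendrogram export writes Newick and labels", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 1, 1))
  res <- clusterProfiles(jaccardDistance(m), k = 2)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  lab <- withr::local_tempfile(fileext = ".tsv")
  exportDendrogram(res, newick = nwk, labels_tsv = lab)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  expect_equal(nrow(read.delim(lab)), 3L)
})
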