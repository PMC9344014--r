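test_that("parser retains only microbially derived records and extracts taxa", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<metabolites>',
    ' <metabolite><accession>A1</accession><name>one</name>',
    '  <biospecimen_locations><biospecimen>Feces</biospecimen></biospecimen_locations>',
    '  <biological_disposition><source kingdom="Bacteria"/></biological_disposition>',
    ' </metabolite>',
    ' <metabolite><accession>A2</accession><name>two</name>',
    '  <biospecimen_locations><biospecimen>Serum</biospecimen></biospecimen_locations>',
    '  <biological_disposition><source kingdom="Plant">Arabidopsis</source></biological_disposition>',
    ' </metabolite>',
    ' <metabolite><accession>A3</accession><name>three</name>',
    '  <biospecimen_locations><biospecimen>Feces</biospecimen></biospecimen_locations>',
    '  <biological_disposition>',
    '   <source kingdom="bacteria">escherichia  coli</source>',
    '   <source kingdom="Fungi">Candida albicans</source>',
    '  </biological_disposition>',
    ' </metabolite>',
    '</metabolites>'), path)
  recs <- suppressMessages(parseMetaboliteXml(path))
  expect_equal(recs$metabolite_id, c("A1", "A3"))
  expect_equal(recs$kingdoms[[1]], "BACTERIA")
  expect_equal(recs$source_taxa[[1]], character(0))
  expect_equal(recs$kingdoms[[2]], c("BACTERIA", "FUNGI"))
  expect_setequal(recs$source_taxa[[2]],
                  c("Escherichia coli", "Candida albicans"))
  expect_message(parseMetaboliteXml(path), "1 record")
})

test_that("malformed XML and unknown biofluid labels are reported", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<metabolites><metabolite>", bad)
  expect_error(parseMetaboliteXml(bad), "malformed XML")

  odd <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<metabolites><metabolite><accession>A1</accession><name>x</name>',
    '<biospecimen_locations><biospecimen>Sweat</biospecimen>',
    '<biospecimen>Feces</biospecimen></biospecimen_locations>',
    '<biological_disposition><source kingdom="Bacteria"/></biological_disposition>',
    '</metabolite></metabolites>'), odd)
  expect_warning(recs <- parseMetaboliteXml(odd), "Sweat")
  expect_equal(recs$biofluids[[1]], "FECES")
})

test_that("write/parse round trip preserves records, including random ones", {
  recs <- tinyRecords()
  path <- withr::local_tempfile(fileext = ".xml")
  writeMetaboliteXml(recs, path)
  back <- parseMetaboliteXml(path)
  expect_equal(back, recs)

  ## property: 100 random records survive the round trip
  set.seed(11)
  n <- 100L
  rand <- metaboliteRecords(
    sprintf("R%03d", seq_len(n)),
    paste("met", seq_len(n)),
    biofluids = replicate(n, sample(c("FECES", "SERUM", "CSF"),
                                    sample(1:3, 1)), simplify = FALSE),
    kingdoms = replicate(n, sample(c("BACTERIA", "FUNGI"),
                                   sample(1:2, 1)), simplify = FALSE),
    source_taxa = replicate(n, {
      k <- sample(0:3, 1)
      if (k == 0) character(0) else sprintf("Genus%02d sp%d", sample(20, k), 1:k)
    }, simplify = FALSE))
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeMetaboliteXml(rand, p2)
  expect_equal(parseMetaboliteXml(p2), rand)

  ## parser idempotence: parse(write(parse(x))) == parse(x)
  p3 <- withr::local_tempfile(fileext = ".xml")
  writeMetaboliteXml(back, p3)
  expect_equal(parseMetaboliteXml(p3), back)
})

test_that("biofluid collections merge by id with set union", {
  a <- metaboliteRecords("M1", "one", list("FECES"), list("BACTERIA"))
  b <- metaboliteRecords("M1", "one", list("SERUM"), list("FUNGI"),
                         list("Aspergillus"))
  m <- mergeBiofluidCollections(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$biofluids[[1]], c("FECES", "SERUM"))
  expect_equal(m$kingdoms[[1]], c("BACTERIA", "FUNGI"))
  expect_equal(m$source_taxa[[1]], "Aspergillus")

  ## disjoint id sets just concatenate: 2 + 3 + 4 -> 9
  mk <- function(ids) metaboliteRecords(ids, ids,
    rep(list("FECES"), length(ids)), rep(list("BACTERIA"), length(ids)))
  expect_equal(nrow(mergeBiofluidCollections(mk(c("a", "b")),
                                             mk(c("c", "d", "e")),
                                             mk(c("f", "g", "h", "i")))), 9L)

  ## overlapping fixture with known union of size 7
  m7 <- mergeBiofluidCollections(mk(c("x1", "x2", "x3", "x4")),
                                 mk(c("x3", "x4", "x5", "x6", "x7")))
  expect_equal(sort(m7$metabolite_id), sprintf("x%d", 1:7))

  ## conflicting names keep the first and warn
  c1 <- metaboliteRecords("M9", "alpha", list("FECES"), list("BACTERIA"))
  c2 <- metaboliteRecords("M9", "beta", list("CSF"), list("BACTERIA"))
  expect_warning(mc <- mergeBiofluidCollections(c1, c2), "conflicting")
  expect_equal(mc$name, "alpha")
})

test_that("kingdom partition is exhaustive, disjoint and conserves totals", {
  empty <- tinyRecords()[0, ]
  expect_equal(unname(partitionByKingdom(empty)), c(0L, 0L, 0L, 0L))

  ## the published accounting: 157 bacteria-only + 11 fungi-only + 20 both
  n <- 157L + 11L + 20L
  kin <- c(rep(list("BACTERIA"), 157), rep(list("FUNGI"), 11),
           rep(list(c("BACTERIA", "FUNGI")), 20))
  recs <- metaboliteRecords(sprintf("H%03d", seq_len(n)), sprintf("h%d", 1:n),
                            rep(list("FECES"), n), kin)
  part <- partitionByKingdom(recs)
  expect_equal(part[["bacteria_only"]], 157L)
  expect_equal(part[["fungi_only"]], 11L)
  expect_equal(part[["both"]], 20L)
  expect_equal(part[["total"]], 188L)
  expect_equal(part[["bacteria_only"]] + part[["fungi_only"]] +
                 part[["both"]], part[["total"]])

  ## random fixture matches a per-record loop
  set.seed(3)
  kin2 <- replicate(50, sample(c("BACTERIA", "FUNGI"), sample(1:2, 1)),
                    simplify = FALSE)
  r2 <- metaboliteRecords(sprintf("K%02d", 1:50), sprintf("k%d", 1:50),
                          rep(list("SERUM"), 50), kin2)
  loop <- table(vapply(kin2, function(k)
    if (setequal(k, "BACTERIA")) "b" else if (setequal(k, "FUNGI")) "f"
    else "both", character(1)))
  p2 <- partitionByKingdom(r2)
  expect_equal(p2[["bacteria_only"]], unname(loop["b"]))
  expect_equal(p2[["both"]], unname(loop["both"]))
})

test_that("biofluid Venn regions sum to the record total", {
  all3 <- metaboliteRecords(sprintf("A%d", 1:4), sprintf("a%d", 1:4),
                            rep(list(c("FECES", "SERUM", "CSF")), 4),
                            rep(list("BACTERIA"), 4))
  ov <- biofluidOverlap(all3, "BACTERIA")
  expect_equal(ov[["all_three"]], 4L)
  expect_equal(sum(ov[1:7]), ov[["total"]])

  disj <- metaboliteRecords(sprintf("D%d", 1:3), sprintf("d%d", 1:3),
                            list("FECES", "SERUM", "CSF"),
                            rep(list("FUNGI"), 3))
  od <- biofluidOverlap(disj, "FUNGI")
  expect_equal(unname(od[c("feces_only", "serum_only", "csf_only")]),
               c(1L, 1L, 1L))
  expect_equal(sum(od[4:7]), 0L)

  ## hand-enumerated mixed fixture
  mixed <- metaboliteRecords(sprintf("X%d", 1:5), sprintf("x%d", 1:5),
                             list(c("FECES", "SERUM"), "FECES",
                                  c("FECES", "SERUM", "CSF"),
                                  c("SERUM", "CSF"), "FECES"),
                             rep(list("BACTERIA"), 5))
  om <- biofluidOverlap(mixed, "ANY")
  expect_equal(om[["feces_serum"]], 1L)
  expect_equal(om[["feces_only"]], 2L)
  expect_equal(om[["serum_csf"]], 1L)
  expect_equal(om[["all_three"]], 1L)
  expect_equal(om[["total"]], 5L)
  expect_error(biofluidOverlap(mixed, "ARCHAEA"))

  ## ANY equals the BACTERIA/FUNGI union for retained records
  expect_equal(biofluidOverlap(all3, "ANY"), biofluidOverlap(all3, "BACTERIA"))
})
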