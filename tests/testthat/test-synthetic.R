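test_that("all generators are deterministic functions of (config, seed)", {
  f1 <- genFamily(seed = 5); f2 <- genFamily(seed = 5)
  expect_identical(as.character(f1$proteins), as.character(f2$proteins))
  expect_identical(f1$truth, f2$truth)
  expect_false(identical(as.character(f1$proteins),
                         as.character(genFamily(seed = 6)$proteins)))

  c1 <- genCounts(seed = 3); c2 <- genCounts(seed = 3)
  expect_identical(c1$counts, c2$counts)

  x1 <- genCrossDataset(seed = 4); x2 <- genCrossDataset(seed = 4)
  expect_identical(progenyTable(x1$fwd), progenyTable(x2$fwd))
  expect_identical(progenyTable(x1$rev), progenyTable(x2$rev))

  p1 <- genTissuePanel(c(a = "pistil_specific", b = "ubiquitous"), seed = 2)
  p2 <- genTissuePanel(c(a = "pistil_specific", b = "ubiquitous"), seed = 2)
  expect_identical(p1$panel, p2$panel)
})

test_that("generator RNG is isolated from the caller's stream", {
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(genFamily(seed = 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("planted LPSC hits its target identity within tolerance", {
  for (s in 1:3) {
    fam <- genFamily(lpscSize = 4, lpscIdentity = 0.95, seed = s)
    ids <- fam$truth$id[fam$truth$lpsc]
    mpi <- meanPairwiseIdentity(as.character(fam$proteins)[ids])
    expect_equal(mpi, 0.95, tolerance = 0.032)
  }
})

test_that("family divergence parameters are validated and honoured", {
  expect_error(genFamily(withinClassDiv = 0.5, betweenClassDiv = 0.3),
               "withinClassDiv")
  fam <- genFamily(nPerClass = 3, withinClassDiv = 0.1, seed = 9)
  rows <- as.character(fam$proteins)
  # within-class pairwise p-distance ~ 2 d (1 - d)
  p <- pDistance(rows[c("cII_1", "cII_2")], 1, 2)
  expect_lt(abs(p - 2 * 0.1 * 0.9), 0.08)
  # CAS histidines preserved unless knocked out
  for (id in fam$truth$id) {
    aa <- strsplit(rows[[id]], "")[[1]]
    expect_equal(aa[fam$casPositions], c("H", "H"), info = id)
  }
})

test_that("planted genomic genes keep the CDS contiguous when intronless", {
  cds <- backTranslate(randProtein(60), 5)
  pg <- plantGene(cds, list(), seed = 5)
  expect_true(grepl(cds, pg$genomic, fixed = TRUE))
  expect_length(exons(pg$model), 1L)
  expect_error(plantGene(cds, list(list(offset = 0, length = 100))),
               "strictly inside")
  expect_error(plantGene(cds, list(list(offset = nchar(cds),
                                        length = 100))),
               "strictly inside")
})

test_that("small progeny counts degrade role recovery to inconclusive", {
  inconc <- vapply(1:40, function(s) {
    cr <- genCrossDataset(nForward = 10, nReciprocal = 10, seed = s)
    rt <- classifyMarkers(cr$fwd, cr$rev, cr$markers)
    any(rt$role == "inconclusive" |
          rt$role != unname(cr$truthRoles[rt$marker]))
  }, TRUE)
  expect_gt(mean(inconc), 0.10)
})

test_that("tissue panels classify back to their truth labels", {
  labs <- c(g1 = "pistil_specific", g2 = "pistil_plus_other",
            g3 = "ubiquitous", g4 = "not_detected")
  for (s in 1:5) {
    pan <- genTissuePanel(labs, seed = s)$panel
    got <- vapply(rownames(pan), function(g)
      tissueSpecificity(pan[g, ]), "")
    expect_equal(got, labs)
  }
  expect_error(genTissuePanel(c(a = "sometimes")), "unknown truth label")
})

test_that("miscall noise perturbs marker calls at the requested rate", {
  cr0 <- genCrossDataset(seed = 21, miscallRate = 0)
  cr1 <- genCrossDataset(seed = 21, miscallRate = 0.05)
  flips <- mapply(function(mk)
    mean(progenyTable(cr0$fwd)[[mk]] != progenyTable(cr1$fwd)[[mk]]),
    markerNames(cr0$fwd))
  expect_equal(mean(flips), 0.05, tolerance = 0.5)
  expect_error(genCrossDataset(miscallRate = 0.2), "miscallRate")
})
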