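test_that("spliced mapping handles intronless and planted-intron genes", {
  cds <- "ATGGCCGATTAA"
  m0 <- inferGeneStructure(cds, cds)
  expect_length(exons(m0), 1L)
  expect_equal(intronLengths(m0), integer(0))

  g <- paste0("ATGGCC", "GTAAGTTTTAG", "GATTAA")
  m1 <- inferGeneStructure(cds, g)
  expect_equal(intronLengths(m1), 11L)
  expect_equal(spliceSites(m1), "GT..AG")
  expect_equal(IRanges::start(exons(m1)), c(1L, 18L))

  expect_error(inferGeneStructure("ACGTACGT", "AAAAAAAACCCC"),
               "unmappable CDS")
  # CDS present twice with zero introns: ambiguous after all tie-breaks
  expect_error(inferGeneStructure("ACGT", "ACGTTTACGT"), "ambiguous")
})

test_that("plant-then-recover is exact for planted intron models", {
  set.seed(67)
  for (k in 1:25) {
    cds <- backTranslate(randProtein(150), seed = k)
    len <- sample(87:374, 1)
    repeat {
      off <- sample(seq_len(nchar(cds) - 1L), 1)
      pg <- tryCatch(plantGene(cds, list(list(offset = off, length = len)),
                               seed = k, geneId = "g"),
                     error = function(e) NULL)
      if (!is.null(pg)) break
    }
    m <- inferGeneStructure(cds, pg$genomic, geneId = "g")
    expect_equal(exons(m), exons(pg$model), info = paste("seed", k))
    expect_equal(spliceSites(m), "GT..AG")
  }
  # two introns recovered at the planted coordinates
  cds <- backTranslate(randProtein(200), seed = 999)
  pg2 <- plantGene(cds, list(list(offset = 120, length = 95),
                             list(offset = 430, length = 210)), seed = 5)
  m2 <- inferGeneStructure(cds, pg2$genomic)
  expect_equal(exons(m2), exons(pg2$model))
  expect_equal(intronLengths(m2), c(95L, 210L))
})

test_that("exon chains always reconstruct the CDS byte-for-byte", {
  set.seed(71)
  for (k in 1:10) {
    cds <- backTranslate(randProtein(80), seed = k)
    pg <- plantGene(cds, list(list(offset = 100, length = 90)), seed = k)
    m <- inferGeneStructure(cds, pg$genomic)
    got <- paste(substring(pg$genomic, IRanges::start(exons(m)),
                           IRanges::end(exons(m))), collapse = "")
    expect_identical(got, cds)
  }
})

test_that("intron length annotation separates plausible from implausible", {
  pg <- plantGene(backTranslate(randProtein(100), 3),
                  list(list(offset = 150, length = 150)), seed = 3)
  chk <- intronLengthCheck(pg$model)
  expect_true(chk$plausible)
  expect_true(chk$inObservedBand)

  g <- paste0("ATGGCC", "GTAG", "GATTAA")  # 4-bp intron
  m <- inferGeneStructure("ATGGCCGATTAA", g)
  chk2 <- intronLengthCheck(m)
  expect_false(chk2$plausible)
  expect_false(chk2$inObservedBand)
})

test_that("the single-intron-in-HV criterion maps codons to columns", {
  # 30-codon CDS, intron after codon 10 (CDS offset 30), gap-free row
  prot <- randProtein(30)
  cds <- backTranslate(prot, seed = 11)
  pg <- plantGene(cds, list(list(offset = 30, length = 90)), seed = 11)
  hv <- hvWindows(8, 15, "HV2")
  r <- intronInHv(pg$model, prot, hv)
  expect_true(r$countOk)
  expect_equal(r$labels, "HV2")
  expect_equal(r$phase, 0L)
  # outside the window
  hvFar <- hvWindows(20, 25, "HV5")
  r2 <- intronInHv(pg$model, prot, hvFar)
  expect_false(r2$countOk)
  expect_equal(r2$labels, "outside")
  # two introns can never satisfy the criterion
  pg3 <- plantGene(cds, list(list(offset = 24, length = 90),
                             list(offset = 45, length = 100)), seed = 12)
  r3 <- intronInHv(pg3$model, prot, hv)
  expect_false(r3$countOk)
  expect_length(r3$labels, 2L)
  # gapped alignment row shifts the column correctly
  gapped <- paste0("---", substr(prot, 1, 10), "--", substr(prot, 11, 30))
  r4 <- intronInHv(pg$model, gapped, hvWindows(11, 18, "HV2"))
  expect_true(r4$countOk)
  expect_equal(r4$column, 13L)
})

test_that("planted class III structures pass the criterion family-wide", {
  fam <- genFamily(nPerClass = 2, seed = 73)
  L <- fam$params$proteinLength
  hv <- hvWindows(round(0.3 * L), round(0.45 * L), "HV")
  iii <- fam$truth$id[fam$truth$class == "III"]
  for (id in iii) {
    prot <- as.character(fam$proteins[[id]])
    cds <- backTranslate(prot, seed = match(id, names(fam$proteins)))
    codon <- sample(seq(round(0.3 * L), round(0.45 * L)), 1)
    pg <- plantGene(cds, list(list(offset = 3 * codon,
                                   length = sample(87:374, 1))),
                    seed = match(id, names(fam$proteins)))
    r <- intronInHv(pg$model, prot, hv)
    expect_true(r$countOk, info = id)
    expect_equal(r$labels, "HV")
  }
})
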