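test_that("NJ solves the three-taxon closed form", {
  dab <- 0.3; dac <- 0.5; dbc <- 0.6
  d <- matrix(c(0, dab, dac, dab, 0, dbc, dac, dbc, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  # terminal branch lengths from the three-point formulas
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], (dab + dac - dbc) / 2)
  expect_equal(bl[["b"]], (dab + dbc - dac) / 2)
  expect_equal(bl[["c"]], (dac + dbc - dab) / 2)
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(19)
  for (k in 1:5) {
    nt <- sample(5:8, 1)
    tr0 <- ape::rtree(nt, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.05, 0.5)
    d <- cophenetic(tr0)
    tr <- njTree(d[tr0$tip.label, tr0$tip.label])
    expect_equal(cophenetic(tr)[tr0$tip.label, tr0$tip.label], d,
                 tolerance = 1e-9)
  }
})

test_that("NJ flags degenerate input", {
  d <- matrix(c(0, .2, .4, .3, 0, .4, .4, .4, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(d), "symmetric")
  expect_error(njTree(matrix(0, 2, 2)), ">= 3 taxa")
  # duplicate taxon gives a zero-length cherry
  d4 <- matrix(c(0, 0, .5, 0, 0, .5, .5, .5, 0), 3,
               dimnames = list(c("a", "a2", "b"), c("a", "a2", "b")))
  tr <- njTree(d4)
  bl <- tr$edge.length[match(match(c("a", "a2"), tr$tip.label),
                             tr$edge[, 2])]
  expect_equal(bl, c(0, 0))
})

test_that("class assignment matches nearest labelled reference", {
  fam <- genFamily(nPerClass = 3, seed = 31)
  msa <- progressiveMsa(c(fam$references, fam$proteins))
  cl <- assignClass(msa, names(fam$proteins), names(fam$references),
                    fam$refClasses)
  # query identical to a reference gets that class at support 1
  msaPlus <- c(as.character(msa),
               qIII = as.character(msa)[["ref_III"]])
  cl2 <- assignClass(msaPlus, "qIII", names(fam$references),
                     fam$refClasses)
  expect_equal(cl2$class, "III")
  expect_equal(cl2$support, 1.0)
  # generator truth agreement on the planted three-class family
  truth <- setNames(fam$truth$class, fam$truth$id)
  expect_gte(mean(cl$class == truth[cl$id]), 0.95)
  # invariant to query order
  clRev <- assignClass(msa, rev(names(fam$proteins)),
                       names(fam$references), fam$refClasses)
  expect_equal(cl[match(clRev$id, cl$id), ], clRev)
})

test_that("queries below the identity floor are unclassified", {
  rows <- c(ref_I = strrep("A", 20), ref_II = strrep("C", 20),
            ref_III = strrep("D", 20), q = strrep("W", 20))
  cl <- assignClass(rows, "q", paste0("ref_", c("I", "II", "III")),
                    setNames(c("I", "II", "III"),
                             paste0("ref_", c("I", "II", "III"))),
                    floor = 0.30)
  expect_equal(cl$class, "unclassified")
})

test_that("LPSC detection flags planted low-polymorphic subclusters", {
  fam <- genFamily(nPerClass = 4, lpscSize = 4, lpscIdentity = 0.96,
                   seed = 41)
  msa <- progressiveMsa(fam$proteins)
  iii <- fam$truth$id[fam$truth$class == "III"]
  lp <- detectLpsc(msa, iii, identityFloor = 0.85, minSize = 3)
  truthLpsc <- setNames(fam$truth$lpsc, fam$truth$id)[iii]
  expect_equal(lp$flags, truthLpsc)

  # all-distinct sequences at ~0.60 identity are never flagged
  set.seed(43)
  base <- strsplit(randProtein(100), "")[[1]]
  div <- vapply(1:4, function(i) {
    aa <- base
    ix <- sample(100, 40)
    for (j in ix) aa[j] <- sample(setdiff(AA20h, aa[j]), 1)
    paste(aa, collapse = "")
  }, "")
  names(div) <- paste0("d", 1:4)
  lp2 <- detectLpsc(div, names(div), identityFloor = 0.85, minSize = 3)
  expect_false(any(lp2$flags))
})

test_that("groups at the observed subcluster identities are flagged", {
  # three groups built at pairwise identities ~0.894 / 0.914 / 0.967,
  # the band reported for low-polymorphic subclusters
  set.seed(47)
  mk <- function(founder, nDiff) {
    aa <- strsplit(founder, "")[[1]]
    ix <- sample(seq_along(aa), nDiff)
    for (j in ix) aa[j] <- sample(setdiff(AA20h, aa[j]), 1)
    paste(aa, collapse = "")
  }
  out <- c()
  for (g in seq_len(3)) {
    founder <- randProtein(230)
    nDiff <- round(230 * c(0.106, 0.086, 0.033)[g] / 2)
    grp <- setNames(vapply(1:3, function(i) mk(founder, nDiff), ""),
                    paste0("g", g, "_", 1:3))
    out <- c(out, grp)
  }
  lp <- detectLpsc(out, names(out), identityFloor = 0.85, minSize = 3)
  expect_true(all(lp$flags))
  expect_length(lp$groups, 3L)
})
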