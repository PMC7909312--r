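#' Run the full screening pipeline on a synthetic dataset
#'
#' End-to-end exercise of every stage with known ground truth: generate a
#' three-class family, align it with the labelled references, assign
#' classes and LPSC flags, compute protein features and CAS histidines,
#' infer gene structures from planted genomic sequences, call tissue
#' specificity, simulate the reciprocal GSI crosses and classify marker
#' roles, then designate S-RNase candidates.
#'
#' A gene is designated iff it is class III, outside any LPSC, basic
#' (pI above `basicPiCutoff`), carries both CAS histidines, has exactly
#' one intron inside the hypervariable window, is pistil-specific, and
#' its marker role is `shared_S` or `unique_S(...)`. On the default
#' scenario the planted S-RNases are `cIII_1` (shared S1), `cIII_2`
#' (maternal Sx) and `cIII_3` (paternal Sy).
#'
#' @param seed RNG seed driving every generator.
#' @param config a [runConfig()].
#' @param nForward,nReciprocal progeny counts of the simulated crosses.
#' @return list: `report` (per-gene [S4Vectors::DataFrame] with all
#'   criteria and the final verdict), `designated`, `expected`, `roles`,
#'   `de` (differential-expression table), `truth`, `seed`.
#' @examples
#' \donttest{
#' res <- runSyntheticPipeline(seed = 1)
#' res$designated
#' }
#' @export
runSyntheticPipeline <- function(seed = 1L, config = runConfig(seed = seed),
                                 nForward = 81L, nReciprocal = 95L) {
  seed <- as.integer(seed)
  fam <- genFamily(seed = seed)
  ids <- names(fam$proteins)
  L <- fam$params$proteinLength

  ## alignment, classes, LPSC
  msa <- progressiveMsa(c(fam$references, fam$proteins))
  rows <- .asRows(msa)
  cl <- assignClass(msa, ids, names(fam$references), fam$refClasses,
                    floor = config$classFloor)
  iii <- cl$id[cl$class == "III"]
  lp <- detectLpsc(msa, iii, config$lpscIdentityFloor, config$lpscMinSize)
  lpscFlag <- setNames(rep(FALSE, length(ids)), ids)
  lpscFlag[names(lp$flags)] <- lp$flags

  ## protein features and CAS histidines
  feats <- proteinFeatures(fam$proteins, pkaTable(config$pkaSet))
  refRow <- strsplit(rows[["ref_III"]], "")[[1]]
  refCols <- which(refRow != "-")
  casCols <- refCols[fam$casPositions]
  cas <- t(vapply(ids, function(id)
    detectCasHistidines(rows[[id]], casCols),
    c(cas1_his = TRUE, cas2_his = TRUE)))

  ## HV window: the stretch between the two CAS segments on the
  ## reference alignment (residues at 30-45% of the protein)
  hvRes <- c(round(0.30 * L), round(0.45 * L))
  hv <- hvWindows(refCols[hvRes[1]], refCols[hvRes[2]], "HV")

  ## planted gene structures: class III genes get one intron inside HV;
  ## class I two introns outside; class II none
  structures <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    cds <- backTranslate(fam$proteins[[id]], seed = seed + 100L + i)
    cls <- fam$truth$class[fam$truth$id == id]
    specs <- .withSeed(seed + 200L + i, {
      if (cls == "III") {
        codon <- sample(hvRes[1]:hvRes[2], 1L)
        list(list(offset = 3L * codon, length = sample(87:374, 1L)))
      } else if (cls == "I") {
        list(list(offset = 3L * 20L, length = sample(87:374, 1L)),
             list(offset = 3L * (L - 30L), length = sample(87:374, 1L)))
      } else list()
    })
    pg <- plantGene(cds, specs, seed = seed + 300L + i, geneId = id)
    model <- inferGeneStructure(cds, pg$genomic, geneId = id)
    hvCall <- intronInHv(model, rows[[id]], hv)
    list(model = model, hvCall = hvCall)
  })
  names(structures) <- ids
  intronOk <- vapply(structures, function(s) s$hvCall$countOk, TRUE)

  ## tissue panel from truth labels
  tissueTruth <- setNames(rep("pistil_plus_other", length(ids)), ids)
  tissueTruth[fam$truth$id[fam$truth$class == "III" & !fam$truth$lpsc]] <-
    "pistil_specific"
  tissueTruth[c("lpsc_2", "lpsc_3")] <- "pistil_specific"
  tissueTruth["lpsc_1"] <- "pistil_plus_other"
  tissueTruth[fam$truth$id[fam$truth$class %in% c("I", "II")]] <-
    rep(c("ubiquitous", "pistil_plus_other"),
        length.out = sum(fam$truth$class %in% c("I", "II")))
  panel <- genTissuePanel(tissueTruth, seed = seed + 7L)$panel
  tissue <- vapply(ids, function(id)
    tissueSpecificity(panel[id, ],
                      detectThreshold = config$detectThreshold), "")

  ## reciprocal crosses; markers named by the genes they track
  scen <- defaultScenario()
  geneOfMarker <- c(mS1 = "cIII_1", mSx = "cIII_2", mSy = "cIII_3",
                    mUnl = "cIII_4", mHom = "lpsc_1")
  for (k in seq_along(scen$markers))
    scen$markers[[k]]@markerId <-
      unname(geneOfMarker[scen$markers[[k]]@markerId])
  names(scen$truthRoles) <- unname(geneOfMarker[names(scen$truthRoles)])
  cross <- genCrossDataset(scen, nForward, nReciprocal, seed = seed + 11L)
  roleTab <- classifyMarkers(cross$fwd, cross$rev, cross$markers,
                             alpha = config$alpha)
  role <- setNames(rep(NA_character_, length(ids)), ids)
  role[roleTab$marker] <- roleTab$role

  ## expression contrast (SI style vs SC mutant style); the maternal
  ## unique S-RNase is the planted down-regulated gene
  cnt <- genCounts(nGenes = 60L, planted = list(list(gene = 1L, fold = 0.125)),
                   geneNames = c("cIII_2", paste0("bg", seq_len(59L))),
                   seed = seed + 13L)
  de <- simpleDeTest(cnt$counts, cnt$groups, seed = seed + 17L,
                     fdrLevel = config$fdrLevel)

  sRole <- !is.na(role) & grepl("^(shared_S|unique_S)", role)
  report <- S4Vectors::DataFrame(
    id = ids,
    class = cl$class[match(ids, cl$id)],
    support = cl$support[match(ids, cl$id)],
    lpsc = unname(lpscFlag[ids]),
    pI = feats$pI[match(ids, feats$id)],
    mw = feats$mw[match(ids, feats$id)],
    cas1 = unname(cas[ids, "cas1_his"]),
    cas2 = unname(cas[ids, "cas2_his"]),
    nIntrons = vapply(structures[ids], function(s)
      length(intronLengths(s$model)), 0L),
    intronInHv = unname(intronOk[ids]),
    tissue = unname(tissue[ids]),
    role = unname(role[ids]))
  report$candidate <- report$class == "III" & !report$lpsc &
    report$pI > config$basicPiCutoff & report$cas1 & report$cas2 &
    report$intronInHv & report$tissue == "pistil_specific" & sRole[ids]

  list(report = report,
       designated = report$id[report$candidate],
       expected = c("cIII_1", "cIII_2", "cIII_3"),
       roles = roleTab, de = de, structures = structures,
       truth = fam$truth, seed = seed)
}
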