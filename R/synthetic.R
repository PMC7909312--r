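#' Generate a synthetic three-class T2-RNase-like protein family
#'
#' Emulates the structure of a T2 ribonuclease family: one shared root,
#' three class ancestors (classes I-III), class members diverged from
#' their ancestor by per-site substitution, a basic-residue compositional
#' bias in class III (so mean pI orders III > II, I as in real
#' families), two preserved CAS histidine positions, and an optional
#' low-polymorphic subcluster (LPSC) regenerated at high identity inside
#' class III.
#'
#' Divergence parameters are per-branch per-site substitution
#' probabilities (substitution always changes the residue), so expected
#' pairwise p-distance between two members of one class is approximately
#' `2 d (1 - d)`; no indels are introduced, keeping p-distances
#' analytically predictable.
#'
#' @param nPerClass members per class (the LPSC adds `lpscSize` extra
#'   class III members).
#' @param withinClassDiv per-branch substitution rate ancestor ->
#'   member; default 0.15 (expected within-class p-distance ~0.26).
#' @param betweenClassDiv per-branch rate root -> class ancestor;
#'   default 0.5. Must exceed `withinClassDiv` and be <= 0.8.
#' @param classIIIBasicBias fraction of class III ancestor substitutions
#'   forced to K/R/H; classes I and II are biased toward D/E instead.
#' @param lpscSize,lpscIdentity size and target mean pairwise identity of
#'   the planted LPSC (0 disables it).
#' @param casKnockouts named integer vector: member id -> which CAS
#'   histidine (1 or 2) to knock out.
#' @param proteinLength residues; default 230 (~25 kDa).
#' @param seed RNG seed; the output is a deterministic function of the
#'   arguments and the seed.
#' @return list: `proteins` ([Biostrings::AAStringSet] of members),
#'   `references` (the class ancestors, labelled), `refClasses`,
#'   `casPositions` (ungapped residue positions of CAS I/II histidines),
#'   `truth` ([S4Vectors::DataFrame]: id, class, lpsc, cas1Intact,
#'   cas2Intact), `params`, `seed`.
#' @examples
#' fam <- genFamily(nPerClass = 2, seed = 1)
#' fam$truth
#' @export
genFamily <- function(nPerClass = 4L, withinClassDiv = 0.15,
                      betweenClassDiv = 0.5, classIIIBasicBias = 0.6,
                      lpscSize = 3L, lpscIdentity = 0.95,
                      casKnockouts = integer(), proteinLength = 230L,
                      seed = 1L) {
  if (withinClassDiv < 0 || withinClassDiv >= betweenClassDiv ||
      betweenClassDiv > 0.8)
    .stopf("need 0 <= withinClassDiv < betweenClassDiv <= 0.8")
  cas <- c(round(proteinLength * 0.2), round(proteinLength * 0.5))
  .withSeed(seed, {
    mut <- function(aa, rate, pool = AA20) {
      idx <- setdiff(which(runif(length(aa)) < rate), cas)
      for (i in idx) aa[i] <- sample(setdiff(pool, aa[i]), 1L)
      aa
    }
    root <- sample(AA20, proteinLength, replace = TRUE)
    root[cas] <- "H"
    biasPool <- function(bias, residues) {
      # substitution targets: 'bias' fraction drawn from the biased set
      function(aa, rate) {
        idx <- setdiff(which(runif(length(aa)) < rate), cas)
        for (i in idx) {
          pool <- if (runif(1) < bias) residues else AA20
          aa[i] <- sample(setdiff(pool, aa[i]), 1L)
        }
        aa
      }
    }
    anc <- list(
      I = biasPool(0.4, c("D", "E"))(root, betweenClassDiv),
      II = biasPool(0.25, c("D", "E"))(root, betweenClassDiv),
      III = biasPool(classIIIBasicBias, c("K", "R", "H"))(root,
                                                          betweenClassDiv))
    ids <- character(); cls <- character(); lps <- logical()
    sqs <- character()
    for (cl in names(anc)) {
      for (k in seq_len(nPerClass)) {
        ids <- c(ids, sprintf("c%s_%d", cl, k))
        cls <- c(cls, cl); lps <- c(lps, FALSE)
        sqs <- c(sqs, paste(mut(anc[[cl]], withinClassDiv), collapse = ""))
      }
    }
    if (lpscSize > 0L) {
      founder <- mut(anc$III, withinClassDiv)
      rLp <- (1 - lpscIdentity) / 2
      for (k in seq_len(lpscSize)) {
        ids <- c(ids, sprintf("lpsc_%d", k))
        cls <- c(cls, "III"); lps <- c(lps, TRUE)
        sqs <- c(sqs, paste(mut(founder, rLp), collapse = ""))
      }
    }
    cas1 <- rep(TRUE, length(ids)); cas2 <- rep(TRUE, length(ids))
    for (id in names(casKnockouts)) {
      i <- match(id, ids)
      if (is.na(i)) .stopf("unknown knockout id '%s'", id)
      w <- casKnockouts[[id]]
      aa <- strsplit(sqs[i], "")[[1]]
      aa[cas[w]] <- sample(setdiff(AA20, "H"), 1L)
      sqs[i] <- paste(aa, collapse = "")
      if (w == 1L) cas1[i] <- FALSE else cas2[i] <- FALSE
    }
    list(
      proteins = Biostrings::AAStringSet(setNames(sqs, ids)),
      references = Biostrings::AAStringSet(
        setNames(vapply(anc, paste, "", collapse = ""),
                 paste0("ref_", names(anc)))),
      refClasses = setNames(names(anc), paste0("ref_", names(anc))),
      casPositions = cas,
      truth = S4Vectors::DataFrame(id = ids, class = cls, lpsc = lps,
                                   cas1Intact = cas1, cas2Intact = cas2),
      params = list(nPerClass = nPerClass,
                    withinClassDiv = withinClassDiv,
                    betweenClassDiv = betweenClassDiv,
                    classIIIBasicBias = classIIIBasicBias,
                    lpscSize = lpscSize, lpscIdentity = lpscIdentity,
                    proteinLength = proteinLength),
      seed = as.integer(seed))
  })
}

#' Back-translate a protein to a CDS
#'
#' Random synonymous codon choice under the standard code (no stop codon
#' appended); used by the generators to derive nucleotide inputs from
#' protein-level truth.
#'
#' @param protein amino-acid sequence.
#' @param seed RNG seed.
#' @return CDS string of length `3 * nchar(protein)`.
#' @export
backTranslate <- function(protein, seed = 1L) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  .withSeed(seed, {
    paste(vapply(aa, function(a) {
      cods <- names(gc)[gc == a]
      if (!length(cods)) .stopf("no codon for residue '%s'", a)
      sample(cods, 1L)
    }, ""), collapse = "")
  })
}

#' Plant introns into a CDS to build a genomic sequence
#'
#' Builds `flank + exon1 + intron1 + ... + flank` with introns carrying
#' the requested splice dinucleotides. Intron interiors and flanks are
#' random over A/C/T only (no G): without G no spurious `GT` donor or
#' `AG` acceptor can form outside the planted junctions, which makes the
#' planted chain the unique optimal spliced mapping and
#' [inferGeneStructure()] an exact inverse of this generator.
#'
#' @param cds coding sequence.
#' @param intronSpecs list of `list(offset, length, splice = "GT..AG")`;
#'   the intron is inserted after CDS position `offset`
#'   (`1 <= offset < nchar(cds)`, strictly inside the CDS), lengths >= 4.
#'   Offsets where the requested splice dinucleotides would spell the
#'   adjacent CDS bases (so the genomic would admit a fewer-intron
#'   reading and the truth model would not describe the sequence) are
#'   rejected with an "unrecoverable plant" error.
#' @param flankLengths integer(2) flanking lengths.
#' @param seed RNG seed.
#' @param geneId id recorded in the truth model.
#' @return list: `genomic` (string), `model` (the true
#'   [GeneModel-class]).
#' @examples
#' pg <- plantGene(strrep("ATG", 50), list(list(offset = 75, length = 90)))
#' intronLengths(pg$model)
#' @export
plantGene <- function(cds, intronSpecs = list(), flankLengths = c(100L, 100L),
                      seed = 1L, geneId = "gene") {
  cds <- toupper(as.character(cds))
  L <- nchar(cds)
  offs <- vapply(intronSpecs, function(s) as.integer(s$offset), 0L)
  if (any(offs < 1L) || any(offs >= L))
    .stopf("intron offsets must be strictly inside the CDS (UTR-adjacent positions are not introns)")
  if (anyDuplicated(offs)) .stopf("overlapping intron offsets")
  o <- order(offs)
  intronSpecs <- intronSpecs[o]; offs <- offs[o]
  cdsCh <- strsplit(cds, "")[[1]]
  .withSeed(seed, {
    rnd <- function(n, alph = c("A", "C", "G", "T"))
      paste(sample(alph, n, replace = TRUE), collapse = "")
    introns <- vapply(seq_along(intronSpecs), function(k) {
      s <- intronSpecs[[k]]
      len <- as.integer(s$length)
      if (len < 4L) .stopf("intron length must be >= 4")
      sp <- if (is.null(s$splice)) "GT..AG" else s$splice
      dn <- strsplit(sub("\\.\\..*$", "", sp), "")[[1]]
      ac <- strsplit(sub("^.*\\.\\.", "", sp), "")[[1]]
      lead <- offs[k]; rem <- L - offs[k]
      interior <- sample(c("A", "C", "T"), max(0L, len - 4L),
                         replace = TRUE)
      # keep the intron from reading through into the adjacent CDS: an
      # interior base is forced to mismatch the CDS continuation on each
      # side, so the planted chain stays the unique parsimony optimum
      if (len >= 5L) {
        if (rem >= 3L && interior[1L] == cdsCh[offs[k] + 3L])
          interior[1L] <- sample(setdiff(c("A", "C", "T"),
                                         cdsCh[offs[k] + 3L]), 1L)
        if (lead >= 3L && interior[len - 4L] == cdsCh[lead - 2L])
          interior[len - 4L] <- sample(setdiff(c("A", "C", "T"),
                                               cdsCh[lead - 2L]), 1L)
      }
      intr <- c(dn, interior, ac)
      # inherent ambiguity: if the splice dinucleotides themselves spell
      # the CDS continuation, the genomic admits a fewer-intron reading
      # and the returned truth would not describe it
      pr <- seq_len(min(len, rem))
      if (all(intr[pr] == cdsCh[offs[k] + pr]))
        .stopf("unrecoverable plant: intron at offset %d reads through into the downstream CDS",
               offs[k])
      jl <- seq(max(1L, lead - len + 1L), lead)
      if (all(intr[len - lead + jl] == cdsCh[jl]))
        .stopf("unrecoverable plant: intron at offset %d reads through into the upstream CDS",
               offs[k])
      paste(intr, collapse = "")
    }, "")
    fl1 <- rnd(flankLengths[1], c("A", "C", "T"))
    fl2 <- rnd(flankLengths[2], c("A", "C", "T"))
    bounds <- c(0L, offs, L)
    pieces <- substring(cds, utils::head(bounds, -1L) + 1L,
                        bounds[-1L])
    genomic <- fl1
    starts <- integer(); ends <- integer()
    for (k in seq_along(pieces)) {
      starts <- c(starts, nchar(genomic) + 1L)
      genomic <- paste0(genomic, pieces[k])
      ends <- c(ends, nchar(genomic))
      if (k <= length(introns)) genomic <- paste0(genomic, introns[k])
    }
    genomic <- paste0(genomic, fl2)
    ss <- vapply(introns, function(x)
      paste0(substr(x, 1, 2), "..", substr(x, nchar(x) - 1L, nchar(x))), "")
    model <- GeneModel(geneId, IRanges::IRanges(starts, ends),
                       unname(ss), cds, nchar(genomic), genomic = genomic)
    list(genomic = genomic, model = model)
  })
}

#' Default semi-compatible cross scenario
#'
#' The reciprocal-cross study design: mother `S1 Sx` x father `S1 Sy`
#' (sharing `S1`, hence semi-compatible) with five markers - one per S
#' allele (S-linked, r = 0), one unlinked marker hemizygous in both
#' parents, and one unlinked marker homozygous in the mother. The truth
#' roles are the five roles the classifier should recover.
#'
#' @param r recombination fraction for the S-linked markers.
#' @return list with `mother`, `father`, `markers`, `truthRoles`.
#' @export
defaultScenario <- function(r = 0) {
  list(
    mother = SGenotype("S1", "Sx"),
    father = SGenotype("S1", "Sy"),
    markers = list(
      markerSpec("mS1", "s_linked", allele = "S1", r = r),
      markerSpec("mSx", "s_linked", allele = "Sx", r = r),
      markerSpec("mSy", "s_linked", allele = "Sy", r = r),
      markerSpec("mUnl", "unlinked", motherGeno = "hemizygous",
                 fatherGeno = "hemizygous"),
      markerSpec("mHom", "unlinked", motherGeno = "homozygous",
                 fatherGeno = "absent")),
    truthRoles = c(mS1 = "shared_S", mSx = "unique_S(mother)",
                   mSy = "unique_S(father)", mUnl = "unlinked_het_both",
                   mHom = "homozygous_non_S"))
}

# swap the parent-specific fields of unlinked specs for the reciprocal cross
.swapParents <- function(mk) {
  if (mk@linkage == "unlinked") {
    tmp <- mk@motherGeno; mk@motherGeno <- mk@fatherGeno
    mk@fatherGeno <- tmp
  }
  mk
}

#' Generate a reciprocal GSI cross dataset with markers
#'
#' Simulates both cross directions of a scenario via [gsiCross()] and
#' [attachMarkers()], optionally adding symmetric genotyping noise.
#'
#' @param scenario a [defaultScenario()]-shaped list.
#' @param nForward,nReciprocal progeny counts (defaults 81 and 95, the
#'   reciprocal population sizes of the emulated design).
#' @param miscallRate probability of flipping any marker call, in
#'   `[0, 0.05]`.
#' @param seed RNG seed (sub-seeds are derived for each stage).
#' @return list: `fwd`, `rev` ([GsiProgeny-class]), `markers`,
#'   `truthRoles`.
#' @export
genCrossDataset <- function(scenario = defaultScenario(), nForward = 81L,
                            nReciprocal = 95L, miscallRate = 0,
                            seed = 1L) {
  if (miscallRate < 0 || miscallRate > 0.05)
    .stopf("miscallRate must be in [0, 0.05]")
  seed <- as.integer(seed)
  fwd <- gsiCross(scenario$mother, scenario$father, nForward,
                  seed = seed, motherName = "mother",
                  fatherName = "father")
  fwd <- attachMarkers(fwd, scenario$markers, seed = seed + 1L)
  revMarkers <- lapply(scenario$markers, .swapParents)
  rev <- gsiCross(scenario$father, scenario$mother, nReciprocal,
                  seed = seed + 2L, motherName = "father",
                  fatherName = "mother")
  rev <- attachMarkers(rev, revMarkers, seed = seed + 3L)
  if (miscallRate > 0) {
    flip <- function(tab, s) {
      .withSeed(s, {
        for (mk in markerNames(tab)) {
          f <- runif(nrow(tab@progeny)) < miscallRate
          tab@progeny[[mk]] <- tab@progeny[[mk]] != f
        }
      })
      tab
    }
    fwd <- flip(fwd, seed + 4L)
    rev <- flip(rev, seed + 5L)
  }
  list(fwd = fwd, rev = rev, markers = scenario$markers,
       truthRoles = scenario$truthRoles)
}

#' Generate a negative-binomial count matrix with planted fold changes
#'
#' Gene-wise negative-binomial counts with log-normal baseline means and
#' library sizes; planted genes are scaled by their fold in group 2,
#' emulating an S-RNase down-regulated in a self-compatible mutant.
#'
#' @param nGenes genes.
#' @param nPerGroup samples per group (two groups).
#' @param dispersion NB dispersion (`size = 1/dispersion`); default 0.1.
#' @param planted list of `list(gene, fold)` (gene index or name).
#' @param libSdLog log-sd of library size factors.
#' @param baseMeanLog,baseSdLog log-normal baseline mean parameters.
#' @param geneNames optional gene names (length `nGenes`).
#' @param seed RNG seed.
#' @return list: `counts` (genes x samples), `groups` (factor), `truth`.
#' @export
genCounts <- function(nGenes = 200L, nPerGroup = 3L, dispersion = 0.1,
                      planted = list(), libSdLog = 0.15,
                      baseMeanLog = log(100), baseSdLog = 1,
                      geneNames = NULL, seed = 1L) {
  if (dispersion <= 0) .stopf("dispersion must be > 0")
  nS <- 2L * nPerGroup
  groups <- factor(rep(c("g1", "g2"), each = nPerGroup))
  .withSeed(seed, {
    mu0 <- rlnorm(nGenes, baseMeanLog, baseSdLog)
    sf <- rlnorm(nS, 0, libSdLog)
    fold <- matrix(1, nGenes, nS)
    genes <- if (is.null(geneNames)) paste0("gene", seq_len(nGenes))
             else geneNames
    for (p in planted) {
      gi <- if (is.character(p$gene)) match(p$gene, genes) else p$gene
      if (p$fold <= 0) .stopf("planted fold must be > 0")
      fold[gi, groups == "g2"] <- p$fold
    }
    counts <- matrix(rnbinom(nGenes * nS,
                             mu = as.vector(outer(mu0, sf) * fold),
                             size = 1 / dispersion),
                     nGenes, nS,
                     dimnames = list(genes, paste0("s", seq_len(nS))))
    list(counts = counts, groups = groups,
         truth = list(planted = planted, dispersion = dispersion,
                      seed = as.integer(seed)))
  })
}

#' Generate a tissue detection panel consistent with truth labels
#'
#' Boolean gene x tissue detection matrix whose rows classify back to
#' their truth labels under [tissueSpecificity()] for any seed
#' (`pistil_specific`: non-empty subset of pistil tissues;
#' `pistil_plus_other`: >= 1 pistil and >= 1 other tissue - always
#' including anther/pollen - but never all tissues; `ubiquitous`: all
#' tissues; `not_detected`: none).
#'
#' @param truthLabels named character vector gene -> label.
#' @param tissues panel tissues (default full vocabulary).
#' @param seed RNG seed.
#' @return list: `panel` (logical matrix genes x tissues), `truth`.
#' @export
genTissuePanel <- function(truthLabels, tissues = tissueVocabulary(),
                           seed = 1L) {
  pist <- intersect(tissues, c("stigma", "style", "ovary"))
  other <- setdiff(tissues, pist)
  bad <- setdiff(truthLabels, c("pistil_specific", "pistil_plus_other",
                                "ubiquitous", "not_detected"))
  if (length(bad)) .stopf("unknown truth label(s): %s",
                          paste(unique(bad), collapse = ", "))
  .withSeed(seed, {
    panel <- matrix(FALSE, length(truthLabels), length(tissues),
                    dimnames = list(names(truthLabels), tissues))
    for (g in names(truthLabels)) {
      lab <- truthLabels[[g]]
      if (lab == "pistil_specific") {
        panel[g, sample(pist, sample(length(pist), 1L))] <- TRUE
      } else if (lab == "pistil_plus_other") {
        panel[g, sample(pist, sample(length(pist), 1L))] <- TRUE
        panel[g, "anther_pollen"] <- TRUE
        extra <- setdiff(other, "anther_pollen")
        keepOut <- sample(extra, 1L)  # at least one tissue stays negative
        more <- setdiff(extra, keepOut)
        panel[g, more] <- runif(length(more)) < 0.3
      } else if (lab == "ubiquitous") {
        panel[g, ] <- TRUE
      }
    }
    list(panel = panel, truth = truthLabels)
  })
}
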