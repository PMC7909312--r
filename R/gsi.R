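#' Simulate a gametophytic self-incompatibility cross
#'
#' Each progeny receives one maternal allele (uniform) and one paternal
#' allele drawn uniformly from the father's alleles that are compatible
#' with the mother's pistil: a pollen allele matching either maternal
#' allele is rejected, except the dominant self-fertility allele, which
#' is always compatible. A cross with no compatible pollen allele is an
#' error ("fully incompatible cross"). In a semi-compatible cross
#' (parents sharing one allele) only two progeny genotypes are possible,
#' at a 1:1 ratio.
#'
#' @param mother,father [SGenotype-class] of the seed and pollen parent.
#' @param n number of progeny.
#' @param seed RNG seed recorded in the table metadata.
#' @param motherName,fatherName labels for the cross direction.
#' @return A [GsiProgeny-class].
#' @examples
#' gsiCross(SGenotype("S1", "Sx"), SGenotype("S1", "Sy"), n = 10, seed = 1)
#' @export
gsiCross <- function(mother, father, n, seed = 1L,
                     motherName = "mother", fatherName = "father") {
  stopifnot(is(mother, "SGenotype"), is(father, "SGenotype"), n >= 1)
  compat <- father@alleles[father@alleles == father@sfAllele |
                           !(father@alleles %in% mother@alleles)]
  if (length(compat) == 0L) .stopf("fully incompatible cross")
  df <- .withSeed(seed, {
    data.frame(
      maternal = sample(mother@alleles, n, replace = TRUE),
      paternal = sample(compat, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  new("GsiProgeny", progeny = df, mother = mother, father = father,
      direction = sprintf("%s x %s", motherName, fatherName),
      seed = as.integer(seed))
}

#' Attach presence/absence markers to simulated progeny
#'
#' S-linked markers ride on the haplotype of their named allele in each
#' parent carrying it, and co-segregate with that allele except for
#' recombination at fraction `r` (a flip of the marker to the other
#' gamete). Unlinked markers are transmitted Mendelianly from each
#' parent's presence genotype (`homozygous`: every gamete;
#' `hemizygous`: half; `absent`: never); a progeny is marker-positive if
#' it received the marker from either parent.
#'
#' @param progeny a [GsiProgeny-class] from [gsiCross()].
#' @param markers list of [markerSpec()] objects.
#' @param seed RNG seed for marker transmission.
#' @return The [GsiProgeny-class] with one logical column per marker.
#' @export
attachMarkers <- function(progeny, markers, seed = 1L) {
  stopifnot(is(progeny, "GsiProgeny"))
  df <- progeny@progeny
  n <- nrow(df)
  mo <- progeny@mother; fa <- progeny@father
  .withSeed(seed, {
    for (mk in markers) {
      validObject(mk)
      if (mk@linkage == "s_linked") {
        A <- mk@allele
        moHas <- A %in% mo@alleles
        faHas <- A %in% fa@alleles
        if (!moHas && !faHas)
          .stopf("marker '%s' linked to allele '%s' absent from both parents",
                 mk@markerId, A)
        fromMo <- if (moHas) {
          flip <- runif(n) < mk@r
          (df$maternal == A) != flip
        } else rep(FALSE, n)
        fromFa <- if (faHas) {
          flip <- runif(n) < mk@r
          (df$paternal == A) != flip
        } else rep(FALSE, n)
        df[[mk@markerId]] <- fromMo | fromFa
      } else {
        trans <- function(geno) switch(geno,
          homozygous = rep(TRUE, n),
          hemizygous = runif(n) < 0.5,
          absent = rep(FALSE, n))
        df[[mk@markerId]] <- trans(mk@motherGeno) | trans(mk@fatherGeno)
      }
    }
  })
  progeny@progeny <- df
  validObject(progeny)
  progeny
}

#' Chi-square goodness-of-fit test for marker segregation
#'
#' Pearson chi-square (df = 1) of observed present/absent counts against
#' an expected 1:1 or 3:1 ratio, upper-tail P. No continuity correction
#' by default: the uncorrected statistic is the one that reproduces the
#' published segregation P values; Yates correction is available behind
#' `correct`.
#'
#' @param present,absent observed counts (non-negative,
#'   `present + absent >= 1`).
#' @param ratio `"1:1"` or `"3:1"` (present:absent).
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @examples
#' segregationTest(58, 23, "1:1")$p   # 0.0001007
#' @export
segregationTest <- function(present, absent, ratio = c("1:1", "3:1"),
                            correct = FALSE) {
  ratio <- match.arg(ratio)
  if (present < 0 || absent < 0) .stopf("negative counts")
  n <- present + absent
  if (n < 1) .stopf("present + absent must be >= 1")
  w <- if (ratio == "1:1") c(0.5, 0.5) else c(0.75, 0.25)
  obs <- c(present, absent)
  expd <- n * w
  dev <- abs(obs - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expd)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Segregation summary for every marker of a progeny table
#'
#' @param progeny a [GsiProgeny-class] with marker columns.
#' @param alpha decision level used for the `fitted` label.
#' @return [S4Vectors::DataFrame]: `marker`, `present`, `absent`,
#'   `chi2_1to1`, `p_1to1`, `chi2_3to1`, `p_3to1`, `allPresent`,
#'   `fitted` (`"1:0"`, `"1:1"`, `"3:1"`, `"1:1|3:1"` or `"none"`).
#' @export
segregationTable <- function(progeny, alpha = 0.05) {
  mks <- markerNames(progeny)
  df <- progeny@progeny
  rows <- lapply(mks, function(mk) {
    pr <- sum(df[[mk]]); ab <- sum(!df[[mk]])
    t1 <- segregationTest(pr, ab, "1:1")
    t3 <- segregationTest(pr, ab, "3:1")
    fit <- if (ab == 0L) "1:0"
      else if (t1$p >= alpha && t3$p >= alpha) "1:1|3:1"
      else if (t1$p >= alpha) "1:1"
      else if (t3$p >= alpha) "3:1"
      else "none"
    S4Vectors::DataFrame(marker = mk, present = pr, absent = ab,
                         chi2_1to1 = t1$chi2, p_1to1 = t1$p,
                         chi2_3to1 = t3$chi2, p_3to1 = t3$p,
                         allPresent = ab == 0L, fitted = fit)
  })
  do.call(rbind, rows)
}

#' Test whether two markers behave as alleles of one locus
#'
#' TRUE iff marker presence is complementary and exhaustive across the
#' progeny: every individual carries exactly one of the two markers
#' (up to `tolerance` miscalls). Complementary segregation in a
#' semi-compatible cross is the signature of two markers riding on the
#' two alternative S haplotypes.
#'
#' @param progeny a [GsiProgeny-class].
#' @param markerA,markerB marker column names.
#' @param tolerance maximum number of violating progeny (default 0).
#' @return logical.
#' @export
sameLocusTest <- function(progeny, markerA, markerB, tolerance = 0L) {
  df <- progeny@progeny
  a <- df[[markerA]]; b <- df[[markerB]]
  if (is.null(a) || is.null(b))
    .stopf("marker(s) not scored on this progeny table")
  if (markerA == markerB) return(FALSE)
  sum((a + b) != 1L) <= tolerance
}

#' Classify one marker's S-haplotype role from reciprocal crosses
#'
#' Implements the decision rules that map a pair of reciprocal
#' segregation records to a role:
#' \itemize{
#'   \item all-present in both crosses: `homozygous_non_S` (an S
#'     haplotype cannot be homozygous);
#'   \item all-present only when the carrying parent is the pollen donor,
#'     1:1 in the other cross, unique to that parent:
#'     `unique_S(<parent>)` (pollen selection forces the unique
#'     compatible allele into every progeny);
#'   \item 1:1 in both, carried by both parents, allelic
#'     ([sameLocusTest()]) with a `unique_S` marker: `shared_S`;
#'   \item fits 3:1 in both: `unlinked_het_both`;
#'   \item 1:1 in both but carried by one parent: `unlinked_het_one`;
#'   \item otherwise `inconclusive`.
#' }
#'
#' @param markerId marker name.
#' @param motherHas,fatherHas does each parent carry the marker.
#' @param segForward,segReciprocal one-row records for this marker from
#'   [segregationTable()] of the forward (mother as seed parent) and
#'   reciprocal cross.
#' @param allelicToUnique ids of `unique_S` markers this marker is
#'   allelic to (empty if none).
#' @param alpha decision level for "fits ratio".
#' @param motherName,fatherName labels used in the `unique_S(...)` role.
#' @return role string.
#' @export
classifyMarker <- function(markerId, motherHas, fatherHas, segForward,
                           segReciprocal, allelicToUnique = character(),
                           alpha = 0.05, motherName = "mother",
                           fatherName = "father") {
  for (sg in list(segForward, segReciprocal))
    if (isTRUE(sg$allPresent) && sg$absent > 0)
      .stopf("contradictory segregation record for '%s'", markerId)
  fwdAll <- isTRUE(segForward$allPresent)
  revAll <- isTRUE(segReciprocal$allPresent)
  fwd11 <- segForward$p_1to1 >= alpha
  rev11 <- segReciprocal$p_1to1 >= alpha
  fwd31 <- segForward$p_3to1 >= alpha
  rev31 <- segReciprocal$p_3to1 >= alpha
  if (fwdAll && revAll) return("homozygous_non_S")
  if (fatherHas && !motherHas && fwdAll && !revAll && rev11)
    return(sprintf("unique_S(%s)", fatherName))
  if (motherHas && !fatherHas && revAll && !fwdAll && fwd11)
    return(sprintf("unique_S(%s)", motherName))
  if (motherHas && fatherHas && fwd11 && rev11 &&
      length(allelicToUnique) > 0L)
    return("shared_S")
  if (fwd31 && rev31 && !fwdAll && !revAll) return("unlinked_het_both")
  if (xor(motherHas, fatherHas) && fwd11 && rev11)
    return("unlinked_het_one")
  "inconclusive"
}

#' Classify every marker of a reciprocal cross pair
#'
#' Computes segregation tables for both cross directions, finds allelic
#' (same-locus) marker pairs, classifies `unique_S` markers first, then
#' resolves `shared_S` via allelic partnership.
#'
#' @param fwd,rev [GsiProgeny-class] tables of the forward and reciprocal
#'   cross (same markers scored on both).
#' @param markers list of [markerSpec()] used to derive parental carriage
#'   (s_linked: allele in parent's genotype; unlinked: presence genotype
#'   not `"absent"`).
#' @param alpha decision level.
#' @return [S4Vectors::DataFrame] with per-marker counts, P values,
#'   carriage, allelic partners and the assigned `role`; the
#'   `sAllele` column names the S allele a `unique_S`/`shared_S` marker
#'   tracks (from its spec), `NA` otherwise.
#' @export
classifyMarkers <- function(fwd, rev, markers, alpha = 0.05) {
  segF <- segregationTable(fwd, alpha)
  segR <- segregationTable(rev, alpha)
  mo <- fwd@mother; fa <- fwd@father
  ids <- vapply(markers, function(m) m@markerId, "")
  moHas <- vapply(markers, function(m)
    if (m@linkage == "s_linked") m@allele %in% mo@alleles
    else m@motherGeno != "absent", TRUE)
  faHas <- vapply(markers, function(m)
    if (m@linkage == "s_linked") m@allele %in% fa@alleles
    else m@fatherGeno != "absent", TRUE)
  allelic <- setNames(vector("list", length(ids)), ids)
  if (length(ids) > 1L) {
    prs <- combn(length(ids), 2L)
    for (k in seq_len(ncol(prs))) {
      a <- ids[prs[1L, k]]; b <- ids[prs[2L, k]]
      if (sameLocusTest(fwd, a, b) || sameLocusTest(rev, a, b)) {
        allelic[[a]] <- c(allelic[[a]], b)
        allelic[[b]] <- c(allelic[[b]], a)
      }
    }
  }
  segRow <- function(tab, mk) tab[tab$marker == mk, , drop = FALSE]
  pass1 <- setNames(vapply(seq_along(ids), function(i)
    classifyMarker(ids[i], moHas[i], faHas[i], segRow(segF, ids[i]),
                   segRow(segR, ids[i]), character(), alpha), ""), ids)
  uniqueIds <- ids[grepl("^unique_S", pass1)]
  roles <- vapply(seq_along(ids), function(i) {
    partners <- intersect(allelic[[ids[i]]], uniqueIds)
    classifyMarker(ids[i], moHas[i], faHas[i], segRow(segF, ids[i]),
                   segRow(segR, ids[i]), partners, alpha)
  }, "")
  sAllele <- vapply(seq_along(ids), function(i) {
    if (grepl("^(unique_S|shared_S)", roles[i]) &&
        markers[[i]]@linkage == "s_linked")
      markers[[i]]@allele else NA_character_
  }, "")
  S4Vectors::DataFrame(
    marker = ids, motherHas = moHas, fatherHas = faHas,
    presentFwd = segF$present[match(ids, segF$marker)],
    absentFwd = segF$absent[match(ids, segF$marker)],
    p11Fwd = segF$p_1to1[match(ids, segF$marker)],
    p31Fwd = segF$p_3to1[match(ids, segF$marker)],
    presentRev = segR$present[match(ids, segR$marker)],
    absentRev = segR$absent[match(ids, segR$marker)],
    p11Rev = segR$p_1to1[match(ids, segR$marker)],
    p31Rev = segR$p_3to1[match(ids, segR$marker)],
    allelicWith = vapply(allelic[ids], function(x)
      paste(x, collapse = ","), ""),
    role = roles, sAllele = sAllele)
}

#' Expected number of class III non-LPSC genes per genome
#'
#' Ploidy/SI-status bookkeeping rule used as a sanity check when counting
#' candidate S-RNases: a diploid self-incompatible plant carries two S
#' haplotypes, a self-compatible diploid effectively one functional one,
#' and a haploid or doubled-haploid genome one.
#'
#' @param ploidy `"haploid"`, `"dihaploid"` or `"diploid"`.
#' @param siStatus `"SI"` or `"SC"`.
#' @return integer count.
#' @examples
#' expectedClassIIICount("diploid", "SI")   # 2
#' @export
expectedClassIIICount <- function(ploidy = c("diploid", "haploid",
                                             "dihaploid"),
                                  siStatus = c("SI", "SC")) {
  ploidy <- match.arg(ploidy)
  siStatus <- match.arg(siStatus)
  if (ploidy == "diploid" && siStatus == "SI") 2L else 1L
}
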