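#' Neighbor-joining tree from a p-distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]). On an additive distance
#' matrix the generating topology and branch lengths are recovered
#' exactly. Negative branch-length estimates (possible on non-additive
#' input) are clamped to zero and flagged in the returned tree's
#' `clamped` attribute.
#'
#' This replaces maximum-likelihood tree inference with bootstrap: the
#' screen needs class membership and subcluster identity, not branch
#' support, and the substitution is recorded in every report header.
#'
#' @param dm symmetric numeric matrix of p-distances with ids as
#'   dimnames; >= 3 taxa.
#' @return An [ape] `phylo` tree (unrooted), attribute `clamped` = number
#'   of branch lengths clamped to zero.
#' @examples
#' d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' njTree(d)
#' @export
njTree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) ||
      !isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)))
    .stopf("distance matrix must be square and symmetric")
  if (nrow(dm) < 3L) .stopf("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Classify query sequences against labelled references
#'
#' Each query receives the class (`I`, `II` or `III`) of its nearest
#' labelled reference by p-distance on the common alignment, or
#' `unclassified` when the nearest-reference identity falls below
#' `floor`. Ties between equally near references of different classes go
#' to the smallest class index (and are messaged).
#'
#' @param msa aligned sequences containing both queries and references
#'   (XStringSet or named character).
#' @param queryIds,refIds row names of queries and references.
#' @param refClasses character vector of class labels (`"I"/"II"/"III"`),
#'   parallel to `refIds` (or named by them).
#' @param floor minimum nearest-reference identity for a class call.
#' @param gapPolicy see [pDistance()].
#' @return A [S4Vectors::DataFrame] with one row per query: `id`,
#'   `class`, `support` (nearest-reference identity), `nearestRef`.
#' @export
assignClass <- function(msa, queryIds, refIds, refClasses, floor = 0.30,
                        gapPolicy = "pairwise_deletion") {
  if (length(refIds) == 0L) .stopf("no labelled references supplied")
  if (is.null(names(refClasses))) names(refClasses) <- refIds
  lv <- c("I", "II", "III")
  if (!all(refClasses %in% lv))
    .stopf("reference classes must be I, II or III")
  if (!all(lv %in% refClasses))
    .stopf("need at least one reference per class (I, II, III)")
  rows <- .asRows(msa)
  res <- lapply(queryIds, function(q) {
    d <- vapply(refIds, function(r) pDistance(rows, q, r, gapPolicy), 0)
    idn <- 1 - d
    best <- which(d == min(d))
    if (length(best) > 1L) {
      cls <- refClasses[refIds[best]]
      pick <- best[order(match(cls, lv))][1L]
      if (length(unique(cls)) > 1L)
        message(sprintf(
          "class tie for '%s'; smallest class index (%s) wins",
          q, refClasses[refIds[pick]]))
      best <- pick
    }
    cl <- if (idn[best] < floor) "unclassified"
          else unname(refClasses[refIds[best]])
    list(id = q, class = cl, support = unname(idn[best]),
         nearestRef = refIds[best])
  })
  S4Vectors::DataFrame(
    id = vapply(res, `[[`, "", "id"),
    class = vapply(res, `[[`, "", "class"),
    support = vapply(res, `[[`, 0, "support"),
    nearestRef = vapply(res, `[[`, "", "nearestRef"))
}

#' Detect low-polymorphic subclusters (LPSCs)
#'
#' Groups class III members by single linkage at pairwise identity >=
#' `identityFloor`; groups of at least `minSize` members whose mean
#' pairwise identity also reaches the floor are flagged as LPSCs. LPSC
#' members lack the allelic diversity expected of S-RNases and are
#' excluded from candidacy downstream.
#'
#' @param msa aligned sequences (XStringSet or named character).
#' @param classIIIIds ids of the class III members to examine.
#' @param identityFloor single-linkage and mean-identity floor; the
#'   default 0.85 sits below observed LPSC identities (~0.89-0.97) and
#'   above typical S-allele identities (~0.6-0.8).
#' @param minSize minimum group size flagged.
#' @param gapPolicy see [pDistance()].
#' @return A list with `flags` (named logical over `classIIIIds`) and
#'   `groups` (list of flagged id vectors).
#' @export
detectLpsc <- function(msa, classIIIIds, identityFloor = 0.85,
                       minSize = 3L, gapPolicy = "pairwise_deletion") {
  flags <- setNames(rep(FALSE, length(classIIIIds)), classIIIIds)
  if (length(classIIIIds) < max(2L, minSize))
    return(list(flags = flags, groups = list()))
  rows <- .asRows(msa)[classIIIIds]
  n <- length(rows)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- pDistance(rows, i, j, gapPolicy)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = 1 - identityFloor)
  groups <- list()
  for (g in unique(grp)) {
    ids <- classIIIIds[grp == g]
    if (length(ids) >= minSize &&
        meanPairwiseIdentity(rows, which(grp == g),
                             gapPolicy) >= identityFloor) {
      flags[ids] <- TRUE
      groups[[length(groups) + 1L]] <- ids
    }
  }
  list(flags = flags, groups = groups)
}
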