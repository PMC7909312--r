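#' Global pairwise alignment with linear gap penalty
#'
#' Needleman-Wunsch alignment with the package's fixed scoring scheme
#' (match/mismatch substitution scores, constant per-column gap penalty)
#' and a deterministic traceback (diagonal preferred, then a gap in `b`,
#' then a gap in `a`).
#'
#' @param a,b sequences (character or XString) of the same molecule type.
#' @param match,mismatch,gap scoring parameters.
#' @return A list with `a`, `b` (gapped aligned strings), `score`, and
#'   `identity` (matches / alignment columns excluding terminal-gap
#'   columns; `NA` when no such columns exist).
#' @examples
#' globalAlign("ACGT", "ACT")
#' @export
globalAlign <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(toupper(as.character(a)), "")[[1]]
  b <- strsplit(toupper(as.character(b)), "")[[1]]
  S <- matrix(mismatch, length(a), length(b))
  if (length(a) && length(b))
    S[outer(a, b, "==")] <- match
  r <- .nw_dp(S, gap)
  ga <- ifelse(r$ai > 0L, a[pmax(r$ai, 1L)], "-")
  gb <- ifelse(r$bi > 0L, b[pmax(r$bi, 1L)], "-")
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = r$score, identity = .alignedIdentity(ga, gb))
}

# identity over alignment columns excluding terminal gap runs of either row
.alignedIdentity <- function(ga, gb) {
  n <- length(ga)
  if (n == 0L) return(NA_real_)
  core <- function(v) {
    ng <- which(v != "-")
    if (!length(ng)) return(c(NA_integer_, NA_integer_))
    range(ng)
  }
  ra <- core(ga); rb <- core(gb)
  lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
  if (is.na(lo) || is.na(hi) || lo > hi) return(NA_real_)
  idx <- lo:hi
  sum(ga[idx] == gb[idx] & ga[idx] != "-") / length(idx)
}

#' Fractional identity of two unaligned sequences
#'
#' Convenience wrapper: globally aligns and returns the identity,
#' excluding terminal gaps (the definition used by the greedy clustering
#' stage).
#'
#' @inheritParams globalAlign
#' @return identity fraction in `[0, 1]`.
#' @export
pairIdentity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  globalAlign(a, b, match, mismatch, gap)$identity
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment ordered by a neighbor-joining
#' guide tree built on pairwise p-distances (from pairwise global
#' alignments). Column order is never rearranged after a merge, and
#' ungapping any output row recovers its input sequence exactly.
#'
#' @param seqs an XStringSet (>= 1 sequence) or named character vector.
#' @param match,mismatch,gap scoring for the profile merges (expected
#'   pair score between columns; constant gap penalty).
#' @return A gapped [Biostrings::AAStringSet] (or `BStringSet` for other
#'   alphabets), all rows of equal width, in the input order.
#' @export
progressiveMsa <- function(seqs, match = 1, mismatch = 0, gap = -1) {
  sqs <- .asRows(seqs)
  ids <- if (!is.null(names(sqs))) names(sqs) else
    paste0("seq", seq_along(sqs))
  n <- length(sqs)
  if (n == 0L) .stopf("no sequences to align")
  if (n == 1L)
    return(Biostrings::AAStringSet(setNames(sqs, ids)))
  if (n == 2L) {
    al <- globalAlign(sqs[1], sqs[2], match, mismatch, gap)
    return(Biostrings::AAStringSet(setNames(c(al$a, al$b), ids)))
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- globalAlign(sqs[i], sqs[j], match, mismatch, gap)
    pd <- 1 - al$identity
    d[i, j] <- d[j, i] <- if (is.na(pd)) 1 else pd
  }
  tr <- ape::reorder.phylo(ape::nj(d), "postorder")
  nodeProf <- vector("list", max(tr$edge))
  for (i in seq_len(n))
    nodeProf[[i]] <- list(rows = sqs[i], ids = ids[i])
  # postorder edges: children are ready before their parent is visited
  parents <- unique(tr$edge[, 1L])
  for (p in parents) {
    ch <- tr$edge[tr$edge[, 1L] == p, 2L]
    prof <- nodeProf[[ch[1L]]]
    for (k in ch[-1L])
      prof <- .mergeProfiles(prof, nodeProf[[k]], match, mismatch, gap)
    nodeProf[[p]] <- prof
  }
  root <- parents[length(parents)]
  prof <- nodeProf[[root]]
  out <- setNames(prof$rows, prof$ids)[ids]
  Biostrings::AAStringSet(out)
}

.profileFreq <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  letters <- sort(setdiff(unique(as.vector(m)), "-"))
  if (!length(letters)) letters <- "X"
  P <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = letters), length(letters))
  }, numeric(length(letters)))
  P <- matrix(P, nrow = length(letters)) / length(rows)
  rownames(P) <- letters
  P
}

.mergeProfiles <- function(pa, pb, match, mismatch, gap) {
  A <- .profileFreq(pa$rows)
  B <- .profileFreq(pb$rows)
  common <- union(rownames(A), rownames(B))
  pad <- function(P) {
    M <- matrix(0, length(common), ncol(P), dimnames = list(common, NULL))
    M[rownames(P), ] <- P
    M
  }
  A <- pad(A); B <- pad(B)
  D <- crossprod(A, B)
  S <- match * D + mismatch * (outer(colSums(A), colSums(B)) - D)
  r <- .nw_dp(S, gap)
  gapCols <- function(rows, idx) {
    chs <- strsplit(rows, "")
    vapply(chs, function(v) paste(ifelse(idx > 0L, v[pmax(idx, 1L)], "-"),
                                  collapse = ""), "")
  }
  list(rows = c(gapCols(pa$rows, r$ai), gapCols(pb$rows, r$bi)),
       ids = c(pa$ids, pb$ids))
}

#' p-distance between two rows of an alignment
#'
#' Proportion of differing sites over the compared sites. Compared sites
#' exclude columns gapped in either of the two rows
#' (`"pairwise_deletion"`, the default) or in any row of the alignment
#' (`"complete_deletion"`). Identity is `1 - p`.
#'
#' @param msa aligned sequences (XStringSet or character), equal widths.
#' @param i,j row indices or names.
#' @param gapPolicy `"pairwise_deletion"` or `"complete_deletion"`.
#' @return p-distance fraction in `[0, 1]`.
#' @examples
#' pDistance(c(a = "AAAA", b = "AAAT"), 1, 2)
#' @export
pDistance <- function(msa, i, j,
                      gapPolicy = c("pairwise_deletion",
                                    "complete_deletion")) {
  gapPolicy <- match.arg(gapPolicy)
  rows <- .asRows(msa)
  if (length(unique(nchar(rows))) != 1L)
    .stopf("alignment rows must have equal width")
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  a <- m[i, ]; b <- m[j, ]
  keep <- if (gapPolicy == "pairwise_deletion") a != "-" & b != "-"
          else colSums(m == "-") == 0L
  if (!any(keep)) .stopf("no overlap: zero compared sites")
  sum(a[keep] != b[keep]) / sum(keep)
}

#' All pairwise p-distances of an alignment
#'
#' @inheritParams pDistance
#' @return A symmetric matrix of p-distances with the alignment ids as
#'   dimnames.
#' @export
distanceMatrix <- function(msa, gapPolicy = "pairwise_deletion") {
  rows <- .asRows(msa)
  ids <- if (!is.null(names(rows))) names(rows) else
    paste0("seq", seq_along(rows))
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- pDistance(rows, i, j, gapPolicy)
  d
}

#' Mean pairwise identity of a group of aligned sequences
#'
#' Mean over all unordered pairs of `1 - p-distance`; the statistic used
#' to call low-polymorphic subclusters.
#'
#' @inheritParams pDistance
#' @param memberIds row names (or indices) of the group; >= 2 required.
#' @return fraction in `[0, 1]`.
#' @export
meanPairwiseIdentity <- function(msa, memberIds = NULL,
                                 gapPolicy = "pairwise_deletion") {
  rows <- .asRows(msa)
  if (!is.null(memberIds)) rows <- rows[memberIds]
  if (length(rows) < 2L) .stopf("need >= 2 members for pairwise identity")
  prs <- combn(length(rows), 2L)
  mean(vapply(seq_len(ncol(prs)), function(k)
    1 - pDistance(rows, prs[1L, k], prs[2L, k], gapPolicy), 0))
}
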