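#' Tissue vocabulary of the expression panel
#'
#' @return character vector of the tissue names a panel may use.
#' @export
tissueVocabulary <- function() {
  c("style", "stigma", "ovary", "anther_pollen", "filament", "sepal",
    "petal", "albedo", "flavedo", "juice_sac")
}

#' Tissue-specificity call for one gene
#'
#' Classifies a detection profile over floral/fruit tissues. An S-RNase
#' is expected to be `pistil_specific` (detected in stigma/style/ovary
#' and nowhere else); any detection in a non-pistil tissue - notably
#' anther and pollen - disqualifies it. The call is invariant to tissue
#' column order.
#'
#' Labels: `not_detected` (nowhere); `pistil_specific` (pistil tissues
#' only); `ubiquitous` (all tissues, or non-pistil only);
#' `pistil_plus_other` (pistil plus a proper subset of other tissues).
#'
#' @param panelRow named logical/numeric vector over the panel tissues
#'   (values are compared against `detectThreshold`).
#' @param pistilSet tissues counted as pistil.
#' @param detectThreshold detection cutoff (boolean panels: keep 1).
#' @return one of `"pistil_specific"`, `"pistil_plus_other"`,
#'   `"ubiquitous"`, `"not_detected"`.
#' @examples
#' tissueSpecificity(c(stigma = 1, style = 1, ovary = 1, anther_pollen = 0,
#'                     filament = 0, sepal = 0, petal = 0, albedo = 0,
#'                     flavedo = 0, juice_sac = 0))
#' @export
tissueSpecificity <- function(panelRow,
                              pistilSet = c("stigma", "style", "ovary"),
                              detectThreshold = 1) {
  tissues <- names(panelRow)
  bad <- setdiff(tissues, tissueVocabulary())
  if (length(bad))
    .stopf("unknown tissue name(s): %s", paste(bad, collapse = ", "))
  det <- as.numeric(panelRow) >= detectThreshold
  names(det) <- tissues
  pist <- det[intersect(tissues, pistilSet)]
  other <- det[setdiff(tissues, pistilSet)]
  if (!any(det)) return("not_detected")
  if (!any(other)) return("pistil_specific")
  if (all(det)) return("ubiquitous")
  if (any(pist)) return("pistil_plus_other")
  "ubiquitous"
}

#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification: `dCt = Ct_target - Ct_reference` per
#' condition, `ddCt = dCt(test) - dCt(control)`, fold change
#' `2^-ddCt`. Replicate standard errors are propagated in quadrature and
#' reported as a fold-change interval.
#'
#' @param ctTargetTest,ctRefTest,ctTargetControl,ctRefControl numeric
#'   vectors of replicate Ct values (>= 1 replicate each, all > 0).
#' @return list with `fold`, `ddct`, `se` (SE of ddCt) and `foldRange`
#'   (`2^-(ddct +/- se)`).
#' @examples
#' ddct(25, 20, 24, 20)$fold   # 0.5
#' @export
ddct <- function(ctTargetTest, ctRefTest, ctTargetControl, ctRefControl) {
  grps <- list(ctTargetTest, ctRefTest, ctTargetControl, ctRefControl)
  if (any(vapply(grps, length, 0L) < 1L) ||
      any(!is.finite(unlist(grps))))
    .stopf("all four Ct conditions need >= 1 finite replicate")
  if (any(unlist(grps) <= 0)) .stopf("Ct values must be > 0")
  mu <- vapply(grps, mean, 0)
  se <- vapply(grps, function(x)
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0, 0)
  dd <- (mu[1] - mu[2]) - (mu[3] - mu[4])
  seDD <- sqrt(sum(se^2))
  list(fold = 2^-dd, ddct = dd, se = seDD,
       foldRange = 2^-(dd + c(1, -1) * seDD))
}

#' Median-of-ratios library size factors
#'
#' Size factor per sample = median across genes of the ratio to the
#' per-gene geometric mean, computed over genes with all-positive
#' counts.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors.
#' @export
sizeFactors <- function(counts) {
  lg <- log(counts)
  gm <- rowMeans(lg)
  use <- is.finite(gm)
  if (!any(use)) .stopf("no gene with all-positive counts")
  apply(counts[use, , drop = FALSE], 2L,
        function(x) exp(stats::median(log(x) - gm[use])))
}

#' Permutation differential-expression test (NOT a DESeq2 equivalent)
#'
#' Simple, clearly-labelled substitute for a negative-binomial DE model:
#' counts are normalized by median-of-ratios size factors, the per-gene
#' statistic is the difference of group means of log2(normalized count
#' + 1), and P values come from group-label permutation - exact
#' enumeration when there are at most 20 distinct label assignments,
#' otherwise `nPerm` random draws. BH correction gives q values.
#' All-zero genes get p = 1 and are flagged.
#'
#' @param counts gene x sample matrix.
#' @param groups factor/vector of two group labels, one per sample.
#' @param nPerm random permutations when exact enumeration is not used.
#' @param seed RNG seed for random permutations.
#' @param fdrLevel FDR level recorded with the result.
#' @return [S4Vectors::DataFrame]: `gene`, `log2fc` (group2 - group1),
#'   `p`, `q`, `direction`, `allZero`; metadata notes the method is
#'   permutation-based, not DESeq2-equivalent.
#' @export
simpleDeTest <- function(counts, groups, nPerm = 1000L, seed = 1L,
                         fdrLevel = 0.05) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    .stopf("exactly two groups required")
  if (any(table(groups) < 2L))
    .stopf("need >= 2 samples per group")
  sf <- sizeFactors(counts)
  l <- log2(sweep(counts, 2L, sf, "/") + 1)
  g2 <- groups == levels(groups)[2L]
  statFor <- function(sel)
    rowMeans(l[, sel, drop = FALSE]) - rowMeans(l[, !sel, drop = FALSE])
  obs <- statFor(g2)
  nSamp <- ncol(counts)
  k <- sum(g2)
  nAssign <- choose(nSamp, k)
  perms <- if (nAssign <= 20L) {
    combn(nSamp, k, function(ix) {
      sel <- rep(FALSE, nSamp); sel[ix] <- TRUE; sel
    }, simplify = FALSE)
  } else {
    .withSeed(seed, replicate(nPerm, sample(g2), simplify = FALSE))
  }
  permStats <- vapply(perms, statFor, numeric(nrow(counts)))
  p <- rowMeans(abs(permStats) >= abs(obs) - 1e-12)
  allZero <- rowSums(counts) == 0
  p[allZero] <- 1
  res <- S4Vectors::DataFrame(
    gene = if (!is.null(rownames(counts))) rownames(counts) else
      paste0("g", seq_len(nrow(counts))),
    log2fc = unname(obs),
    p = unname(p),
    q = unname(p.adjust(p, "BH")),
    direction = ifelse(obs > 0, "up", ifelse(obs < 0, "down", "none")),
    allZero = unname(allZero))
  S4Vectors::metadata(res) <- list(
    method = "permutation (NOT DESeq2-equivalent)",
    exact = nAssign <= 20L, fdrLevel = fdrLevel)
  res
}
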