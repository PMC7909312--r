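#' Infer exon/intron structure by exact spliced mapping
#'
#' Finds the exon chain on the genomic sequence whose concatenation
#' reproduces the CDS exactly (Sanger-grade input: no mismatches),
#' minimizing the number of introns, preferring `GT..AG` introns among
#' equal-count solutions, then leftmost donors. The reconstruction of the
#' CDS from the chosen exons is asserted on every call.
#'
#' @param cds coding sequence (character or [Biostrings::DNAString]).
#' @param genomic genomic sequence containing the gene.
#' @param maxIntrons maximum number of introns allowed (default 3).
#' @param geneId id recorded in the model.
#' @return A [GeneModel-class]; splice donor/acceptor dinucleotides are
#'   reported per intron.
#' @examples
#' g <- paste0("ATGGCC", "GTAAGTTTTAG", "GATTAA")   # one 11-bp intron
#' inferGeneStructure("ATGGCCGATTAA", g)
#' @export
inferGeneStructure <- function(cds, genomic, maxIntrons = 3L,
                               geneId = "gene") {
  cds <- toupper(as.character(cds))
  genomic <- toupper(as.character(genomic))
  n <- nchar(cds); m <- nchar(genomic)
  if (n < 1L) .stopf("empty CDS")
  if (n > m) .stopf("CDS longer than genomic sequence")
  alph <- c("A", "C", "G", "T", "N")
  ci <- match(strsplit(cds, "")[[1]], alph)
  gi <- match(strsplit(genomic, "")[[1]], alph)
  if (anyNA(ci) || anyNA(gi))
    .stopf("sequences must be A/C/G/T/N")
  gch <- strsplit(genomic, "")[[1]]
  # donorOk[j]: intron starting at genomic j begins GT;
  # accOk[j]: intron ending at genomic j ends AG
  donorOk <- c(gch[-m] == "G" & gch[-1L] == "T", FALSE)
  accOk <- c(FALSE, gch[-m] == "A" & gch[-1L] == "G")
  BIG <- 1e6
  # DP matrix is transposed: Ft[j, i] = cost with cds i at genomic j
  Ft <- .spliced_cost(ci, gi, as.integer(donorOk), as.integer(accOk), BIG)
  last <- Ft[, n]
  if (all(!is.finite(last))) .stopf("unmappable CDS")
  best <- min(last)
  nIntrons <- best %/% BIG
  if (nIntrons > maxIntrons)
    .stopf("unmappable CDS within %d introns (needs %d)",
           maxIntrons, nIntrons)
  chains <- .enumerateChains(Ft, donorOk, accOk, BIG, best, cap = 64L)
  if (length(chains) > 1L) {
    # GT..AG preference is already in the DP cost; remaining tie-break is
    # leftmost donors (donor = base after each exon end)
    donKey <- vapply(chains, function(ch)
      paste(formatC(utils::head(ch$ends, -1L) + 1L, width = 10,
                    flag = "0"), collapse = ","), "")
    ord <- order(donKey)
    chains <- chains[ord]
    donKey <- donKey[ord]
    if (donKey[1L] == donKey[2L]) {
      cand <- vapply(chains[donKey == donKey[1L]], function(ch)
        paste(sprintf("%d-%d", ch$starts, ch$ends), collapse = ","), "")
      .stopf("ambiguous spliced mapping; candidate exon chains: %s",
             paste(cand, collapse = " | "))
    }
  }
  ch <- chains[[1L]]
  ex <- IRanges::IRanges(ch$starts, ch$ends)
  ss <- character(0)
  if (length(ex) > 1L) {
    ds <- IRanges::end(ex)[-length(ex)] + 1L
    as <- IRanges::start(ex)[-1L] - 1L
    ss <- paste0(substring(genomic, ds, pmin(ds + 1L, m)), "..",
                 substring(genomic, pmax(as - 1L, 1L), as))
  }
  GeneModel(geneId, ex, ss, cds, m, genomic = genomic)
}

# Enumerate all optimal exon chains from the spliced-mapping DP matrix.
# Returns list of list(starts, ends) (genomic, 1-based). The walk is
# iterative along diagonal (same-exon) runs and recurses only at intron
# decisions; capped to keep pathological inputs bounded.
.enumerateChains <- function(Ft, donorOk, accOk, BIG, best, cap = 64L) {
  m <- nrow(Ft); n <- ncol(Ft)
  donorOkPad <- c(donorOk, FALSE)
  sols <- list()
  walk <- function(i, j, exonEnd, starts, endsAcc) {
    repeat {
      if (length(sols) >= cap)
        .stopf("ambiguous spliced mapping: too many optimal chains")
      if (i == 1L) {
        sols[[length(sols) + 1L]] <<-
          list(starts = c(j, starts), ends = c(exonEnd, endsAcc))
        return(invisible(NULL))
      }
      diagOk <- j > 1L && is.finite(Ft[j - 1L, i - 1L]) &&
        Ft[j - 1L, i - 1L] == Ft[j, i]
      if (Ft[j, i] >= BIG && j > 2L) {
        jp <- seq_len(j - 2L)
        v <- Ft[jp, i - 1L]
        canonical <- donorOkPad[jp + 1L] & accOk[j - 1L]
        cost <- v + BIG + as.numeric(!canonical)
        for (jpk in jp[is.finite(v) & cost == Ft[j, i]])
          walk(i - 1L, jpk, jpk, c(j, starts), c(exonEnd, endsAcc))
      }
      if (!diagOk) return(invisible(NULL))
      i <- i - 1L; j <- j - 1L
    }
  }
  for (je in which(Ft[, n] == best)) walk(n, je, je, integer(0), integer(0))
  sols
}

#' Plausibility annotation of intron lengths
#'
#' Checks each intron of a model against a configurable plausible range
#' (default 50-2000 bp) and annotates, without filtering, whether it also
#' falls in the 87-374 bp band observed for citrus class III T2 RNase
#' introns.
#'
#' @param model a [GeneModel-class].
#' @param range plausible length range.
#' @param observedBand annotation band reported alongside.
#' @return data.frame with `intron`, `length`, `plausible`,
#'   `inObservedBand`.
#' @export
intronLengthCheck <- function(model, range = c(50L, 2000L),
                              observedBand = c(87L, 374L)) {
  len <- intronLengths(model)
  data.frame(intron = seq_along(len), length = len,
             plausible = len >= range[1] & len <= range[2],
             inObservedBand = len >= observedBand[1] &
               len <= observedBand[2])
}

#' Hypervariable / conserved window annotation on an alignment
#'
#' Builds the named alignment-column windows (HV1-HV5, C1-C5 style) used
#' to test the structural S-RNase criterion. Windows must not overlap.
#'
#' @param starts,ends alignment columns (1-based inclusive).
#' @param labels window names (default `HV1..HVn`).
#' @return named [IRanges::IRanges].
#' @examples
#' hvWindows(c(10, 50), c(20, 70))
#' @export
hvWindows <- function(starts, ends, labels = paste0("HV", seq_along(starts))) {
  w <- IRanges::IRanges(starts, ends, names = labels)
  if (length(w) > 1L) {
    o <- order(IRanges::start(w))
    if (any(IRanges::start(w)[o][-1L] <=
            IRanges::end(w)[o][-length(w)]))
      .stopf("HV windows must not overlap")
  }
  w
}

#' Single-intron-in-HV structural criterion
#'
#' Maps each intron's donor-site CDS coordinate to its codon, then to the
#' corresponding column of the gene's aligned protein row, and tests the
#' S-RNase structural criterion: exactly one intron, located inside a
#' hypervariable window. Intron phase (0/1/2) is reported.
#'
#' @param model a [GeneModel-class].
#' @param alignedRow the gene's gapped protein alignment row.
#' @param hv [hvWindows()] on the same alignment.
#' @return list with `countOk` (TRUE iff exactly one intron inside an HV
#'   window), `labels` (window name, `"outside"` or `"unalignable"` per
#'   intron), `phase`, `column`.
#' @export
intronInHv <- function(model, alignedRow, hv) {
  row <- strsplit(as.character(alignedRow), "")[[1]]
  if (any(IRanges::end(hv) > length(row)))
    .stopf("HV windows outside alignment width")
  resCols <- which(row != "-")
  ex <- IRanges::width(exons(model))
  nIn <- length(ex) - 1L
  if (nIn == 0L)
    return(list(countOk = FALSE, labels = character(0),
                phase = integer(0), column = integer(0)))
  donorCds <- cumsum(ex)[-length(ex)]   # last CDS base of each exon
  codon <- ceiling(donorCds / 3)
  phase <- donorCds %% 3L
  labels <- character(nIn); column <- rep(NA_integer_, nIn)
  for (k in seq_len(nIn)) {
    if (codon[k] > length(resCols)) { labels[k] <- "unalignable"; next }
    col <- resCols[codon[k]]
    column[k] <- col
    hit <- which(col >= IRanges::start(hv) & col <= IRanges::end(hv))
    labels[k] <- if (length(hit)) names(hv)[hit[1L]] else "outside"
  }
  countOk <- nIn == 1L && labels[1L] %in% names(hv)
  list(countOk = countOk, labels = labels, phase = phase, column = column)
}
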