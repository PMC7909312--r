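#' Longest open reading frame across all six frames
#'
#' Finds the longest ORF of a transcript, scanning the three forward and
#' three reverse-complement frames. Candidate ORFs are stop-free runs of
#' codons; with `requireStart = TRUE` a run must begin at the first
#' methionine of its stop-delimited segment. ORFs may run off either end
#' of the transcript (assembled transcripts are frequently truncated), so
#' neither a leading start codon nor a trailing stop is required by
#' default.
#'
#' Ties on protein length are broken by frame order
#' (+1, +2, +3, -1, -2, -3), then by the leftmost start within the frame.
#'
#' @param transcript nucleotide sequence (character or
#'   [Biostrings::DNAString]); IUPAC ambiguity codes are allowed and
#'   translate to `X`.
#' @param minAa minimum protein length (residues) to report; default 200,
#'   the screen's short-sequence cutoff.
#' @param requireStart require the ORF to start at a methionine.
#' @param id transcript id recorded in the call.
#' @return A list with elements `transcript_id`, `frame` (in
#'   `-3..-1, 1..3`), `nt_start`/`nt_end` (0-based half-open on the
#'   forward strand), and `protein`; or `NULL` if no ORF reaches `minAa`.
#' @examples
#' longestOrf("ATGAAATAA", minAa = 1, requireStart = TRUE)
#' @export
longestOrf <- function(transcript, minAa = 200L, requireStart = FALSE,
                       id = "transcript") {
  if (minAa < 1L) .stopf("minAa must be >= 1")
  sq <- toupper(as.character(transcript))
  ok <- strsplit("ACGTUMRWSYKVHDBN", "")[[1]]
  bad <- setdiff(unique(strsplit(sq, "")[[1]]), ok)
  if (length(bad))
    .stopf("non-nucleotide character(s) in transcript: %s",
           paste(bad, collapse = ", "))
  sq <- chartr("U", "T", sq)
  L <- nchar(sq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  best <- NULL
  frames <- list(c(1L, 0L), c(2L, 1L), c(3L, 2L),
                 c(-1L, 0L), c(-2L, 1L), c(-3L, 2L))
  for (fr in frames) {
    strandSeq <- if (fr[1] > 0) sq else rc
    off <- fr[2]
    nCodon <- (L - off) %/% 3L
    if (nCodon < 1L) next
    codons <- substring(strandSeq, off + 3L * (seq_len(nCodon) - 1L) + 1L,
                        off + 3L * seq_len(nCodon))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    # stop-delimited segments of the frame translation
    stops <- c(0L, which(aa == "*"), nCodon + 1L)
    for (k in seq_len(length(stops) - 1L)) {
      a <- stops[k] + 1L
      b <- stops[k + 1L] - 1L
      if (b < a) next
      if (requireStart) {
        m <- which(aa[a:b] == "M")
        if (!length(m)) next
        a <- a + m[1L] - 1L
      }
      len <- b - a + 1L
      if (len < minAa) next
      if (!is.null(best) && len <= best$len) next
      # strand-local 0-based half-open nt coords, then forward-strand
      s0 <- off + 3L * (a - 1L)
      e0 <- off + 3L * b
      if (fr[1] < 0) { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
      best <- list(len = len, frame = fr[1], nt_start = s0, nt_end = e0,
                   protein = paste(aa[a:(a + len - 1L)], collapse = ""))
    }
  }
  if (is.null(best)) return(NULL)
  list(transcript_id = id, frame = best$frame, nt_start = best$nt_start,
       nt_end = best$nt_end, protein = best$protein)
}

#' Extract proteins from a set of transcripts by longest ORF
#'
#' @param transcripts a [Biostrings::DNAStringSet].
#' @inheritParams longestOrf
#' @return An [Biostrings::AAStringSet] of the retained proteins, named by
#'   transcript id; transcripts with no ORF of at least `minAa` residues
#'   are dropped.
#' @export
extractProteins <- function(transcripts, minAa = 200L,
                            requireStart = FALSE) {
  ids <- fastaIds(transcripts)
  calls <- lapply(seq_along(transcripts), function(i)
    longestOrf(transcripts[[i]], minAa = minAa,
               requireStart = requireStart, id = ids[i]))
  keep <- !vapply(calls, is.null, TRUE)
  prots <- vapply(calls[keep], `[[`, "", "protein")
  Biostrings::AAStringSet(setNames(prots, ids[keep]))
}
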