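# Independent brute-force / direct-formula oracles. These deliberately
# re-derive each quantity from its definition, sharing no code with the
# implementation under test.

AA20h <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randProtein <- function(len) paste(sample(AA20h, len, TRUE), collapse = "")
randDna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = "")

# exhaustive six-frame ORF scan: every stop-delimited run, every frame,
# with the same tie rules (longest, then frame order, then leftmost)
oracleLongestOrf <- function(seq, minAa, requireStart) {
  seq <- chartr("U", "T", toupper(seq))
  L <- nchar(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  best <- NULL
  for (fi in seq_len(6)) {
    fr <- c(1, 2, 3, -1, -2, -3)[fi]
    s <- if (fr > 0) seq else rc
    off <- abs(fr) - 1
    nc <- (L - off) %/% 3
    if (nc < 1) next
    aa <- vapply(seq_len(nc), function(k) {
      cod <- substr(s, off + 3 * (k - 1) + 1, off + 3 * k)
      if (grepl("[^ACGT]", cod)) "X"
      else Biostrings::GENETIC_CODE[[cod]]
    }, "")
    bounds <- c(0, which(aa == "*"), nc + 1)
    for (b in seq_len(length(bounds) - 1)) {
      a0 <- bounds[b] + 1; b0 <- bounds[b + 1] - 1
      if (b0 < a0) next
      if (requireStart) {
        mpos <- which(aa[a0:b0] == "M")
        if (!length(mpos)) next
        a0 <- a0 + mpos[1] - 1
      }
      len <- b0 - a0 + 1
      if (len < minAa) next
      if (is.null(best) || len > best$len)
        best <- list(len = len, frame = fr,
                     protein = paste(aa[a0:b0], collapse = ""))
    }
  }
  best
}

# exhaustive enumeration of all global alignments (for short sequences)
oracleAlignScore <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  f <- function(i, j) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best,
                  (if (A[i] == B[j]) match else mismatch) + f(i + 1, j + 1))
    if (i <= length(A)) best <- max(best, gap + f(i + 1, j))
    if (j <= length(B)) best <- max(best, gap + f(i, j + 1))
    best
  }
  f(1, 1)
}

# term-by-term Henderson-Hasselbalch sum, looping over residues
oracleNetCharge <- function(protein, pH, pka = pkaTable()) {
  ch <- 1 / (1 + 10^(pH - pka$Nterm)) - 1 / (1 + 10^(pka$Cterm - pH))
  for (a in strsplit(protein, "")[[1]]) {
    if (a %in% c("H", "K", "R"))
      ch <- ch + 1 / (1 + 10^(pH - pka[[a]]))
    if (a %in% c("C", "D", "E", "Y"))
      ch <- ch - 1 / (1 + 10^(pka[[a]] - pH))
  }
  ch
}

# vectorized charge curve on a 1e-4 pH grid; pI = grid argmin of |charge|
oracleGridPi <- function(protein, pka = pkaTable()) {
  cnt <- table(factor(strsplit(protein, "")[[1]],
                      levels = c("C", "D", "E", "H", "K", "R", "Y")))
  ph <- seq(0, 14, by = 1e-4)
  ch <- 1 / (1 + 10^(ph - pka$Nterm)) - 1 / (1 + 10^(pka$Cterm - ph))
  for (a in c("H", "K", "R"))
    ch <- ch + cnt[[a]] / (1 + 10^(ph - pka[[a]]))
  for (a in c("C", "D", "E", "Y"))
    ch <- ch - cnt[[a]] / (1 + 10^(pka[[a]] - ph))
  ph[which.min(abs(ch))]
}

# column-by-column site counting
oraclePDistance <- function(rowA, rowB) {
  a <- strsplit(rowA, "")[[1]]; b <- strsplit(rowB, "")[[1]]
  diff <- 0L; comp <- 0L
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") next
    comp <- comp + 1L
    if (a[k] != b[k]) diff <- diff + 1L
  }
  diff / comp
}

# two-step textbook evaluation of the relative-quantification formula
oracleDdct <- function(tt, rt, tc, rc) {
  dctTest <- mean(tt) - mean(rt)
  dctCtrl <- mean(tc) - mean(rc)
  2^-(dctTest - dctCtrl)
}
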