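# Average residue masses (Da) and the EMBOSS pKa constants used by the
# charge model. Masses are residue (water-free) averages; one water is
# added per chain.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

#' pKa constant sets for the protein charge model
#'
#' The default set is the EMBOSS convention (used by `iep`): ionizable
#' side chains C, D, E, H, K, R, Y plus the two termini. The set is
#' pluggable because published pI values depend on the constant set the
#' original calculator used; the set name is recorded in feature tables.
#'
#' @param name currently `"EMBOSS"`.
#' @return A named list of pKa values (`Nterm`, `Cterm`, `C`, `D`, `E`,
#'   `H`, `K`, `R`, `Y`) with a `name` element.
#' @examples
#' pkaTable()$K
#' @export
pkaTable <- function(name = "EMBOSS") {
  tabs <- list(EMBOSS = list(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9,
                             E = 4.1, H = 6.5, K = 10.8, R = 12.5,
                             Y = 10.1))
  if (!name %in% names(tabs)) .stopf("unknown pKa set '%s'", name)
  c(tabs[[name]], list(name = name))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch charge model: each basic group (N-terminus, H,
#' K, R) contributes `1 / (1 + 10^(pH - pKa))`, each acidic group
#' (C-terminus, C, D, E, Y) contributes `-1 / (1 + 10^(pKa - pH))`. The
#' result is strictly decreasing in pH. Unknown residue codes are counted
#' as non-ionizable (messaged once per call).
#'
#' @param protein amino-acid sequence (character or AAString).
#' @param pH in `[0, 14]`.
#' @param pka a [pkaTable()].
#' @param cysteineIonizable treat C as ionizable (EMBOSS convention).
#' @param includeTermini include the terminal groups.
#' @return signed charge in elementary-charge units.
#' @examples
#' netCharge("ACD", 0)   # ~ +1: only the N-terminus is charged
#' @export
netCharge <- function(protein, pH, pka = pkaTable(),
                      cysteineIonizable = TRUE, includeTermini = TRUE) {
  if (pH < 0 || pH > 14) .stopf("pH must be in [0, 14]")
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (!length(aa)) .stopf("empty protein")
  unknown <- setdiff(unique(aa), names(.AA_MASS))
  if (length(unknown))
    message("non-ionizable unknown residue code(s): ",
            paste(unknown, collapse = ", "))
  cnt <- table(factor(aa, levels = names(.AA_MASS)))
  basic <- function(n, pk) n / (1 + 10^(pH - pk))
  acid <- function(n, pk) -n / (1 + 10^(pk - pH))
  ch <- basic(cnt[["H"]], pka$H) + basic(cnt[["K"]], pka$K) +
        basic(cnt[["R"]], pka$R) +
        acid(cnt[["D"]], pka$D) + acid(cnt[["E"]], pka$E) +
        acid(cnt[["Y"]], pka$Y)
  if (cysteineIonizable) ch <- ch + acid(cnt[["C"]], pka$C)
  if (includeTermini)
    ch <- ch + basic(1, pka$Nterm) + acid(1, pka$Cterm)
  unname(ch)
}

#' Isoelectric point by bisection
#'
#' The pH at which [netCharge()] is zero, found by bisection on
#' `[0, 14]` (the charge is strictly monotone, so the root is unique),
#' with a 200-iteration cap.
#'
#' @inheritParams netCharge
#' @param tol pH tolerance of the bisection.
#' @return pH of zero net charge.
#' @examples
#' isoelectricPoint("GKG") > isoelectricPoint("GDG")
#' @export
isoelectricPoint <- function(protein, pka = pkaTable(), tol = 1e-4,
                             cysteineIonizable = TRUE,
                             includeTermini = TRUE) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (!length(aa)) .stopf("empty protein")
  ionizable <- c("C"[cysteineIonizable], "D", "E", "H", "K", "R", "Y")
  if (!includeTermini && !any(aa %in% ionizable))
    .stopf("pI undefined: no ionizable groups")
  f <- function(p) netCharge(protein, p, pka, cysteineIonizable,
                             includeTermini)
  lo <- 0; hi <- 14
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight of a protein (average isotopic)
#'
#' Sum of residue average masses plus one water.
#'
#' @inheritParams netCharge
#' @return mass in daltons.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(protein) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (!length(aa)) .stopf("empty protein")
  unknown <- setdiff(unique(aa), names(.AA_MASS))
  if (length(unknown))
    .stopf("unknown residue code(s): %s", paste(unknown, collapse = ", "))
  sum(.AA_MASS[aa]) + .WATER_MASS
}

#' Presence of the two catalytic CAS histidines
#'
#' T2 RNases carry two conserved segments (CAS I and CAS II), each with a
#' histidine essential for RNase activity. Given the two CAS histidine
#' columns of a reference-annotated alignment, this reports whether a
#' query row has `H` in those columns.
#'
#' @param alignedRow the query's gapped alignment row (character).
#' @param casColumns integer(2): alignment columns of the CAS I and
#'   CAS II histidines.
#' @return named logical `c(cas1_his, cas2_his)`.
#' @export
detectCasHistidines <- function(alignedRow, casColumns) {
  row <- strsplit(as.character(alignedRow), "")[[1]]
  if (any(casColumns < 1L) || any(casColumns > length(row)))
    .stopf("CAS annotation columns outside alignment width (%d)",
           length(row))
  ch <- row[casColumns]
  c(cas1_his = ch[1] == "H", cas2_his = ch[2] == "H")
}

#' Per-sequence protein feature table
#'
#' Length, molecular weight and isoelectric point for each protein; the
#' S-RNase likeness features aggregated downstream.
#'
#' @param proteins [Biostrings::AAStringSet] (ungapped).
#' @param pka a [pkaTable()].
#' @param localization optional externally supplied subcellular
#'   localization column (e.g. from a dedicated predictor), recycled or
#'   named by id.
#' @return [S4Vectors::DataFrame] with `id`, `length`, `mw`, `pI`
#'   (metadata records the pKa set name).
#' @export
proteinFeatures <- function(proteins, pka = pkaTable(),
                            localization = NULL) {
  sqs <- .asRows(proteins)
  ids <- if (!is.null(names(sqs))) names(sqs) else
    paste0("seq", seq_along(sqs))
  df <- S4Vectors::DataFrame(
    id = ids,
    length = nchar(sqs),
    mw = vapply(sqs, molecularWeight, 0, USE.NAMES = FALSE),
    pI = vapply(sqs, function(s) isoelectricPoint(s, pka), 0,
                USE.NAMES = FALSE))
  if (!is.null(localization)) {
    df$localization <- if (!is.null(names(localization)))
      unname(localization[ids]) else localization
  }
  S4Vectors::metadata(df)$pkaSet <- pka$name
  df
}

#' Class-wise aggregation of protein features
#'
#' Mean pI, mean molecular weight and counts per phylogenetic class,
#' mirroring the class-level summaries used to contrast the basic class
#' III proteins against the acidic classes I and II.
#'
#' @param features output of [proteinFeatures()].
#' @param classes character vector of class labels named by id (or
#'   parallel to the feature rows).
#' @return [S4Vectors::DataFrame] with one row per class.
#' @export
classSummary <- function(features, classes) {
  if (!is.null(names(classes))) classes <- classes[features$id]
  sp <- split(seq_len(nrow(features)), classes)
  S4Vectors::DataFrame(
    class = names(sp),
    n = lengths(sp),
    meanPi = vapply(sp, function(i) mean(features$pI[i]), 0),
    meanMw = vapply(sp, function(i) mean(features$mw[i]), 0))
}
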