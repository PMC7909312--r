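#' @include AllClasses.R
NULL

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param exons [IRanges::IRanges] of exon coordinates (1-based inclusive
#'   on the genomic sequence), sorted and non-overlapping.
#' @param spliceSites character vector of `"NN..NN"` donor/acceptor
#'   dinucleotides, one per intron.
#' @param cds the spliced CDS the exons encode.
#' @param genomicLength length of the genomic sequence.
#' @param genomic optional genomic sequence (character or
#'   [Biostrings::DNAString]); when given, the concatenated exon sequence
#'   is checked against `cds` (hard postcondition of spliced mapping).
#' @return A [GeneModel-class] object.
#' @examples
#' GeneModel("g1", IRanges::IRanges(1, 300), character(),
#'           cds = strrep("A", 300), genomicLength = 300L)
#' @export
GeneModel <- function(geneId, exons, spliceSites = character(), cds,
                      genomicLength, genomic = NULL) {
  if (!is.null(genomic)) {
    genomic <- as.character(genomic)
    genomicLength <- nchar(genomic)
    got <- paste(substring(genomic, IRanges::start(exons),
                           IRanges::end(exons)), collapse = "")
    if (!identical(got, as.character(cds)))
      .stopf("exon chain does not reconstruct the CDS for gene '%s'", geneId)
  }
  new("GeneModel", geneId = as.character(geneId), exons = exons,
      spliceSites = as.character(spliceSites), cds = as.character(cds),
      genomicLength = as.integer(genomicLength))
}

#' Construct an SGenotype
#'
#' @param a1,a2 the two S-allele labels.
#' @param sfAllele label of the dominant self-fertility allele
#'   (default `"Sf"`); pollen carrying it is never rejected.
#' @return An [SGenotype-class].
#' @examples
#' SGenotype("S1", "Sx")
#' @export
SGenotype <- function(a1, a2, sfAllele = "Sf") {
  new("SGenotype", alleles = c(a1, a2), sfAllele = sfAllele)
}

#' Construct a MarkerSpec
#'
#' S-linked markers ride on one named S allele of the parent(s) carrying
#' that allele and co-segregate with it except for recombination at
#' fraction `r`. Unlinked markers segregate Mendelianly from each parent's
#' presence genotype.
#'
#' @param markerId marker identifier.
#' @param linkage `"s_linked"` or `"unlinked"`.
#' @param allele linked S allele label (required for s_linked).
#' @param r recombination fraction to the S locus, `[0, 0.5]`, default 0.
#' @param motherGeno,fatherGeno `"absent"`, `"hemizygous"` or
#'   `"homozygous"` (unlinked markers).
#' @return A [MarkerSpec-class].
#' @examples
#' markerSpec("mSy", "s_linked", allele = "Sy")
#' markerSpec("mU", "unlinked", motherGeno = "hemizygous",
#'            fatherGeno = "hemizygous")
#' @export
markerSpec <- function(markerId, linkage = c("s_linked", "unlinked"),
                       allele = NULL, r = 0,
                       motherGeno = "absent", fatherGeno = "absent") {
  linkage <- match.arg(linkage)
  new("MarkerSpec", markerId = markerId, linkage = linkage,
      allele = allele, r = r, motherGeno = motherGeno,
      fatherGeno = fatherGeno)
}
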