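#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' GeneModel: exon/intron structure of a gene on its genomic sequence
#'
#' Holds the exon chain inferred by spliced mapping of a CDS onto a genomic
#' sequence. Exon coordinates are 1-based inclusive on the genomic sequence
#' (the convention used by [IRanges::IRanges] and by GFF3 output); introns
#' are the gaps between consecutive exons.
#'
#' @slot geneId single gene identifier.
#' @slot exons [IRanges::IRanges] of exon coordinates, sorted, disjoint.
#' @slot spliceSites character vector, one per intron, formatted
#'   `"GT..AG"` (donor/acceptor dinucleotides).
#' @slot cds the spliced CDS sequence the exons reconstruct.
#' @slot genomicLength length of the genomic sequence the model lives on.
#'
#' @seealso [inferGeneStructure()], [writeGff3()], [intronInHv()]
#' @export
setClass("GeneModel", representation(
  geneId = "character",
  exons = "IRanges",
  spliceSites = "character",
  cds = "character",
  genomicLength = "integer"
))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (length(ex) < 1L)
    msg <- c(msg, "at least one exon required")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE))
    msg <- c(msg, "exons must be sorted by start")
  if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
    msg <- c(msg, "exons must be non-overlapping with introns of length >= 1")
  if (any(st < 1L) || any(en > object@genomicLength))
    msg <- c(msg, "exon coordinates outside the genomic sequence")
  if (length(object@spliceSites) != max(0L, length(ex) - 1L))
    msg <- c(msg, "one splice-site record per intron required")
  if (sum(IRanges::width(ex)) != nchar(object@cds))
    msg <- c(msg, "total exon width must equal CDS length")
  if (length(msg)) msg else TRUE
})

#' SGenotype: a diploid S-locus genotype
#'
#' Two S-allele labels, e.g. `S1`/`Sx`. The label given in `sfAllele`
#' (default `"Sf"`) denotes the dominant self-fertility allele: pollen
#' carrying it is never rejected.
#'
#' @slot alleles character(2) allele labels.
#' @slot sfAllele label treated as the self-fertility allele.
#' @seealso [gsiCross()]
#' @export
setClass("SGenotype", representation(
  alleles = "character",
  sfAllele = "character"
))

setValidity("SGenotype", function(object) {
  if (length(object@alleles) != 2L || any(!nzchar(object@alleles)))
    return("an SGenotype carries exactly two non-empty allele labels")
  if (length(object@sfAllele) != 1L)
    return("sfAllele must be a single label")
  TRUE
})

#' MarkerSpec: a presence/absence marker attached to a GSI cross
#'
#' Either S-linked (rides on one named S allele, with recombination
#' fraction `r` to the S locus) or unlinked (transmitted Mendelianly from
#' each parent's presence genotype: `absent`, `hemizygous` or
#' `homozygous`).
#'
#' @slot markerId marker identifier.
#' @slot linkage `"s_linked"` or `"unlinked"`.
#' @slot allele linked S allele label (s_linked only).
#' @slot r recombination fraction to the S locus, in `[0, 0.5]`.
#' @slot motherGeno,fatherGeno presence genotype per parent (unlinked only).
#' @seealso [markerSpec()], [attachMarkers()]
#' @export
setClass("MarkerSpec", representation(
  markerId = "character",
  linkage = "character",
  allele = "characterOrNULL",
  r = "numeric",
  motherGeno = "character",
  fatherGeno = "character"
))

setValidity("MarkerSpec", function(object) {
  msg <- character()
  if (!object@linkage %in% c("s_linked", "unlinked"))
    msg <- c(msg, "linkage must be 's_linked' or 'unlinked'")
  if (object@linkage == "s_linked" &&
      (is.null(object@allele) || length(object@allele) != 1L))
    msg <- c(msg, "s_linked markers need exactly one linked allele label")
  if (object@r < 0 || object@r > 0.5)
    msg <- c(msg, "recombination fraction r must be in [0, 0.5]")
  geno <- c("absent", "hemizygous", "homozygous")
  if (!object@motherGeno %in% geno || !object@fatherGeno %in% geno)
    msg <- c(msg, "parent genotypes must be absent/hemizygous/homozygous")
  if (length(msg)) msg else TRUE
})

#' GsiProgeny: a simulated (or observed) progeny table
#'
#' One row per progeny, with the transmitted maternal/paternal S alleles
#' and one logical column per scored marker. Simulated tables can never
#' violate the GSI rejection rule (a paternal allele matching either
#' maternal allele, unless it is the self-fertility allele): this is
#' enforced by the class validity.
#'
#' @slot progeny data.frame with columns `maternal`, `paternal`, then
#'   marker columns (logical).
#' @slot mother,father [SGenotype-class] of the seed and pollen parent.
#' @slot direction label of the cross, e.g. `"mother x father"`.
#' @slot seed RNG seed used for simulation (NA for observed data).
#' @seealso [gsiCross()], [attachMarkers()], [segregationTable()]
#' @export
setClass("GsiProgeny", representation(
  progeny = "data.frame",
  mother = "SGenotype",
  father = "SGenotype",
  direction = "character",
  seed = "integer"
))

setValidity("GsiProgeny", function(object) {
  df <- object@progeny
  msg <- character()
  if (nrow(df) < 1L) msg <- c(msg, "progeny table must have n > 0 rows")
  if (!all(c("maternal", "paternal") %in% colnames(df)))
    msg <- c(msg, "progeny table needs 'maternal' and 'paternal' columns")
  else {
    ma <- object@mother@alleles
    sf <- object@mother@sfAllele
    bad <- df$paternal %in% setdiff(ma, sf)
    if (any(bad))
      msg <- c(msg, sprintf(
        "GSI rejection rule violated in %d progeny row(s)", sum(bad)))
    if (!all(df$maternal %in% ma))
      msg <- c(msg, "maternal alleles must come from the mother")
    if (!all(df$paternal %in% object@father@alleles))
      msg <- c(msg, "paternal alleles must come from the father")
  }
  if (length(msg)) msg else TRUE
})
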