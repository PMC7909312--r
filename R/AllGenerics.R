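#' @include AllClasses.R
NULL

#' Accessors for GeneModel, SGenotype and GsiProgeny objects
#'
#' `exons()` returns the exon [IRanges::IRanges]; `introns()` the intron
#' ranges derived as the gaps between exons; `intronLengths()` their
#' widths; `spliceSites()` the donor/acceptor dinucleotides; `geneId()`
#' the identifier; `cdsSeq()` the spliced CDS. `alleles()` returns the two
#' S-allele labels of an [SGenotype-class]. `progenyTable()` returns the
#' underlying data.frame of a [GsiProgeny-class] and `markerNames()` its
#' marker columns.
#'
#' @param x a `GeneModel`, `SGenotype` or `GsiProgeny` object.
#' @return See the individual accessor descriptions.
#' @examples
#' gm <- GeneModel("g1", IRanges::IRanges(c(1, 201), c(100, 300)),
#'                 spliceSites = "GT..AG",
#'                 cds = strrep("A", 200), genomicLength = 300L)
#' introns(gm)
#' intronLengths(gm)
#' @name GeneModel-accessors
#' @aliases exons introns intronLengths spliceSites geneId cdsSeq alleles
#'   progenyTable markerNames
NULL

#' @rdname GeneModel-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("intronLengths", function(x) standardGeneric("intronLengths"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("spliceSites", function(x) standardGeneric("spliceSites"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("progenyTable", function(x) standardGeneric("progenyTable"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname GeneModel-accessors
setMethod("exons", "GeneModel", function(x) x@exons)

#' @rdname GeneModel-accessors
setMethod("introns", "GeneModel", function(x) {
  ex <- x@exons
  if (length(ex) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(IRanges::end(ex)[-length(ex)] + 1L,
                   IRanges::start(ex)[-1L] - 1L)
})

#' @rdname GeneModel-accessors
setMethod("intronLengths", "GeneModel",
          function(x) IRanges::width(introns(x)))

#' @rdname GeneModel-accessors
setMethod("spliceSites", "GeneModel", function(x) x@spliceSites)

#' @rdname GeneModel-accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname GeneModel-accessors
setMethod("cdsSeq", "GeneModel", function(x) x@cds)

#' @rdname GeneModel-accessors
setMethod("alleles", "SGenotype", function(x) x@alleles)

#' @rdname GeneModel-accessors
setMethod("progenyTable", "GsiProgeny", function(x) x@progeny)

#' @rdname GeneModel-accessors
setMethod("markerNames", "GsiProgeny", function(x)
  setdiff(colnames(x@progeny), c("maternal", "paternal")))

setMethod("show", "GeneModel", function(object) {
  ni <- length(object@exons) - 1L
  cat(sprintf("GeneModel '%s': %d exon(s), %d intron(s) on %d bp genomic\n",
              object@geneId, length(object@exons), ni,
              object@genomicLength))
  if (ni > 0L)
    cat(sprintf("  intron lengths: %s; splice sites: %s\n",
                paste(intronLengths(object), collapse = ", "),
                paste(object@spliceSites, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "SGenotype", function(object) {
  sf <- object@alleles %in% object@sfAllele
  lab <- paste0(object@alleles, ifelse(sf, " (self-fertile)", ""))
  cat("SGenotype:", paste(lab, collapse = " / "), "\n")
  invisible(NULL)
})

setMethod("show", "GsiProgeny", function(object) {
  cat(sprintf("GsiProgeny: %d progeny from %s [seed %s]\n",
              nrow(object@progeny), object@direction,
              ifelse(is.na(object@seed), "NA", object@seed)))
  mk <- markerNames(object)
  if (length(mk)) cat("  markers:", paste(mk, collapse = ", "), "\n")
  invisible(NULL)
})
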