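#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString
NULL

#' Total duplex nucleotides sequenced
#'
#' Sum of per-position duplex depths over a depth profile, optionally
#' restricted to a subset of regions. This is the denominator of every
#' mutation frequency.
#'
#' @param x a [DepthProfile-class].
#' @param region optional [GenomicRanges::GRanges] restriction.
#' @return numeric, summed duplex depth (duplex nucleotides).
#' @export
setGeneric("totalDuplexNucleotides",
           function(x, region = NULL) standardGeneric("totalDuplexNucleotides"))

#' Duplex depth at genomic positions
#'
#' @param x a [DepthProfile-class].
#' @param chrom character vector of chromosomes.
#' @param pos integer vector of 1-based positions.
#' @return integer vector of depths (`NA` where uncovered).
#' @export
setGeneric("depthAt", function(x, chrom, pos) standardGeneric("depthAt"))

#' @rdname geneAccessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname geneAccessors
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))

#' @rdname geneAccessors
#' @export
setGeneric("cdsIntervals", function(x) standardGeneric("cdsIntervals"))

#' @rdname geneAccessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' @rdname geneAccessors
#' @export
setGeneric("geneDomains", function(x) standardGeneric("geneDomains"))

#' Accessors for gene models
#'
#' `geneId()`, `cdsSequence()`, `cdsIntervals()`, `geneDomains()` return the
#' corresponding slots; `proteinLength()` returns the number of encoded
#' residues, excluding the terminal stop codon when the CDS ends in one.
#'
#' @param x a [GeneModel-class].
#' @name geneAccessors
NULL

setMethod("geneId", "GeneModel", function(x) x@geneId)
setMethod("cdsSequence", "GeneModel", function(x) x@cdsSequence)
setMethod("cdsIntervals", "GeneModel", function(x) x@cdsIntervals)
setMethod("geneDomains", "GeneModel", function(x) x@domains)
setMethod("proteinLength", "GeneModel", function(x) {
    L <- length(x@cdsSequence) %/% 3L
    last <- as.character(Biostrings::subseq(x@cdsSequence,
        length(x@cdsSequence) - 2L, length(x@cdsSequence)))
    if (Biostrings::GENETIC_CODE[[last]] == "*") L - 1L else L
})

#' @rdname cohortAccessors
#' @export
setGeneric("cohortCalls", function(x) standardGeneric("cohortCalls"))

#' @rdname cohortAccessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' @rdname cohortAccessors
#' @export
setGeneric("cohortDepth", function(x, sample) standardGeneric("cohortDepth"))

#' @rdname cohortAccessors
#' @export
setGeneric("cohortReads", function(x) standardGeneric("cohortReads"))

#' @rdname cohortAccessors
#' @export
setGeneric("cohortMask", function(x) standardGeneric("cohortMask"))

#' @rdname cohortAccessors
#' @export
setGeneric("cohortGeneModels", function(x) standardGeneric("cohortGeneModels"))

#' Accessors for synthetic cohorts
#'
#' @param x a [DuplexCohort-class].
#' @param sample sample identifier (for `cohortDepth`); if missing, the
#'   full named list of depth profiles is returned.
#' @name cohortAccessors
NULL

setMethod("cohortCalls", "DuplexCohort", function(x) x@calls)
setMethod("cohortMetadata", "DuplexCohort", function(x) x@metadata)
setMethod("cohortDepth", "DuplexCohort", function(x, sample) {
    if (missing(sample)) x@depth else x@depth[[sample]]
})
setMethod("cohortReads", "DuplexCohort", function(x) x@reads)
setMethod("cohortMask", "DuplexCohort", function(x) x@mask)
setMethod("cohortGeneModels", "DuplexCohort", function(x) x@geneModels)

#' @rdname dndsAccessors
#' @export
setGeneric("dndsEstimate", function(x) standardGeneric("dndsEstimate"))

#' @rdname dndsAccessors
#' @export
setGeneric("dndsIQR", function(x) standardGeneric("dndsIQR"))

#' @rdname dndsAccessors
#' @export
setGeneric("dndsReplicates", function(x) standardGeneric("dndsReplicates"))

#' Accessors for dN/dS results
#'
#' `dndsEstimate()` returns the pseudocounted point estimate, `dndsIQR()`
#' the bootstrap 25th/75th percentiles as a length-2 vector, and
#' `dndsReplicates()` the full replicate distribution.
#'
#' @param x a [DndsResult-class].
#' @name dndsAccessors
NULL

setMethod("dndsEstimate", "DndsResult", function(x) x@point)
setMethod("dndsIQR", "DndsResult", function(x) c(q25 = x@q25, q75 = x@q75))
setMethod("dndsReplicates", "DndsResult", function(x) x@replicates)
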